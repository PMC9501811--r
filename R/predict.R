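# stratified replicate index draws: every replicate holds exactly n1
# presences and n0 absences
resample_indices <- function(idx1, idx0, n1, n0, n_reps, seed,
                             replace = FALSE) {
  withr::with_seed(seed, purrr::map(seq_len(n_reps), function(r)
    c(sample(idx1, n1, replace = replace),
      sample(idx0, n0, replace = replace))))
}

#' Predicted UEL distribution by stratified subsampling
#'
#' Emulates the resampling scheme behind the predicted upper elevational
#' limit: each of `n_reps` replicates draws `ceiling(frac * n1)` presences
#' and `ceiling(frac * n0)` absences (stratified, without replacement by
#' default), refits the full seven-model HOF family with AIC selection, and
#' extracts the outer border. The predicted UEL is the mean outer border;
#' a 95% interval is taken from the 2.5/97.5 percentiles of the replicate
#' outer borders (a normal-approximation interval is also reported).
#' Replicates whose border is censored at the top of the gradient
#' contribute the gradient maximum and are counted in `n_censored`.
#'
#' @param pa_series tibble with `elevation`, `presence`.
#' @param frac fraction of each stratum drawn per replicate.
#' @param n_reps number of replicates.
#' @param seed integer seed controlling both the draws and the fits.
#' @param replace draw within replicates with replacement (bootstrap-style)
#'   instead of subsampling.
#' @param species optional label carried into the result.
#' @inheritParams fit_hof
#' @return a `uel_prediction` object: `ob_samples`, `mean_ob`, `median_ob`,
#'   `ci_low`/`ci_high` (percentile), `ci_low_norm`/`ci_high_norm`,
#'   `n_censored`, `n_failed`, `status` (`"ok"` or `"unstable"` when more
#'   than half the replicates failed, in which case no CI is reported).
#' @export
resample_ob <- function(pa_series, frac = 0.25, n_reps = 100, seed = 1,
                        n_starts = 10, min_presences = 5, maxit = 500,
                        replace = FALSE, species = NA_character_) {
  if (frac <= 0 || frac > 1) abort("`frac` must lie in (0, 1].")
  idx1 <- which(pa_series$presence == 1)
  idx0 <- which(pa_series$presence == 0)
  n1 <- ceiling(frac * length(idx1))
  n0 <- ceiling(frac * length(idx0))
  if (length(idx1) < ceiling(1 / frac) || length(idx0) < ceiling(1 / frac))
    abort(sprintf(paste0("need at least %d presences and %d absences so ",
                         "every replicate holds one of each"),
                  ceiling(1 / frac), ceiling(1 / frac)),
          class = "uelshift_unfittable")
  draws <- resample_indices(idx1, idx0, n1, n0, n_reps, seed, replace)
  # fit the full series once per type; replicate refits warm-start from
  # these optima with a reduced fresh-start design
  family <- tryCatch(
    purrr::map(1:7, function(tp)
      fit_hof(pa_series, tp, n_starts = n_starts, seed = seed + tp,
              min_presences = min_presences, maxit = maxit)),
    error = function(e) NULL)
  rep_starts <- if (is.null(family)) n_starts else max(3L, n_starts %/% 3L)
  reps <- purrr::map(seq_len(n_reps), function(r) {
    sub <- pa_series[sort(draws[[r]]), ]
    tryCatch({
      fit <- select_hof(sub, n_starts = rep_starts, seed = seed,
                        min_presences = min(min_presences, n1),
                        maxit = maxit, warm_fits = family)
      outer_border(fit)
    }, error = function(e) NULL)
  })
  ok <- !purrr::map_lgl(reps, is.null)
  ob <- purrr::map_dbl(reps[ok], "ob")
  censored <- purrr::map_lgl(reps[ok], "censored")
  res <- list(species = species, ob_samples = ob,
              n_reps = n_reps, n_failed = sum(!ok),
              n_censored = sum(censored), frac = frac,
              status = if (sum(!ok) > n_reps / 2) "unstable" else "ok")
  if (res$status == "ok") {
    qs <- unname(quantile(ob, c(0.025, 0.975)))
    res <- c(res, list(mean_ob = mean(ob), median_ob = median(ob),
                       ci_low = qs[1], ci_high = qs[2],
                       ci_low_norm = mean(ob) - 1.96 * sd(ob),
                       ci_high_norm = mean(ob) + 1.96 * sd(ob)))
  } else {
    warn(sprintf("%d of %d replicates failed: prediction unstable, no CI",
                 res$n_failed, n_reps))
    res <- c(res, list(mean_ob = mean(ob), median_ob = median(ob),
                       ci_low = NA_real_, ci_high = NA_real_,
                       ci_low_norm = NA_real_, ci_high_norm = NA_real_))
  }
  structure(res, class = "uel_prediction")
}

#' @export
print.uel_prediction <- function(x, ...) {
  cat(sprintf("predicted UEL: %.1f m [%.1f, %.1f] (%d reps, %d censored, %d failed)\n",
              x$mean_ob, x$ci_low, x$ci_high, x$n_reps, x$n_censored,
              x$n_failed))
  invisible(x)
}

#' Classify a species' climatic-equilibrium status
#'
#' A species is in climatic equilibrium when its observed UEL falls inside
#' the 95% confidence interval of the predicted UEL; it is `"below"`
#' (observed limit lower than predicted: room for upward expansion) when
#' the observed UEL lies under the interval and `"above"` when over it.
#' The standardized difference `delta_std = |UELo - UELp| / UELp` is
#' reported alongside.
#'
#' @param observed observed UEL in m a.s.l.
#' @param predicted a [resample_ob()] result.
#' @param species optional label (defaults to the prediction's).
#' @return one-row tibble: `species`, `uel_observed`, `uel_predicted`,
#'   `ci_low`, `ci_high`, `class`, `delta_std`, `n_censored`.
#' @export
classify_equilibrium <- function(observed, predicted, species = NULL) {
  stopifnot(inherits(predicted, "uel_prediction"))
  species <- species %||% predicted$species
  cls <- if (predicted$status != "ok" || is.na(predicted$ci_low)) {
    "undetermined"
  } else if (observed < predicted$ci_low) {
    "below"
  } else if (observed > predicted$ci_high) {
    "above"
  } else {
    "equilibrium"
  }
  tibble::tibble(species = species, uel_observed = observed,
                 uel_predicted = predicted$mean_ob,
                 ci_low = predicted$ci_low, ci_high = predicted$ci_high,
                 class = cls,
                 delta_std = standardized_delta(observed, predicted$mean_ob),
                 n_censored = predicted$n_censored)
}

#' Cohort summary of equilibrium classes
#'
#' @param results tibble of rows from [classify_equilibrium()].
#' @return tibble with `class`, `n` and integer-rounded percentage `pct`.
#' @export
cohort_summary <- function(results) {
  if (nrow(results) == 0) abort("no results to summarise.")
  results |>
    dplyr::count(class = factor(.data$class,
                                levels = c("below", "equilibrium", "above",
                                           "undetermined")),
                 .drop = FALSE, name = "n") |>
    dplyr::filter(!(.data$class == "undetermined" & .data$n == 0)) |>
    dplyr::mutate(pct = round(100 * .data$n / sum(.data$n)))
}
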