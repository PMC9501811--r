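#' Tidy a fitted HOF model
#'
#' @param x a `hof_fit`.
#' @param ... unused.
#' @return tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.hof_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' One-row summary of a fitted HOF model
#'
#' @param x a `hof_fit`.
#' @param ... unused.
#' @return tibble with model type, parameter count, log-likelihood, AIC,
#'   maximum response and gradient range.
#' @export
glance.hof_fit <- function(x, ...) {
  tibble::tibble(model = x$model, k = x$k, logL = x$logL, AIC = x$AIC,
                 y_max = x$y_max, n = x$n,
                 x_min = x$x_scaling[1], x_max = x$x_scaling[2],
                 degenerate = x$degenerate %||% NA_character_)
}

#' Tidy a predicted-UEL resampling distribution
#'
#' @param x a `uel_prediction`.
#' @param ... unused.
#' @return tibble with one row per replicate outer border.
#' @export
tidy.uel_prediction <- function(x, ...) {
  tibble::tibble(species = x$species, rep = seq_along(x$ob_samples),
                 ob = x$ob_samples)
}

#' One-row summary of a predicted UEL
#'
#' @param x a `uel_prediction`.
#' @param ... unused.
#' @return tibble with the mean/median outer border, both 95% intervals,
#'   and the censoring/failure counts.
#' @export
glance.uel_prediction <- function(x, ...) {
  tibble::tibble(species = x$species, mean_ob = x$mean_ob,
                 median_ob = x$median_ob, ci_low = x$ci_low,
                 ci_high = x$ci_high, ci_low_norm = x$ci_low_norm,
                 ci_high_norm = x$ci_high_norm, n_reps = x$n_reps,
                 n_censored = x$n_censored, n_failed = x$n_failed,
                 status = x$status)
}

#' Tidy an observed-versus-predicted regression
#'
#' @param x an `obs_pred_fit`.
#' @param ... unused.
#' @return tibble with the intercept and slope rows plus the slope-vs-1
#'   test.
#' @export
tidy.obs_pred_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble::tibble(term = c("(Intercept)", "predicted", "slope_vs_1"),
                 estimate = c(sm[1, 1], sm[2, 1], 1 - x$slope),
                 std_error = c(sm[1, 2], sm[2, 2], x$se_slope),
                 statistic = c(sm[1, 3], sm[2, 3], x$t_slope1),
                 p_value = c(sm[1, 4], sm[2, 4], x$p_slope1))
}

#' One-row summary of an observed-versus-predicted regression
#'
#' @param x an `obs_pred_fit`.
#' @param ... unused.
#' @return tibble with `n`, `df`, `r2`, slope, and both test statistics.
#' @export
glance.obs_pred_fit <- function(x, ...) {
  tibble::tibble(n = x$n, df = x$df, r2 = x$r2, slope = x$slope,
                 se_slope = x$se_slope, intercept = x$intercept,
                 t_corr = x$t_corr, p_corr = x$p_corr,
                 t_slope1 = x$t_slope1, p_slope1 = x$p_slope1)
}
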