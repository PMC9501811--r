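#' Wilcoxon test for upper-elevational-limit comparisons
#'
#' Rank-based comparison of species-matched UEL vectors, with ties handled
#' by midranks. For small samples the null distribution is enumerated
#' exhaustively (all sign patterns for the paired signed-rank variant, all
#' rank assignments for the unpaired rank-sum variant); larger samples use
#' the normal approximation with continuity and tie corrections. The
#' default is unpaired: the rank-sum statistic is the one whose scale
#' matches W reported for the 2008-vs-2018 comparison, even though species
#' are matched across years (the paired variant is a flag away).
#'
#' @param uel_a,uel_b UEL vectors (equal length if `paired`).
#' @param paired use the signed-rank variant.
#' @param alternative `"two.sided"`, `"greater"` (a > b) or `"less"`.
#' @param exact_n_max largest sample size for which the exact null is
#'   enumerated.
#' @return one-row tibble: `statistic`, `p_value`, `method`, `n_a`, `n_b`.
#' @export
wilcoxon_uel <- function(uel_a, uel_b, paired = FALSE,
                         alternative = c("two.sided", "greater", "less"),
                         exact_n_max = 10) {
  alternative <- match.arg(alternative)
  uel_a <- uel_a[!is.na(uel_a)]
  uel_b <- uel_b[!is.na(uel_b)]
  if (paired) {
    if (length(uel_a) != length(uel_b))
      abort("paired vectors must have equal length.")
    wilcoxon_signed_rank(uel_a, uel_b, alternative, exact_n_max)
  } else {
    if (length(uel_a) < 3 || length(uel_b) < 3)
      abort("need at least 3 observations per group.")
    wilcoxon_rank_sum(uel_a, uel_b, alternative, exact_n_max)
  }
}

p_from_null <- function(stat, null_stats, alternative) {
  ge <- mean(null_stats >= stat - 1e-9)
  le <- mean(null_stats <= stat + 1e-9)
  switch(alternative,
         greater = ge, less = le,
         two.sided = min(1, 2 * min(ge, le)))
}

wilcoxon_rank_sum <- function(a, b, alternative, exact_n_max) {
  n1 <- length(a)
  n2 <- length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (max(n1, n2) <= exact_n_max) {
    sets <- utils::combn(n1 + n2, n1)
    null_w <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- p_from_null(w, null_w, alternative)
    method <- "rank-sum (exact enumeration)"
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    if (sig2 <= 0)
      return(tibble::tibble(statistic = w, p_value = 1,
                            method = "rank-sum (degenerate: all tied)",
                            n_a = n1, n_b = n2))
    z_num <- w - mu
    cc <- switch(alternative, two.sided = sign(z_num) * 0.5, greater = 0.5,
                 less = -0.5)
    z <- (z_num - cc) / sqrt(sig2)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    p <- min(1, p)
    method <- "rank-sum (normal approximation)"
  }
  tibble::tibble(statistic = w, p_value = p, method = method,
                 n_a = n1, n_b = n2)
}

wilcoxon_signed_rank <- function(a, b, alternative, exact_n_max) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("all paired differences are zero; p = 1")
    return(tibble::tibble(statistic = 0, p_value = 1,
                          method = "signed-rank (degenerate)",
                          n_a = length(a), n_b = length(b)))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_n_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    null_v <- as.numeric(signs %*% r)
    p <- p_from_null(v, null_v, alternative)
    method <- "signed-rank (exact enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z_num <- v - mu
    cc <- switch(alternative, two.sided = sign(z_num) * 0.5, greater = 0.5,
                 less = -0.5)
    z <- (z_num - cc) / sqrt(sig2)
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    p <- min(1, p)
    method <- "signed-rank (normal approximation)"
  }
  tibble::tibble(statistic = v, p_value = p, method = method,
                 n_a = length(a), n_b = length(b))
}

#' Temporal change records for observed UELs
#'
#' @param data tibble with one row per species.
#' @param uel_first,uel_last columns holding the first- and last-epoch
#'   observed UELs (m a.s.l.).
#' @param species column holding the species label.
#' @param stability_threshold absolute change (m) at or under which a
#'   species counts as stable. The default 0 treats any movement as change;
#'   set it to the survey's plot spacing to absorb quantization.
#' @return tibble with `species`, `uel_first`, `uel_last`, `delta` and
#'   `change_class` in `"up"`, `"down"`, `"stable"`; species missing an
#'   epoch are excluded with a message.
#' @export
classify_change <- function(data, uel_first = uel_2008, uel_last = uel_2018,
                            species = species, stability_threshold = 0) {
  if (stability_threshold < 0) abort("`stability_threshold` must be >= 0.")
  rec <- dplyr::transmute(data, species = {{ species }},
                          uel_first = {{ uel_first }},
                          uel_last = {{ uel_last }})
  incomplete <- is.na(rec$uel_first) | is.na(rec$uel_last)
  if (any(incomplete))
    inform(paste0("excluding species missing an epoch: ",
                  paste(rec$species[incomplete], collapse = ", ")))
  rec |>
    dplyr::filter(!incomplete) |>
    dplyr::mutate(delta = .data$uel_last - .data$uel_first,
                  change_class = dplyr::case_when(
                    abs(.data$delta) <= stability_threshold ~ "stable",
                    .data$delta > stability_threshold ~ "up",
                    TRUE ~ "down"))
}

#' Summary of temporal change classes
#'
#' @param records a [classify_change()] result.
#' @return tibble with `change_class`, `n`, integer-rounded `pct`.
#' @export
change_summary <- function(records) {
  records |>
    dplyr::count(change_class = factor(.data$change_class,
                                       levels = c("up", "down", "stable")),
                 .drop = FALSE, name = "n") |>
    dplyr::mutate(pct = round(100 * .data$n / sum(.data$n)))
}

#' Observed-versus-predicted UEL regression
#'
#' Ordinary least squares of observed on predicted limits, reporting both
#' the correlation test (H0: r = 0, `t_corr = r sqrt(df / (1 - r^2))`) and
#' the departure of the slope from the 1:1 line
#' (H0: b = 1, `t_slope1 = (1 - b) / se(b)`), each on `n - 2` degrees of
#' freedom. A slope significantly below 1 indicates that species with high
#' predicted limits sit proportionally further below them.
#'
#' @param data tibble with one row per species.
#' @param observed,predicted columns holding the observed and predicted
#'   UELs.
#' @return an `obs_pred_fit` object; see [tidy.obs_pred_fit()] and
#'   [glance.obs_pred_fit()].
#' @export
regress_obs_pred <- function(data, observed = uel_observed,
                             predicted = uel_predicted) {
  d <- dplyr::transmute(data, observed = {{ observed }},
                        predicted = {{ predicted }}) |>
    na.omit()
  n <- nrow(d)
  if (n < 3) abort("need at least 3 matched species.")
  if (sd(d$predicted) == 0) abort("predictor has zero variance.")
  mod <- lm(observed ~ predicted, data = d)
  sm <- summary(mod)
  b <- unname(sm$coefficients["predicted", "Estimate"])
  se_b <- unname(sm$coefficients["predicted", "Std. Error"])
  r2 <- sm$r.squared
  df <- n - 2
  r <- sign(b) * sqrt(r2)
  t_corr <- r * sqrt(df / (1 - min(r2, 1 - 1e-15)))
  # an exactly proportional fit has numerator 0: report 0, not float noise
  t_slope1 <- if (abs(1 - b) < 1e-10 * max(1, abs(b))) 0 else (1 - b) / se_b
  structure(list(model = mod, n = n, df = df, slope = b, se_slope = se_b,
                 intercept = unname(sm$coefficients["(Intercept)",
                                                    "Estimate"]),
                 r2 = r2, t_corr = t_corr,
                 p_corr = 2 * pt(-abs(t_corr), df),
                 t_slope1 = t_slope1,
                 p_slope1 = 2 * pt(-abs(t_slope1), df)),
            class = "obs_pred_fit")
}

#' @export
print.obs_pred_fit <- function(x, ...) {
  cat(sprintf("observed ~ predicted UEL (n = %d)\n", x$n))
  cat(sprintf("  r2 = %.2f, t = %.2f, d.f. = %d, p = %.4g\n",
              x$r2, x$t_corr, x$df, x$p_corr))
  cat(sprintf("  slope b = %.2f vs 1: t = %.2f, p = %.4g\n",
              x$slope, x$t_slope1, x$p_slope1))
  invisible(x)
}

#' Sequential ANOVA of a response on species traits
#'
#' Linear model `response ~ residence_time + dispersal_mode + life_span`
#' with sequential (Type-I) sums of squares in that fixed order, matching
#' the conventional presentation with Df 1, 2, 2. Rows with missing values
#' are dropped listwise; single-level factors are dropped with a warning.
#'
#' @param data tibble with the trait columns `residence_time` (numeric
#'   years), `dispersal_mode` and `life_span` (categorical) and a response.
#' @param response column holding the response (e.g., standardized UEL
#'   difference).
#' @param type `"sequential"` (Type-I) or `"type2"` sums of squares.
#' @return tibble with `term`, `df`, `sumsq`, `meansq`, `statistic`,
#'   `p_value` (residual row included).
#' @export
trait_model <- function(data, response, type = c("sequential", "type2")) {
  type <- match.arg(type)
  d <- dplyr::transmute(data, response = {{ response }},
                        residence_time = .data$residence_time,
                        dispersal_mode = .data$dispersal_mode,
                        life_span = .data$life_span) |>
    na.omit()
  terms <- c("residence_time", "dispersal_mode", "life_span")
  for (tm in c("dispersal_mode", "life_span")) {
    if (length(unique(d[[tm]])) < 2) {
      warn(sprintf("factor `%s` has a single level and was dropped", tm))
      terms <- setdiff(terms, tm)
    }
  }
  form <- stats::reformulate(terms, response = "response")
  mod <- lm(form, data = d)
  if (mod$df.residual < 1) abort("no residual degrees of freedom.")
  tab <- if (type == "sequential") {
    as.data.frame(anova(mod))
  } else {
    if (!requireNamespace("car", quietly = TRUE))
      abort("Type-II sums of squares need the 'car' package.")
    tb <- as.data.frame(car::Anova(mod, type = 2))
    tb <- tb[, c("Df", "Sum Sq", "F value", "Pr(>F)")]
    tb$`Mean Sq` <- tb$`Sum Sq` / tb$Df
    tb[, c("Df", "Sum Sq", "Mean Sq", "F value", "Pr(>F)")]
  }
  tibble::tibble(term = rownames(tab), df = tab$Df, sumsq = tab$`Sum Sq`,
                 meansq = tab$`Mean Sq`, statistic = tab$`F value`,
                 p_value = tab$`Pr(>F)`)
}

#' Standardized difference between observed and predicted limits
#'
#' `delta = |UELo - UELp| / UELp`: the shortfall of the observed limit as a
#' fraction of the predicted one. Scale-free, so invariant to measuring
#' elevation in metres or kilometres.
#'
#' @param uelo,uelp observed and predicted UELs (same units; `uelp > 0`).
#' @return non-negative numeric vector.
#' @export
standardized_delta <- function(uelo, uelp) {
  if (any(uelp <= 0, na.rm = TRUE)) abort("`uelp` must be positive.")
  abs(uelo - uelp) / uelp
}
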