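#' @title Huisman-Olff-Fresco response models
#' @description
#' The seven hierarchical HOF shapes relate occurrence probability to a
#' gradient `x` (here, elevation) rescaled to `u = (x - x_min) /
#' (x_max - x_min)`. With the maximum attainable response fixed at 1 for
#' presence/absence data the model equations are
#' \deqn{I:\; y = 1/(1+e^{a})}
#' \deqn{II:\; y = 1/(1+e^{a+bu})}
#' \deqn{III:\; y = 1/(1+e^{a+bu}) \cdot 1/(1+e^{c})}
#' \deqn{IV:\; y = 1/(1+e^{a+bu}) \cdot 1/(1+e^{c-bu})}
#' \deqn{V:\; y = 1/(1+e^{a+bu}) \cdot 1/(1+e^{c-du})}
#' with VI and VII the sum of two model-IV-shaped humps, the second shifted
#' by `f` (and, for VII, scaled by a height ratio `r`), clipped to `[0, 1]`.
#' Free-parameter counts are 1, 2, 3, 3, 4, 4 and 5.
#' @name hof_models
NULL

hof_param_names <- list(c("a"), c("a", "b"), c("a", "b", "c"),
                        c("a", "b", "c"), c("a", "b", "c", "d"),
                        c("a", "b", "c", "f"), c("a", "b", "c", "f", "r"))

hof_k <- c(1L, 2L, 3L, 3L, 4L, 4L, 5L)

hof_roman <- c("I", "II", "III", "IV", "V", "VI", "VII")

# Parameter boxes. Slopes b, d are capped at 1000 (the sigmoid evaluation
# is overflow-safe at any slope; the cap only needs to exceed the steepest
# transition the data can resolve). Location-type intercepts are coupled to
# slope through the inflection u = -a/b (and c/d on the descending side),
# so their range must cover +/- 1.1 * slope cap for transitions anywhere on
# the gradient; pure level parameters (a in model I, c in model III) only
# set a plateau through 1/(1+e^t) and +/-25 already spans probabilities
# within 1e-10 of 0 and 1.
hof_slope_max <- 1000

hof_bounds <- function(type) {
  nm <- hof_param_names[[type]]
  loc <- 1.1 * hof_slope_max
  a_max <- if (type == 1) 25 else loc
  c_max <- if (type == 3) 25 else loc
  lower <- c(a = -a_max, b = 1e-8, c = -c_max, d = 1e-8, f = 0, r = 0)
  upper <- c(a = a_max, b = hof_slope_max, c = c_max, d = hof_slope_max,
             f = 1, r = 1)
  list(lower = unname(lower[nm]), upper = unname(upper[nm]), names = nm)
}

scale_gradient <- function(x, x_scaling) {
  (x - x_scaling[1]) / (x_scaling[2] - x_scaling[1])
}

#' Evaluate a HOF response curve
#'
#' @param type model type, 1-7.
#' @param params named or positional numeric parameter vector (see
#'   [hof_models]).
#' @param u gradient values on the fitted `[0, 1]` scale.
#' @return occurrence probabilities in `[0, 1]`.
#' @export
hof_curve <- function(type, params, u) {
  stopifnot(type %in% 1:7, length(params) == hof_k[type])
  .hof_response_cpp(as.integer(type), as.numeric(params), as.numeric(u))
}

#' Predicted occurrence probability of a fitted HOF model
#'
#' @param fit a `hof_fit` from [fit_hof()] or [select_hof()].
#' @param x elevations in m a.s.l.
#' @return occurrence probabilities in `[0, 1]`.
#' @export
hof_response <- function(fit, x) {
  stopifnot(inherits(fit, "hof_fit"))
  hof_curve(fit$type, fit$params, scale_gradient(x, fit$x_scaling))
}

#' Bernoulli negative log-likelihood of a HOF model
#'
#' \eqn{-\sum_i [y_i \log p_i + (1-y_i)\log(1-p_i)]} with probabilities
#' clipped to `[1e-9, 1 - 1e-9]`.
#'
#' @param type model type, 1-7.
#' @param params parameter vector.
#' @param pa_series tibble with `elevation` and `presence` columns.
#' @param x_scaling length-2 gradient range mapping elevation to `[0, 1]`
#'   (default: the series range).
#' @return scalar negative log-likelihood.
#' @export
hof_negloglik <- function(type, params, pa_series,
                          x_scaling = range(pa_series$elevation)) {
  if (nrow(pa_series) < 1) abort("series needs at least one observation.")
  u <- scale_gradient(pa_series$elevation, x_scaling)
  .hof_nll_cpp(as.integer(type), as.numeric(params), u,
               as.numeric(pa_series$presence))
}

# Latin-hypercube starting values. Slopes are spread log-uniformly over
# [0.5, slope cap] so shallow and near-step responses are both reachable;
# location-coupled intercepts are derived from a uniformly sampled
# transition position on the (slightly padded) gradient, a = -u_infl * b
# and c = u_desc * d, so starts describe curves that actually vary within
# the observed range at every slope.
hof_starts <- function(type, n_starts, seed) {
  bds <- hof_bounds(type)
  k <- length(bds$names)
  uni <- withr::with_seed(seed, lhs::randomLHS(n_starts, k))
  log_slope <- function(q) exp(log(0.5) + q * (log(hof_slope_max) - log(0.5)))
  b <- if ("b" %in% bds$names) log_slope(uni[, which(bds$names == "b")])
  d <- if ("d" %in% bds$names) log_slope(uni[, which(bds$names == "d")]) else b
  starts <- matrix(NA_real_, n_starts, k)
  for (j in seq_len(k)) {
    starts[, j] <- switch(bds$names[j],
      a = if (type == 1) -25 + uni[, j] * 50 else -(-0.1 + 1.2 * uni[, j]) * b,
      b = b,
      c = if (type == 3) -25 + uni[, j] * 50 else (-0.1 + 1.2 * uni[, j]) * d,
      d = d,
      f = uni[, j],
      r = uni[, j])
  }
  starts
}

new_hof_fit <- function(type, params, logL, x_scaling, n, degenerate = NULL,
                        converged = TRUE) {
  k <- hof_k[type]
  u <- seq(0, 1, length.out = 1001)
  y <- hof_curve(type, params, u)
  structure(list(type = type, model = hof_roman[type],
                 params = setNames(as.numeric(params),
                                   hof_param_names[[type]]),
                 logL = logL, k = k, AIC = 2 * k - 2 * logL,
                 x_scaling = x_scaling, y_max = max(y), n = n,
                 degenerate = degenerate, converged = converged),
            class = "hof_fit")
}

#' Fit one HOF model type by maximum likelihood
#'
#' Bounded multi-start optimization of the Bernoulli negative
#' log-likelihood: `n_starts` Latin-hypercube starting points, Nelder-Mead
#' within the parameter box (model I has a closed-form ML fit). The result
#' is deterministic given the seed.
#'
#' Series without contrast (all presences or all absences) yield a flagged
#' model-I plateau fit rather than an error; series with fewer than
#' `min_presences` presences are unfittable and raise a classed error
#' (`uelshift_unfittable`), which cohort drivers record and skip.
#'
#' @param pa_series tibble with `elevation`, `presence` (0/1).
#' @param type model type, 1-7.
#' @param n_starts number of starting points.
#' @param seed integer seed for the start design.
#' @param min_presences minimum number of presences required.
#' @param maxit Nelder-Mead iteration cap per start.
#' @param warm_starts optional numeric matrix (or vector) of additional
#'   starting parameter vectors, e.g. the optimum of a closely related
#'   fit; rows are appended to the Latin-hypercube design.
#' @return a `hof_fit` object.
#' @export
fit_hof <- function(pa_series, type, n_starts = 10, seed = 1,
                    min_presences = 5, maxit = 500, warm_starts = NULL) {
  stopifnot(type %in% 1:7)
  y <- pa_series$presence
  n <- length(y)
  if (n < 1) abort("series needs at least one observation.")
  x_scaling <- range(pa_series$elevation)
  if (diff(x_scaling) == 0) x_scaling <- x_scaling + c(-0.5, 0.5)
  degenerate <- if (all(y == 1)) "all_ones" else if (all(y == 0)) "all_zeros"
  if (is.null(degenerate) && sum(y) < min_presences)
    abort(sprintf("only %d presences (< %d): series unfittable", sum(y),
                  min_presences),
          class = "uelshift_unfittable")
  if (type == 1 || !is.null(degenerate)) {
    # closed-form ML plateau: p-hat = mean(y), a = logit(1 - p-hat)
    eps <- 1e-9
    phat <- min(max(mean(y), eps), 1 - eps)
    a <- min(max(log((1 - phat) / phat), -25), 25)
    fit <- new_hof_fit(1L, a, -hof_negloglik(1L, a, pa_series, x_scaling),
                       x_scaling, n, degenerate = degenerate)
    return(fit)
  }
  b <- hof_bounds(type)
  starts <- hof_starts(type, n_starts, seed)
  if (!is.null(warm_starts))
    starts <- rbind(matrix(warm_starts, ncol = hof_k[type]), starts)
  u <- scale_gradient(pa_series$elevation, x_scaling)
  res <- .hof_fit_cpp(as.integer(type), u, as.numeric(y), starts,
                      b$lower, b$upper, as.integer(maxit))
  new_hof_fit(as.integer(type), res$par, -res$nll, x_scaling, n,
              converged = res$converged)
}

#' Fit all seven HOF types and select by AIC
#'
#' Fits types I-VII and returns the fit with minimum `AIC = 2k - 2 logL`.
#' Ties (difference below `1e-6`) go to the model with fewer free
#' parameters, then to the lower type number. The per-type AIC table is
#' attached as `$aic_table`.
#'
#' @inheritParams fit_hof
#' @param warm_fits optional list of seven `hof_fit` objects (one per
#'   type), whose parameters seed the corresponding refits; used by the
#'   resampler to warm-start replicate fits from the full-series optima.
#' @return the selected `hof_fit`.
#' @export
select_hof <- function(pa_series, n_starts = 10, seed = 1,
                       min_presences = 5, maxit = 500, warm_fits = NULL) {
  fits <- purrr::map(1:7, function(tp)
    fit_hof(pa_series, tp, n_starts = n_starts, seed = seed + tp,
            min_presences = min_presences, maxit = maxit,
            warm_starts = if (!is.null(warm_fits) &&
                                warm_fits[[tp]]$type == tp)
              warm_fits[[tp]]$params))
  if (!is.null(fits[[1]]$degenerate)) {
    best <- fits[[1]]
    best$aic_table <- tibble::tibble(model = "I", k = 1L,
                                     logL = best$logL, AIC = best$AIC)
    return(best)
  }
  aic <- purrr::map_dbl(fits, "AIC")
  ord <- order(aic - min(aic) >= 1e-6, hof_k, 1:7)
  best <- fits[[ord[1]]]
  best$aic_table <- tibble::tibble(model = hof_roman, k = hof_k,
                                   logL = purrr::map_dbl(fits, "logL"),
                                   AIC = aic)
  best
}

#' @export
print.hof_fit <- function(x, ...) {
  cat(sprintf("HOF model %s (k = %d): logL = %.3f, AIC = %.3f\n",
              x$model, x$k, x$logL, x$AIC))
  cat("  params:", paste(names(x$params),
                         sprintf("%.4g", x$params), sep = " = ",
                         collapse = ", "), "\n")
  if (!is.null(x$degenerate)) cat("  degenerate series:", x$degenerate, "\n")
  invisible(x)
}

#' Outer border of a fitted response curve
#'
#' The predicted upper elevational limit: the highest elevation at which
#' the fitted occurrence probability still reaches `exp(-2)` of the highest
#' estimated response value. The response is scanned on a dense elevation
#' lattice (step <= 1 m) on the descending, upper side; the threshold
#' crossing is refined by bisection to +/- 0.1 m. When the response is
#' still at or above the threshold at the top of the gradient, the border
#' is censored at the top.
#'
#' @param fit a `hof_fit`.
#' @param step lattice spacing in m.
#' @param tol bisection tolerance in m.
#' @return one-row tibble with `ob` (m a.s.l.), `censored`, `y_max`.
#' @export
outer_border <- function(fit, step = 1, tol = 0.01) {
  stopifnot(inherits(fit, "hof_fit"))
  xr <- fit$x_scaling
  grid <- seq(xr[1], xr[2], length.out = max(2L, ceiling(diff(xr) / step) + 1L))
  y <- hof_response(fit, grid)
  y_max <- max(y)
  if (y_max <= 0) abort("degenerate fit: fitted response is zero everywhere.")
  thr <- exp(-2) * y_max
  above <- y >= thr
  i_last <- max(which(above))
  if (i_last == length(grid))
    return(tibble::tibble(ob = xr[2], censored = TRUE, y_max = y_max))
  lo <- grid[i_last]
  hi <- grid[i_last + 1]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (hof_response(fit, mid) >= thr) lo <- mid else hi <- mid
  }
  tibble::tibble(ob = (lo + hi) / 2, censored = FALSE, y_max = y_max)
}
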