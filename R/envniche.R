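#' Calibrate the two-axis PCA environmental space
#'
#' Centers and scales the climate variables of the global background and
#' extracts the first two principal axes, the plane in which the niche is
#' delineated. The sign of each axis is fixed so that its largest-magnitude
#' loading is positive, making scores reproducible across platforms.
#'
#' @param data tibble of background samples carrying the climate variables.
#' @param vars tidy-select specification of the climate columns
#'   (default: all columns starting with `"bio"`).
#' @return an `env_pca` object with elements `means`, `sds`, `loadings`
#'   (variables x 2), `explained_variance` (fraction per retained axis) and
#'   `var_names`.
#' @export
env_pca <- function(data, vars = dplyr::starts_with("bio")) {
  x <- dplyr::select(data, {{ vars }})
  if (ncol(x) < 2) abort("need at least 2 climate variables.")
  if (nrow(x) < 3) abort("need at least 3 samples to calibrate the PCA.")
  bad_rows <- which(!stats::complete.cases(x))
  if (length(bad_rows) > 0)
    abort(paste0("missing climate values in rows: ",
                 paste(utils::head(bad_rows, 10), collapse = ", ")))
  sds <- purrr::map_dbl(x, sd)
  if (any(sds == 0))
    abort(paste0("constant climate variable(s): ",
                 paste(names(x)[sds == 0], collapse = ", ")))
  pc <- prcomp(as.matrix(x), center = TRUE, scale. = TRUE)
  load <- pc$rotation[, 1:2, drop = FALSE]
  for (a in 1:2) {
    top <- which.max(abs(load[, a]))
    if (load[top, a] < 0) load[, a] <- -load[, a]
  }
  structure(list(means = pc$center, sds = pc$scale, loadings = load,
                 explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[1:2],
                 var_names = names(x)),
            class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  cat("PCA environmental space:", length(x$var_names), "variables\n")
  cat(sprintf("  axis 1: %.1f%% of variance; axis 2: %.1f%%\n",
              100 * x$explained_variance[1], 100 * x$explained_variance[2]))
  invisible(x)
}

#' Project samples into the calibrated environmental space
#'
#' @param pca an [env_pca()] calibration.
#' @param data tibble carrying every calibration climate variable.
#' @return a tibble with scores `pc1`, `pc2` (other columns of `data` such
#'   as `id` and `elevation` are carried through).
#' @export
project_env <- function(pca, data) {
  stopifnot(inherits(pca, "env_pca"))
  missing_vars <- setdiff(pca$var_names, names(data))
  if (length(missing_vars) > 0)
    abort(paste0("samples lack calibration variable(s): ",
                 paste(missing_vars, collapse = ", ")))
  x <- as.matrix(data[pca$var_names])
  scores <- scale(x, center = pca$means, scale = pca$sds) %*% pca$loadings
  dplyr::bind_cols(
    dplyr::select(data, dplyr::any_of(c("id", "elevation", "species"))),
    tibble::tibble(pc1 = as.vector(scores[, 1]), pc2 = as.vector(scores[, 2])))
}

scott_bandwidth <- function(x, fallback = 1e-8) {
  h <- sd(x) * length(x)^(-1 / 6)
  # degenerate point clouds (zero spread) get a nominal positive bandwidth
  if (!is.finite(h) || h <= 0) h <- max(diff(range(x)) / 100, fallback)
  h
}

# product-Gaussian KDE evaluated on the grid cell centers, as a matrix
# product (R x n) %*% (n x R); returns an R x R matrix normalized to sum 1
kde_on_grid <- function(px, py, cx, cy, hx, hy) {
  a <- outer(cx, px, function(g, p) dnorm(g, p, hx))
  b <- outer(py, cy, function(p, g) dnorm(g, p, hy))
  d <- (a %*% b) / length(px)
  d / sum(d)
}

#' Build the gridded environmental space
#'
#' Evaluates Gaussian kernel densities of the occurrence scores and of the
#' background scores on an `R x R` lattice spanning the calibration
#' (background) score range padded by the background bandwidth. Each density
#' is normalized to sum to 1 over the grid. Bandwidths follow Scott's rule
#' per axis (`sd * n^(-1/6)`).
#'
#' @param bg_scores,occ_scores tibbles with `pc1`, `pc2` columns
#'   (from [project_env()]).
#' @param R grid resolution (cells per axis).
#' @param min_occurrences species with fewer occurrences are skipped: a
#'   warning is raised and `NULL` returned (never an error), so cohort loops
#'   can drop them gracefully.
#' @param correction when `TRUE`, the occurrence density is divided by the
#'   background availability density before renormalization
#'   (occupancy-corrected niche).
#' @param thin_duplicates when `TRUE`, occurrences falling in the same grid
#'   cell are collapsed to one record before density estimation.
#' @return an `env_grid` object (or `NULL` when skipped) with densities,
#'   cell edges/centers and bandwidths.
#' @export
build_env_grid <- function(bg_scores, occ_scores, R = 100,
                           min_occurrences = 5, correction = FALSE,
                           thin_duplicates = FALSE) {
  if (nrow(occ_scores) < min_occurrences) {
    warn(sprintf("only %d occurrences (< %d); species skipped",
                 nrow(occ_scores), min_occurrences))
    return(NULL)
  }
  hx_bg <- scott_bandwidth(bg_scores$pc1)
  hy_bg <- scott_bandwidth(bg_scores$pc2)
  lims <- list(x = range(bg_scores$pc1) + c(-hx_bg, hx_bg),
               y = range(bg_scores$pc2) + c(-hy_bg, hy_bg))
  edges_x <- seq(lims$x[1], lims$x[2], length.out = R + 1)
  edges_y <- seq(lims$y[1], lims$y[2], length.out = R + 1)
  cx <- (edges_x[-1] + edges_x[-(R + 1)]) / 2
  cy <- (edges_y[-1] + edges_y[-(R + 1)]) / 2
  if (thin_duplicates) {
    cell <- paste(findInterval(occ_scores$pc1, edges_x),
                  findInterval(occ_scores$pc2, edges_y))
    occ_scores <- occ_scores[!duplicated(cell), ]
  }
  hx_occ <- scott_bandwidth(occ_scores$pc1, fallback = diff(edges_x[1:2]))
  hy_occ <- scott_bandwidth(occ_scores$pc2, fallback = diff(edges_y[1:2]))
  occ_d <- kde_on_grid(occ_scores$pc1, occ_scores$pc2, cx, cy, hx_occ, hy_occ)
  bg_d <- kde_on_grid(bg_scores$pc1, bg_scores$pc2, cx, cy, hx_bg, hy_bg)
  if (correction) {
    corr <- occ_d / pmax(bg_d, .Machine$double.eps)
    corr[bg_d <= 0] <- 0
    occ_d <- corr / sum(corr)
  }
  structure(list(R = R, edges_x = edges_x, edges_y = edges_y,
                 centers_x = cx, centers_y = cy,
                 occ_density = occ_d, bg_density = bg_d,
                 bandwidths = c(occ_x = hx_occ, occ_y = hy_occ,
                                bg_x = hx_bg, bg_y = hy_bg),
                 n_occ = nrow(occ_scores), correction = correction),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("environmental grid %dx%d; %d occurrences%s\n", x$R, x$R,
              x$n_occ, if (x$correction) " (availability-corrected)" else ""))
  invisible(x)
}

#' Delineate the species' global climatic niche
#'
#' Selects the densest grid cells until `level` of the occurrence density
#' mass is retained, leaving out the most extreme `1 - level` of the niche
#' surface. Ties at the cut are resolved by including all tied cells.
#'
#' @param grid an [build_env_grid()] result.
#' @param level retained density fraction in (0, 1].
#' @return a `niche_region` with the boolean cell `mask`, the `level`, the
#'   density threshold and the retained mass.
#' @export
delineate_niche <- function(grid, level = 0.99) {
  stopifnot(inherits(grid, "env_grid"))
  if (level <= 0 || level > 1) abort("`level` must lie in (0, 1].")
  d <- grid$occ_density
  if (level == 1) {
    mask <- d > 0
    thr <- 0
  } else {
    srt <- sort(as.numeric(d), decreasing = TRUE)
    cum <- cumsum(srt)
    thr <- srt[which(cum >= level)[1]]
    mask <- d >= thr & d > 0
  }
  structure(list(mask = mask, level = level, threshold = thr,
                 mass = sum(d[mask])),
            class = "niche_region")
}

#' @export
print.niche_region <- function(x, ...) {
  cat(sprintf("niche region: %d cells, %.4f of density mass (level %.2f)\n",
              sum(x$mask), x$mass, x$level))
  invisible(x)
}

#' Area of the niche region in squared axis units
#'
#' @param niche a [delineate_niche()] result.
#' @param grid the grid it was derived from.
#' @return numeric scalar.
#' @export
niche_area <- function(niche, grid) {
  cell <- diff(grid$edges_x[1:2]) * diff(grid$edges_y[1:2])
  sum(niche$mask) * cell
}
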