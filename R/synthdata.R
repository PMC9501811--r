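#' Configuration of a synthetic global climate world
#'
#' The synthetic world stands in for the global background: `n_background`
#' geo-referenced points whose climate vectors are driven by a small number of
#' latent gradients (the first latent is a temperature in degrees Celsius,
#' decreasing away from the equator), mixed into `n_climate_vars` collinear
#' bioclim-style variables by a loading matrix plus independent Gaussian
#' observation noise.
#'
#' @param n_background number of background points.
#' @param n_climate_vars number of climate variables (columns `bio01`...).
#' @param latent_dim number of latent climate gradients (>= 1).
#' @param loading_matrix optional `n_climate_vars x latent_dim` matrix of
#'   latent-to-variable weights; defaults to [default_loadings()].
#' @param noise_sd per-variable observation noise standard deviation
#'   (scalar or length `n_climate_vars`).
#' @param seed integer seed; the same seed reproduces the world exactly.
#' @return a `world_config` list.
#' @export
world_config <- function(n_background = 10000, n_climate_vars = 19,
                         latent_dim = 3, loading_matrix = NULL,
                         noise_sd = 0.2, seed = 1) {
  if (n_background < 1) abort("`n_background` must be positive.")
  if (n_climate_vars < latent_dim || latent_dim < 1)
    abort("need `n_climate_vars` >= `latent_dim` >= 1.")
  if (any(noise_sd < 0)) abort("`noise_sd` must be non-negative.")
  if (is.null(loading_matrix))
    loading_matrix <- default_loadings(n_climate_vars, latent_dim)
  stopifnot(nrow(loading_matrix) == n_climate_vars,
            ncol(loading_matrix) == latent_dim)
  structure(list(n_background = as.integer(n_background),
                 n_climate_vars = as.integer(n_climate_vars),
                 latent_dim = as.integer(latent_dim),
                 loading_matrix = loading_matrix,
                 noise_sd = rep_len(noise_sd, n_climate_vars),
                 seed = as.integer(seed)),
            class = "world_config")
}

#' Default latent-to-variable loading matrix
#'
#' Each climate variable loads with weight 1 on one primary latent gradient
#' (cycling through the gradients) and with smaller deterministic
#' cross-loadings on the others, giving the collinear structure typical of
#' bioclim variable sets. Deterministic: no randomness, so the world seed
#' only affects sampled points.
#'
#' @param n_vars,latent_dim dimensions of the matrix.
#' @return an `n_vars x latent_dim` numeric matrix.
#' @export
default_loadings <- function(n_vars, latent_dim) {
  w <- matrix(0, n_vars, latent_dim)
  for (j in seq_len(n_vars)) {
    primary <- (j - 1L) %% latent_dim + 1L
    w[j, ] <- 0.35 * cos(j * seq_len(latent_dim))
    w[j, primary] <- 1
  }
  w
}

latent_names <- function(d) paste0("latent", seq_len(d))
bio_names <- function(p) sprintf("bio%02d", seq_len(p))

# Latent gradients tied to synthetic geography so climate and location
# covary. Latitudes are drawn symmetrically and temperature falls linearly
# with |lat|, so the availability density of the temperature latent is flat
# across the whole span: regional mountain climates are then climatically
# nested in the background rather than sitting in a rarity tail.
latents_from_geography <- function(lon, lat, d) {
  n <- length(lon)
  l <- matrix(0, n, d)
  l[, 1] <- 28 - 0.62 * abs(lat) + rnorm(n, 0, 2)
  if (d >= 2) l[, 2] <- 1.2 * sin(pi * lon / 180) + 0.5 * cos(pi * lat / 90) +
      rnorm(n, 0, 0.6)
  if (d >= 3) l[, 3] <- 0.8 * cos(pi * lon / 90) + rnorm(n, 0, 0.8)
  if (d > 3) l[, 4:d] <- rnorm(n * (d - 3))
  colnames(l) <- latent_names(d)
  l
}

#' Generate the synthetic global background
#'
#' Draws `n_background` points with uniform synthetic coordinates, computes
#' their latent climate gradients from geography, and mixes them into the
#' observed climate variables. The temperature-like first latent spans
#' roughly -18 to 30 degrees Celsius so that any mountain transect generated
#' by [make_region()] is climatically nested within the background.
#'
#' @param config a [world_config()].
#' @return a tibble with columns `id`, `lon`, `lat`, `latent*` (the hidden
#'   gradients, kept for ground-truth checks) and `bio*` (observed climate).
#' @export
make_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  withr::with_seed(config$seed, {
    n <- config$n_background
    d <- config$latent_dim
    p <- config$n_climate_vars
    lon <- runif(n, -180, 180)
    lat <- runif(n, -75, 75)
    lat_mat <- latents_from_geography(lon, lat, d)
    clim <- lat_mat %*% t(config$loading_matrix) +
      matrix(rnorm(n * p, 0, rep(config$noise_sd, each = n)), n, p)
    colnames(clim) <- bio_names(p)
    tibble::tibble(id = seq_len(n), lon = lon, lat = lat) |>
      dplyr::bind_cols(tibble::as_tibble(lat_mat), tibble::as_tibble(clim))
  })
}

#' Configuration of a synthetic mountain region
#'
#' The region emulates a roadside transect: points span
#' `[elev_min, elev_max]` and the temperature-like latent falls with
#' elevation at `lapse_rate` degrees Celsius per km from `base_temp` at the
#' bottom. The elevation-to-climate map is deterministic unless
#' `microclimate_sd > 0`, which jitters each point's temperature to mimic
#' sub-pixel topographic variation.
#'
#' @param elev_min,elev_max elevation span in m a.s.l.
#' @param elev_step optional band spacing in m; when given, one point per
#'   band is generated and `n_points` is ignored.
#' @param lapse_rate temperature lapse in degrees Celsius per km (>= 0).
#' @param base_temp temperature at `elev_min`, degrees Celsius.
#' @param n_points number of evenly spaced regional points.
#' @param latent_position values of the non-temperature latents across the
#'   region (recycled to `latent_dim - 1`).
#' @param microclimate_sd sd (degrees Celsius) of per-point temperature
#'   jitter; 0 for a noiseless map.
#' @param seed seed used only when `microclimate_sd > 0`.
#' @return a `region_config` list.
#' @export
region_config <- function(elev_min = 1900, elev_max = 3600, elev_step = NULL,
                          lapse_rate = 6.1, base_temp = 7, n_points = 2000,
                          latent_position = 0, microclimate_sd = 0, seed = 1) {
  if (elev_min >= elev_max) abort("`elev_min` must be below `elev_max`.")
  if (lapse_rate < 0) abort("`lapse_rate` must be non-negative.")
  if (microclimate_sd < 0) abort("`microclimate_sd` must be non-negative.")
  if (n_points < 2) abort("`n_points` must be at least 2.")
  structure(list(elev_min = elev_min, elev_max = elev_max,
                 elev_step = elev_step, lapse_rate = lapse_rate,
                 base_temp = base_temp, n_points = as.integer(n_points),
                 latent_position = latent_position,
                 microclimate_sd = microclimate_sd, seed = as.integer(seed)),
            class = "region_config")
}

# mean (noiseless) temperature at elevation under a region config
region_temperature <- function(config, elevation) {
  config$base_temp - config$lapse_rate * (elevation - config$elev_min) / 1000
}

#' Generate the synthetic regional environmental space
#'
#' @param config a [region_config()].
#' @param world the [world_config()] whose loading matrix maps latents to
#'   observed climate (no observation noise is added regionally).
#' @return a tibble with `id`, `elevation`, `latent*`, `bio*`.
#' @export
make_region <- function(config, world) {
  stopifnot(inherits(config, "region_config"), inherits(world, "world_config"))
  elev <- if (!is.null(config$elev_step)) {
    seq(config$elev_min, config$elev_max, by = config$elev_step)
  } else {
    seq(config$elev_min, config$elev_max, length.out = config$n_points)
  }
  n <- length(elev)
  d <- world$latent_dim
  l <- matrix(0, n, d)
  l[, 1] <- region_temperature(config, elev)
  if (config$microclimate_sd > 0)
    l[, 1] <- l[, 1] + withr::with_seed(config$seed,
                                        rnorm(n, 0, config$microclimate_sd))
  if (d > 1)
    l[, -1] <- matrix(rep_len(config$latent_position, d - 1), n, d - 1,
                      byrow = TRUE)
  colnames(l) <- latent_names(d)
  clim <- l %*% t(world$loading_matrix)
  colnames(clim) <- bio_names(world$n_climate_vars)
  tibble::tibble(id = seq_len(n), elevation = elev) |>
    dplyr::bind_cols(tibble::as_tibble(l), tibble::as_tibble(clim))
}

#' Define a synthetic species with a Gaussian climatic niche
#'
#' The niche is an axis-aligned Gaussian in latent climate space. Its 99%
#' quantile ellipsoid, intersected with the regional elevation-climate line,
#' gives an analytically known true upper elevational limit
#' (see [true_uel()]). `dispersal_deficit` places the realized survey limit
#' that many metres below the climatic limit, emulating a species not yet at
#' climatic equilibrium.
#'
#' @param name species label.
#' @param niche_center,niche_sd numeric vectors in latent space (length =
#'   `latent_dim`); `niche_sd` must be positive component-wise.
#' @param detection_prob per-plot detection probability in surveys.
#' @param dispersal_deficit metres below the climatic limit at which the
#'   realized limit sits (0 = climatic equilibrium).
#' @return a `synth_species` list.
#' @export
synthetic_species <- function(name, niche_center, niche_sd,
                              detection_prob = 1, dispersal_deficit = 0) {
  if (length(niche_center) != length(niche_sd))
    abort("`niche_center` and `niche_sd` must have the same length.")
  if (any(niche_sd <= 0)) abort("`niche_sd` must be positive component-wise.")
  if (detection_prob < 0 || detection_prob > 1)
    abort("`detection_prob` must lie in [0, 1].")
  structure(list(name = name, niche_center = niche_center,
                 niche_sd = niche_sd, detection_prob = detection_prob,
                 dispersal_deficit = dispersal_deficit),
            class = "synth_species")
}

species_mahalanobis2 <- function(species, latent_mat) {
  z <- sweep(sweep(latent_mat, 2, species$niche_center), 2, species$niche_sd,
             "/")
  rowSums(z^2)
}

#' Analytic true upper elevational limit of a synthetic species
#'
#' The highest elevation whose (noiseless) regional climate lies inside the
#' species' `level` Gaussian quantile ellipsoid in latent space. Because the
#' elevation-to-climate map is deterministic and monotone in temperature,
#' the limit has a closed form: the elevation at which mean temperature
#' falls to the niche's cold bound.
#'
#' @param species a [synthetic_species()].
#' @param region a [region_config()].
#' @param level Gaussian quantile defining the niche ellipsoid.
#' @return a one-row tibble with `species`, `uel` (m a.s.l., `NA` when
#'   absent) and `status` in `"ok"`, `"absent"`, `"unbounded"`.
#' @export
true_uel <- function(species, region, level = 0.99) {
  stopifnot(inherits(species, "synth_species"),
            inherits(region, "region_config"))
  d <- length(species$niche_center)
  q <- qchisq(level, df = d)
  pos <- if (d > 1) rep_len(region$latent_position, d - 1) else numeric(0)
  m_rest <- if (d > 1) {
    sum(((pos - species$niche_center[-1]) / species$niche_sd[-1])^2)
  } else 0
  out <- function(uel, status)
    tibble::tibble(species = species$name, uel = uel, status = status)
  if (m_rest > q) return(out(NA_real_, "absent"))
  half <- species$niche_sd[1] * sqrt(q - m_rest)
  t_lo <- species$niche_center[1] - half
  t_hi <- species$niche_center[1] + half
  t_top <- region_temperature(region, region$elev_max)
  t_bot <- region$base_temp
  if (region$lapse_rate == 0) {
    if (t_bot >= t_lo && t_bot <= t_hi) return(out(region$elev_max, "unbounded"))
    return(out(NA_real_, "absent"))
  }
  if (t_hi < t_top || t_lo > t_bot) return(out(NA_real_, "absent"))
  uel <- region$elev_min + (region$base_temp - t_lo) * 1000 / region$lapse_rate
  if (uel >= region$elev_max) return(out(region$elev_max, "unbounded"))
  out(uel, "ok")
}

#' Sample global occurrence records for a synthetic species
#'
#' Each background point is accepted independently with probability equal to
#' the species' Gaussian suitability at its latent position; if more than
#' `n` points are accepted, `n` are kept at random. Records carry a
#' lognormal synthetic coordinate uncertainty (median 300 m) so the < 1 km
#' occurrence filter removes a seed-stable, nontrivial fraction.
#'
#' @param species a [synthetic_species()].
#' @param background a world tibble from [make_world()].
#' @param n target number of occurrences.
#' @param seed integer seed.
#' @return a tibble of accepted background rows plus `species` and
#'   `coordinate_uncertainty_m`. If fewer than `n` points are achievable a
#'   warning is raised and the shorter set returned (never padded).
#' @export
sample_occurrences <- function(species, background, n, seed = 1) {
  stopifnot(inherits(species, "synth_species"))
  d <- length(species$niche_center)
  lm <- as.matrix(background[latent_names(d)])
  w <- exp(-0.5 * species_mahalanobis2(species, lm))
  withr::with_seed(seed, {
    keep <- which(rbinom(nrow(background), 1, w) == 1)
    if (length(keep) > n) keep <- sort(sample(keep, n))
    if (length(keep) < n)
      warn(sprintf("only %d of %d requested occurrences achievable for '%s'",
                   length(keep), n, species$name))
    unc <- rlnorm(length(keep), meanlog = log(300), sdlog = 1)
  })
  background[keep, ] |>
    dplyr::mutate(species = species$name,
                  coordinate_uncertainty_m = unc, .before = 1)
}

#' Simulate a roadside presence survey over one or more epochs
#'
#' Plots are laid every `plot_step` m along the gradient (either one merged
#' transect or two partially overlapping roads). A species is present in a
#' plot when the plot sits at or below its realized limit (true climatic
#' limit minus `dispersal_deficit`), thinned by its detection probability;
#' the observed UEL per epoch is the highest plot with a detection. Species
#' traits (residence time, dispersal mode, life span) are drawn at random
#' and are independent of the dynamics unless `trait_effect > 0`, which
#' shifts the final epoch's realized limit in proportion to standardized
#' residence time (a power-analysis knob).
#'
#' @param species_list list of [synthetic_species()].
#' @param region a [region_config()].
#' @param epochs number of survey epochs (2 emulates the 2008/2018 design).
#' @param seed integer seed.
#' @param plot_step plot spacing in m.
#' @param layout `"merged"` for a single transect spanning the whole
#'   gradient, `"per_road"` for two roads (the second spanning 2400-3500 m)
#'   with per-species limits taken as the max across roads.
#' @param trait_effect metres of epoch-2 limit shift per standard deviation
#'   of residence time (default 0: traits uninformative).
#' @param level niche quantile passed to [true_uel()].
#' @return a list with tibbles `plots` (plot-by-species detections), `uel`
#'   (observed UEL per species and epoch) and `traits`.
#' @export
make_survey <- function(species_list, region, epochs = 2, seed = 1,
                        plot_step = 100, layout = c("merged", "per_road"),
                        trait_effect = 0, level = 0.99) {
  layout <- match.arg(layout)
  stopifnot(inherits(region, "region_config"))
  roads <- if (layout == "merged") {
    list(road1 = seq(region$elev_min, region$elev_max, by = plot_step))
  } else {
    list(road1 = seq(region$elev_min, region$elev_max, by = plot_step),
         road2 = seq(max(region$elev_min, 2400), min(region$elev_max, 3500),
                     by = plot_step))
  }
  plot_tbl <- purrr::imap_dfr(roads, function(elevs, rd)
    tibble::tibble(road = rd, plot = paste0(rd, "_", seq_along(elevs)),
                   elevation = elevs))
  nm <- purrr::map_chr(species_list, "name")
  withr::with_seed(seed, {
    traits <- tibble::tibble(
      species = nm,
      residence_time = sample(20:120, length(nm), replace = TRUE),
      dispersal_mode = sample(c("wind", "animal", "non-assisted"),
                              length(nm), replace = TRUE),
      life_span = sample(c("annual", "biennial", "perennial"),
                         length(nm), replace = TRUE))
    rt_std <- as.numeric(scale(traits$residence_time))
    if (anyNA(rt_std)) rt_std <- rep(0, length(nm))
    plots <- purrr::map_dfr(seq_along(species_list), function(i) {
      sp <- species_list[[i]]
      tu <- true_uel(sp, region, level = level)
      if (tu$status == "absent") {
        inform(sprintf("species '%s' absent from the region; no detections",
                       sp$name))
        return(NULL)
      }
      realized <- tu$uel - sp$dispersal_deficit
      purrr::map_dfr(seq_len(epochs), function(ep) {
        lim <- realized
        if (ep == epochs && trait_effect > 0)
          lim <- lim + trait_effect * rt_std[i]
        reachable <- plot_tbl$elevation <= lim
        det <- reachable & runif(nrow(plot_tbl)) < sp$detection_prob
        dplyr::mutate(plot_tbl, species = sp$name, epoch = ep, present = det)
      })
    })
  })
  if (nrow(plots) == 0) abort("no species present in the region.")
  years <- if (epochs == 2) c(2008, 2018) else seq_len(epochs)
  plots <- dplyr::mutate(plots, year = years[.data$epoch])
  uel <- plots |>
    dplyr::filter(.data$present) |>
    dplyr::group_by(.data$species, .data$year) |>
    dplyr::summarise(uel_observed = max(.data$elevation), .groups = "drop")
  undetected <- setdiff(nm, unique(uel$species))
  if (length(undetected) > 0)
    inform(paste0("species never detected in survey (excluded downstream): ",
                  paste(undetected, collapse = ", ")))
  list(plots = dplyr::select(plots, "road", "plot", "elevation", "species",
                             "year", "present"),
       uel = uel, traits = traits)
}
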