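#' Parameter-recovery study for the equilibrium classifier
#'
#' Runs the full prediction pipeline on independently generated synthetic
#' worlds with a species of analytically known true upper limit, and
#' classifies two observers against the predicted-limit interval: one at
#' climatic equilibrium (realized limit = true limit, dispersal deficit 0)
#' and one lagging `deficit` metres below it. Reports, per world, the
#' predicted limit with its 95% interval, both classifications, and
#' whether the interval covers the analytic truth.
#'
#' The default conditions are the package's reference study: a 10,000-point
#' background with three latent climate gradients, a 2,000-point regional
#' transect spanning 1900-3600 m with 0.3 degrees C of microclimate
#' scatter, a species with temperature tolerance sd 2 degrees C whose true
#' limit sits at 2800 m, and the 100 x 25% stratified resampler.
#'
#' @param n_worlds number of independent worlds.
#' @param seed master seed; world `w` uses seeds derived as
#'   `seed + 1000 * w + offset`.
#' @param n_background,n_occurrences,n_regional sizes of the background,
#'   occurrence sample (target) and regional transect.
#' @param microclimate_sd per-point temperature jitter in the region
#'   (degrees C).
#' @param niche_sd species tolerance sd per latent dimension (degrees C
#'   for the first).
#' @param true_uel_target elevation (m) at which the species' true upper
#'   limit is placed.
#' @param deficit dispersal deficit (m) of the lagging observer.
#' @param n_reps,frac resampling design.
#' @param grid_R,level niche grid resolution and density level.
#' @return tibble with one row per world: `true_uel`, `mean_ob`, `ci_low`,
#'   `ci_high`, `n_censored`, `class_deficit0`, `class_deficit`, `covered`.
#' @export
equilibrium_recovery_study <- function(n_worlds = 100, seed = 1,
                                       n_background = 10000,
                                       n_occurrences = 2000,
                                       n_regional = 2000,
                                       microclimate_sd = 0.3,
                                       niche_sd = c(2, 1.5, 1.5),
                                       true_uel_target = 2800,
                                       deficit = 500, n_reps = 100,
                                       frac = 0.25, grid_R = 100,
                                       level = 0.99) {
  d <- length(niche_sd)
  purrr::map_dfr(seq_len(n_worlds), function(w) {
    sw <- seed + 1000L * w
    wc <- world_config(n_background = n_background, latent_dim = d,
                       seed = sw)
    world <- make_world(wc)
    rc <- region_config(n_points = n_regional,
                        microclimate_sd = microclimate_sd, seed = sw + 1)
    reg <- make_region(rc, wc)
    t_lo <- region_temperature(rc, true_uel_target)
    center <- c(t_lo + sqrt(qchisq(level, d)) * niche_sd[1], rep(0, d - 1))
    sp <- synthetic_species("focal", center, niche_sd)
    tu <- true_uel(sp, rc, level = level)
    occ <- suppressWarnings(
      sample_occurrences(sp, world, n_occurrences, seed = sw + 2))
    pca <- env_pca(world)
    grid <- build_env_grid(project_env(pca, world),
                           project_env(pca, occ), R = grid_R)
    niche <- delineate_niche(grid, level = level)
    suit <- attach_elevation(
      classify_points(niche, grid, project_env(pca, reg)))
    pa <- make_pa_series(suit)
    pred <- resample_ob(pa, frac = frac, n_reps = n_reps, seed = sw + 3,
                        species = "focal")
    tibble::tibble(
      world = w, true_uel = tu$uel, mean_ob = pred$mean_ob,
      ci_low = pred$ci_low, ci_high = pred$ci_high,
      n_censored = pred$n_censored,
      class_deficit0 = classify_equilibrium(tu$uel, pred)$class,
      class_deficit = classify_equilibrium(tu$uel - deficit, pred)$class,
      covered = !is.na(pred$ci_low) && pred$ci_low <= tu$uel &&
        tu$uel <= pred$ci_high)
  })
}
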