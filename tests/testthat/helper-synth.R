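# small synthetic fixtures shared across test files

tiny_world <- function(seed = 1, n = 1500, d = 2, noise_sd = 0.05) {
  world_config(n_background = n, latent_dim = d, noise_sd = noise_sd,
               seed = seed)
}

# species whose true upper limit sits at `uel` metres under `region`
# (temperature niche bound placed analytically)
species_with_uel <- function(uel, region, sd1 = 2, d = 2, sd_rest = 1.5,
                             name = "sp") {
  t_lo <- region$base_temp -
    region$lapse_rate * (uel - region$elev_min) / 1000
  c1 <- t_lo + sqrt(qchisq(0.99, d)) * sd1
  synthetic_species(name, c(c1, rep(0, d - 1)), c(sd1, rep(sd_rest, d - 1)))
}

# a step presence/absence series: suitable below `edge`, unsuitable above
step_pa <- function(edge = 2800, n = 400, lo = 1900, hi = 3600) {
  elev <- seq(lo, hi, length.out = n)
  tibble::tibble(elevation = elev, presence = as.integer(elev <= edge))
}

# Bernoulli draws from a decreasing model-II response on [lo, hi]
simulate_model2_pa <- function(a = -6, b = 12, n = 400, lo = 1900,
                               hi = 3600, seed = 1) {
  elev <- seq(lo, hi, length.out = n)
  u <- (elev - lo) / (hi - lo)
  p <- 1 / (1 + exp(a + b * u))
  withr::with_seed(seed,
    tibble::tibble(elevation = elev, presence = rbinom(n, 1, p)))
}

# three-species end-to-end fixture shared by the pipeline tests
pipeline_fixture <- function() {
  wc <- world_config(n_background = 3000, latent_dim = 2, seed = 11)
  w <- make_world(wc)
  rc <- region_config(n_points = 800, microclimate_sd = 0.3, seed = 12)
  reg <- make_region(rc, wc)
  sps <- list(species_with_uel(3100, rc, name = "alpha"),
              species_with_uel(2700, rc, name = "beta"),
              species_with_uel(2900, rc, name = "gamma"))
  occ <- purrr::map_dfr(seq_along(sps), function(i)
    suppressWarnings(sample_occurrences(sps[[i]], w, 600, seed = 20 + i)))
  sv <- make_survey(sps, rc, seed = 13, plot_step = 100)
  list(world = w, region = reg, occ = occ, survey = sv)
}

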