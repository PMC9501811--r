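test_that("world generation is a pure function of config and seed", {
  w1 <- make_world(tiny_world(seed = 1, n = 500))
  w2 <- make_world(tiny_world(seed = 1, n = 500))
  w3 <- make_world(tiny_world(seed = 2, n = 500))
  expect_identical(w1, w2)
  expect_false(isTRUE(all.equal(w1$bio01, w3$bio01)))
  expect_equal(nrow(w1), 500)
  expect_error(world_config(n_background = 0), "positive")
  expect_error(world_config(n_climate_vars = 2, latent_dim = 5))
})

test_that("latent structure makes climate variables collinear", {
  w <- make_world(world_config(n_background = 2000, latent_dim = 3,
                               noise_sd = 0.05, seed = 7))
  pv <- prcomp(as.matrix(dplyr::select(w, dplyr::starts_with("bio"))),
               scale. = TRUE)
  expect_gte(sum(pv$sdev[1:3]^2) / sum(pv$sdev^2), 0.95)
  # degenerate: one latent, no noise -> perfect rank correlation
  w0 <- make_world(world_config(n_background = 200, latent_dim = 1,
                                noise_sd = 0, seed = 1))
  cors <- cor(w0$bio01, dplyr::select(w0, dplyr::starts_with("bio")),
              method = "spearman")
  expect_true(all(abs(cors) == 1))
})

test_that("regional transect follows the configured lapse rate", {
  wc <- tiny_world()
  rc <- region_config(elev_min = 2000, elev_max = 3000, lapse_rate = 6.1,
                      n_points = 101)
  reg <- make_region(rc, wc)
  expect_equal(reg$latent1[1] - reg$latent1[101], 6.1, tolerance = 1e-10)
  # lapse 0: climate constant over elevation
  flat <- make_region(region_config(lapse_rate = 0, n_points = 50), wc)
  expect_equal(sd(flat$latent1), 0)
  # banded layout: 1900..3600 by 100 m gives 18 bands
  bands <- make_region(region_config(elev_step = 100), wc)
  expect_equal(nrow(bands), 18)
  expect_error(region_config(elev_min = 3000, elev_max = 2000))
})

test_that("occurrence sampling tracks the niche and the seed", {
  wc <- tiny_world(n = 3000)
  w <- make_world(wc)
  cold <- synthetic_species("cold", c(-5, 0), c(3, 2))
  occ <- suppressWarnings(sample_occurrences(cold, w, 500, seed = 3))
  expect_lt(mean(occ$latent1), mean(w$latent1))
  expect_identical(occ,
                   suppressWarnings(sample_occurrences(cold, w, 500,
                                                       seed = 3)))
  # near-flat suitability accepts essentially everywhere
  vague <- synthetic_species("vague", c(5, 0), c(1e6, 1e6))
  occ2 <- sample_occurrences(vague, w, 3000, seed = 4)
  expect_gt(nrow(occ2), 2900)
  expect_true(all(occ2$coordinate_uncertainty_m > 0))
})

test_that("analytic true limit matches a brute-force scan over the region", {
  wc <- tiny_world()
  rc <- region_config(n_points = 4000)
  reg <- make_region(rc, wc)
  q <- qchisq(0.99, 2)
  withr::with_seed(42, {
    for (i in 1:100) {
      sp <- synthetic_species(paste0("s", i),
                              c(runif(1, -8, 15), runif(1, -2, 2)),
                              c(runif(1, 0.5, 6), runif(1, 0.5, 3)))
      m2 <- (reg$latent1 - sp$niche_center[1])^2 / sp$niche_sd[1]^2 +
        (reg$latent2 - sp$niche_center[2])^2 / sp$niche_sd[2]^2
      inside <- m2 <= q
      tu <- true_uel(sp, rc)
      if (!any(inside)) {
        expect_identical(tu$status, "absent")
      } else {
        scan_uel <- max(reg$elevation[inside])
        if (tu$status == "unbounded") {
          expect_equal(scan_uel, rc$elev_max)
        } else {
          # scan is quantized to the point spacing just below the boundary
          expect_lte(scan_uel, tu$uel + 1e-9)
          expect_gt(scan_uel, tu$uel - diff(range(reg$elevation)) / 4000 - 1e-9)
        }
      }
    }
  })
})

test_that("true limit is monotone as the niche centre warms", {
  rc <- region_config()
  centers <- seq(0, 14, by = 1)
  uels <- vapply(centers, function(c1) {
    tu <- true_uel(synthetic_species("s", c(c1, 0), c(2, 1)), rc)
    if (tu$status == "absent") -Inf else tu$uel
  }, numeric(1))
  expect_true(all(diff(uels[is.finite(uels)]) <= 1e-9))
})

test_that("surveys report the quantized realized limit", {
  wc <- tiny_world()
  rc <- region_config()
  sp <- species_with_uel(3070, rc)
  sv <- make_survey(list(sp), rc, seed = 1)
  # perfect detection, no deficit: observed = highest plot below true limit
  expect_true(all(sv$uel$uel_observed == 3000))
  lag <- synthetic_species("lag", sp$niche_center, sp$niche_sd,
                           dispersal_deficit = 500)
  sv2 <- make_survey(list(lag), rc, seed = 1)
  expect_true(all(sv2$uel$uel_observed == 2500))
  # undetectable species vanish from the survey with a log entry
  ghost <- synthetic_species("ghost", sp$niche_center, sp$niche_sd,
                             detection_prob = 0)
  expect_message(sv3 <- make_survey(list(sp, ghost), rc, seed = 1),
                 "never detected")
  expect_false("ghost" %in% sv3$uel$species)
  expect_setequal(sv3$traits$species, c("sp", "ghost"))
})

test_that("two equal epochs show no systematic limit change", {
  wc <- tiny_world()
  rc <- region_config()
  sp <- species_with_uel(3050, rc)
  sp$detection_prob <- 0.8
  deltas <- vapply(1:200, function(s) {
    uel <- make_survey(list(sp), rc, seed = s)$uel
    if (nrow(uel) < 2) return(NA_real_)
    diff(uel$uel_observed[order(uel$year)])
  }, numeric(1))
  deltas <- deltas[!is.na(deltas)]
  # mean change within Monte-Carlo error of zero
  expect_lt(abs(mean(deltas)), 3 * sd(deltas) / sqrt(length(deltas)) + 1e-9)
})
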