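suit_fixture <- function(seed = 1, uel = 3070, microclimate_sd = 0,
                         n_occ = 800) {
  wc <- tiny_world(seed = seed, n = 4000)
  w <- make_world(wc)
  rc <- region_config(n_points = 1000, microclimate_sd = microclimate_sd,
                      seed = seed + 1)
  reg <- make_region(rc, wc)
  sp <- species_with_uel(uel, rc)
  occ <- suppressWarnings(sample_occurrences(sp, w, n_occ, seed = seed + 2))
  pca <- env_pca(w)
  list(wc = wc, rc = rc, reg = reg, sp = sp,
       bs = project_env(pca, w), os = project_env(pca, occ),
       rs = project_env(pca, reg))
}

test_that("zone partition is exhaustive and exclusive", {
  fx <- suit_fixture()
  g <- build_env_grid(fx$bs, fx$os)
  nr <- delineate_niche(g)
  zones <- classify_points(nr, g, fx$rs)
  expect_equal(nrow(zones), nrow(fx$rs))
  expect_true(all(zones$zone %in% c("A", "B")))
  expect_equal(sum(zones$zone == "A") + sum(zones$zone == "B"), nrow(zones))
  expect_error(classify_points(nr, g, fx$rs[0, ]), "empty")
})

test_that("all-inclusive mask labels every point suitable", {
  fx <- suit_fixture()
  g <- build_env_grid(fx$bs, fx$os)
  nr <- delineate_niche(g, 1)
  nr$mask[] <- TRUE
  zones <- classify_points(nr, g, fx$rs)
  expect_true(all(zones$zone == "A"))
  # points outside the grid ranges are unsuitable by definition
  far <- tibble::tibble(pc1 = c(99, -99), pc2 = c(99, 0))
  expect_true(all(classify_points(nr, g, far)$zone == "B"))
})

test_that("classification agrees with the analytic niche ellipsoid", {
  # plentiful occurrences and a moderate niche keep the estimation error
  # well inside the agreement tolerance, isolating the classification step
  wc <- tiny_world(seed = 3, n = 8000)
  w <- make_world(wc)
  rc <- region_config(n_points = 1000)
  reg <- make_region(rc, wc)
  sp <- species_with_uel(3070, rc, sd1 = 1.2)
  occ <- suppressWarnings(sample_occurrences(sp, w, 1500, seed = 5))
  pca <- env_pca(w)
  fx <- list(reg = reg, sp = sp, bs = project_env(pca, w),
             os = project_env(pca, occ), rs = project_env(pca, reg))
  g <- build_env_grid(fx$bs, fx$os)
  nr <- delineate_niche(g)
  zones <- classify_points(nr, g, fx$rs)
  q <- qchisq(0.99, 2)
  m2 <- (fx$reg$latent1 - fx$sp$niche_center[1])^2 / fx$sp$niche_sd[1]^2 +
    (fx$reg$latent2 - fx$sp$niche_center[2])^2 / fx$sp$niche_sd[2]^2
  truth <- ifelse(m2 <= q, "A", "B")
  expect_gte(mean(zones$zone == truth), 0.95)
})

test_that("a smaller niche region never converts unsuitable to suitable", {
  fx <- suit_fixture(seed = 4)
  g <- build_env_grid(fx$bs, fx$os)
  big <- classify_points(delineate_niche(g, 0.99), g, fx$rs)
  small <- classify_points(delineate_niche(g, 0.90), g, fx$rs)
  expect_false(any(big$zone == "B" & small$zone == "A"))
})

test_that("elevations attach natively or by nearest DEM cell", {
  fx <- suit_fixture()
  g <- build_env_grid(fx$bs, fx$os)
  zones <- classify_points(delineate_niche(g), g,
                           dplyr::bind_cols(fx$rs))
  tab <- attach_elevation(zones)
  expect_identical(tab$elevation, fx$reg$elevation)
  expect_named(tab, c("id", "pc1", "pc2", "zone", "elevation"))
  # flat DEM lookup
  pts <- tibble::tibble(id = 1:3, lon = c(0.1, 0.5, 0.9),
                        lat = c(0.2, 0.5, 0.8), zone = "A")
  dem <- list(x = seq(0, 1, 0.25), y = seq(0, 1, 0.25),
              z = matrix(2500, 5, 5))
  expect_true(all(attach_elevation(pts, dem)$elevation == 2500))
  bad <- dplyr::mutate(pts, lon = lon + 10)
  expect_error(attach_elevation(bad, dem), "outside DEM")
})

test_that("presence/absence series conserve and order the points", {
  fx <- suit_fixture()
  g <- build_env_grid(fx$bs, fx$os)
  tab <- attach_elevation(classify_points(delineate_niche(g), g, fx$rs))
  pa <- make_pa_series(tab)
  expect_equal(nrow(pa), nrow(tab))
  expect_equal(sum(pa$presence) + sum(1 - pa$presence), nrow(tab))
  expect_true(!is.unsorted(pa$elevation))
  # a step-like truth: suitable low, unsuitable high
  expect_gt(mean(pa$presence[pa$elevation < 2500]), 0.9)
  expect_lt(mean(pa$presence[pa$elevation > 3400]), 0.1)
  # degenerate series are flagged, not dropped
  all_a <- tibble::tibble(zone = rep("A", 5), elevation = 1:5)
  expect_message(pa_a <- make_pa_series(all_a), "no upper contrast")
  expect_identical(attr(pa_a, "flag"), "no_upper_contrast")
  all_b <- tibble::tibble(zone = rep("B", 5), elevation = 1:5)
  expect_message(pa_b <- make_pa_series(all_b), "no ")
  expect_identical(attr(pa_b, "flag"), "no_presences")
})
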