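test_that("rank-sum test matches enumeration, ties and degeneracies", {
  # identical vectors of length 22: expectation-centred W, p = 1
  x <- rep(2500, 22)
  res <- wilcoxon_uel(x, x)
  expect_equal(res$statistic, 22^2 / 2)
  expect_equal(res$p_value, 1)
  # agreement with stats::wilcox.test exact p on tie-free data
  withr::with_seed(31, {
    for (rep in 1:10) {
      a <- rnorm(7)
      b <- rnorm(9, 0.5)
      ours <- wilcoxon_uel(a, b)
      ref <- stats::wilcox.test(a, b, exact = TRUE)
      expect_equal(ours$statistic, unname(ref$statistic))
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    }
  })
  # normal approximation close to the exact null at n = 10
  withr::with_seed(32, {
    for (rep in 1:10) {
      a <- rnorm(10)
      b <- rnorm(10, 0.3)
      exact <- wilcoxon_uel(a, b, exact_n_max = 10)
      approx <- wilcoxon_uel(a, b, exact_n_max = 0)
      expect_lt(abs(exact$p_value - approx$p_value), 0.02)
    }
  })
})

test_that("signed-rank test matches enumeration on shifted pairs", {
  # all deltas +100, n = 6: only the all-positive pattern is as extreme
  a <- c(2100, 2300, 2500, 2700, 2900, 3100)
  res <- wilcoxon_uel(a + 100, a, paired = TRUE, alternative = "greater")
  expect_equal(res$p_value, 1 / 64)
  # two-sided doubles the tail
  res2 <- wilcoxon_uel(a + 100, a, paired = TRUE)
  expect_equal(res2$p_value, 2 / 64)
  # all-zero differences: warned, p = 1
  expect_warning(res3 <- wilcoxon_uel(a, a, paired = TRUE), "zero")
  expect_equal(res3$p_value, 1)
  # agreement with stats::wilcox.test on tie-free pairs
  withr::with_seed(33, {
    for (rep in 1:10) {
      d1 <- rnorm(8)
      d2 <- rnorm(8, 0.4)
      ours <- wilcoxon_uel(d1, d2, paired = TRUE)
      ref <- stats::wilcox.test(d1, d2, paired = TRUE, exact = TRUE)
      expect_equal(ours$statistic, unname(ref$statistic))
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("temporal change classes respect the stability threshold", {
  d <- tibble::tibble(species = c("a", "b", "c", "d"),
                      uel_2008 = c(2500, 2500, 2500, NA),
                      uel_2018 = c(2500, 2425, 2700, 2600))
  expect_message(rec <- classify_change(d), "missing an epoch")
  expect_equal(rec$change_class, c("stable", "down", "up"))
  expect_equal(rec$delta, c(0, -75, 200))
  rec2 <- suppressMessages(classify_change(d, stability_threshold = 100))
  expect_equal(rec2$change_class, c("stable", "stable", "up"))
  # cohort of 22 with 5 up / 9 down / 8 stable
  cohort <- tibble::tibble(
    species = paste0("s", 1:22),
    uel_2008 = rep(2500, 22),
    uel_2018 = 2500 + c(rep(250, 5), rep(-200, 9), rep(0, 8)))
  s <- change_summary(classify_change(cohort))
  expect_equal(s$pct[s$change_class == "up"], 23)
  expect_equal(s$pct[s$change_class == "down"], 41)
  expect_equal(s$pct[s$change_class == "stable"], 36)
})

test_that("observed~predicted regression matches the normal equations", {
  withr::with_seed(34, {
    d <- tibble::tibble(uel_predicted = runif(20, 2500, 3500))
    d$uel_observed <- 400 + 0.6 * d$uel_predicted + rnorm(20, 0, 80)
  })
  fit <- regress_obs_pred(d)
  X <- cbind(1, d$uel_predicted)
  beta <- solve(t(X) %*% X, t(X) %*% d$uel_observed)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-8)
  expect_equal(fit$slope, beta[2], tolerance = 1e-8)
  expect_equal(fit$df, 18)
  # identity data: slope 1, r2 1, slope-vs-1 statistic 0
  ident <- tibble::tibble(uel_predicted = seq(2000, 3000, 100))
  ident$uel_observed <- ident$uel_predicted
  fid <- suppressWarnings(regress_obs_pred(ident))
  expect_equal(fid$slope, 1, tolerance = 1e-12)
  expect_equal(fid$r2, 1, tolerance = 1e-12)
  expect_equal(fid$t_slope1, 0, tolerance = 1e-6)
  expect_error(regress_obs_pred(
    tibble::tibble(uel_predicted = rep(3000, 5),
                   uel_observed = rnorm(5))), "zero variance")
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "slope_vs_1"], 1 - fit$slope)
  expect_equal(glance(fit)$r2, fit$r2)
})

test_that("trait ANOVA uses sequential sums of squares with Df 1/2/2", {
  withr::with_seed(35, {
    d <- tibble::tibble(
      residence_time = sample(20:120, 22, replace = TRUE),
      dispersal_mode = sample(c("wind", "animal", "non-assisted"), 22,
                              replace = TRUE),
      life_span = sample(c("annual", "biennial", "perennial"), 22,
                         replace = TRUE),
      delta = rnorm(22))
  })
  tab <- trait_model(d, response = delta)
  expect_equal(tab$term, c("residence_time", "dispersal_mode", "life_span",
                           "Residuals"))
  expect_equal(tab$df[1:3], c(1, 2, 2))
  # sequential terms partition the total sum of squares
  expect_equal(sum(tab$sumsq), sum((d$delta - mean(d$delta))^2),
               tolerance = 1e-8)
  # a response perfectly explained by residence time
  d2 <- d
  d2$delta <- 10 * d2$residence_time
  tab2 <- suppressWarnings(trait_model(d2, response = delta))
  expect_lt(tab2$sumsq[tab2$term == "Residuals"], 1e-12 * sum(tab2$sumsq))
  # single-level factor is dropped with a warning
  d3 <- d
  d3$life_span <- "perennial"
  expect_warning(tab3 <- trait_model(d3, response = delta), "single level")
  expect_false("life_span" %in% tab3$term)
  # type-II variant reports the same terms with the same residual row
  tab4 <- trait_model(d, response = delta, type = "type2")
  expect_setequal(tab4$term, tab$term)
  expect_equal(tab4$sumsq[tab4$term == "Residuals"],
               tab$sumsq[tab$term == "Residuals"], tolerance = 1e-8)
})

test_that("standardized delta is a scale-free ratio", {
  expect_equal(standardized_delta(3000, 3000), 0)
  expect_equal(standardized_delta(2400, 3000), 0.2)
  expect_equal(standardized_delta(2.4, 3), 0.2)
  expect_error(standardized_delta(2400, 0), "positive")
})
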