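test_that("response curves match their closed forms and the oracle", {
  u <- seq(-0.2, 1.2, length.out = 101)
  # model I at a = 0 is flat at one half
  expect_equal(hof_curve(1, 0, u), rep(0.5, 101))
  # model II with positive slope is strictly decreasing
  y2 <- hof_curve(2, c(-4, 9), u)
  expect_true(all(diff(y2) < 0))
  # model IV with a = c peaks at u = 0 on a symmetric gradient
  ug <- seq(-0.5, 0.5, length.out = 401)
  y4 <- hof_curve(4, c(-2, 14, -2), ug)
  expect_equal(ug[which.max(y4)], 0, tolerance = 0.005)
  # all seven types agree with the independent reference implementation
  withr::with_seed(21, {
    for (tp in 1:7) {
      for (rep in 1:20) {
        p <- oracle_random_params(tp)
        expect_equal(hof_curve(tp, p, u), oracle_hof_response(tp, p, u),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("responses stay within [0, 1] for random parameters", {
  u <- seq(-0.5, 1.5, length.out = 201)
  withr::with_seed(22, {
    for (tp in 1:7) {
      for (rep in 1:50) {
        y <- hof_curve(tp, oracle_random_params(tp), u)
        expect_true(all(y >= 0 & y <= 1))
      }
    }
  })
})

test_that("negative log-likelihood matches the brute-force sum", {
  pa <- simulate_model2_pa(n = 60, seed = 2)
  u <- (pa$elevation - 1900) / 1700
  # closed form: flat model at one half scores n log 2
  expect_equal(hof_negloglik(1, 0, pa), 60 * log(2), tolerance = 1e-12)
  withr::with_seed(23, {
    for (tp in 1:7) {
      for (rep in 1:30) {
        p <- oracle_random_params(tp)
        expect_equal(hof_negloglik(tp, p, pa),
                     oracle_nll(tp, p, u, pa$presence), tolerance = 1e-10)
      }
    }
  })
})

test_that("model II fits recover known simulation parameters", {
  pa <- simulate_model2_pa(a = -6, b = 12, n = 400, seed = 5)
  fit <- fit_hof(pa, 2, seed = 1)
  # inflection: u = -a/b = 0.5 -> 2750 m; within 5% of the gradient span
  infl <- 1900 + (-fit$params["a"] / fit$params["b"]) * 1700
  expect_lt(abs(infl - 2750), 0.05 * 1700)
  # determinism under the seed
  fit2 <- fit_hof(pa, 2, seed = 1)
  expect_identical(fit$params, fit2$params)
  fit3 <- fit_hof(pa, 2, seed = 99)
  expect_equal(fit$logL, fit3$logL, tolerance = 1e-4)
})

test_that("degenerate and unfittable series are handled explicitly", {
  all1 <- tibble::tibble(elevation = seq(2000, 3000, 100),
                         presence = 1L)
  fit <- fit_hof(all1, 4)
  expect_identical(fit$model, "I")
  expect_identical(fit$degenerate, "all_ones")
  expect_gt(hof_response(fit, 2500), 0.999)
  sparse <- tibble::tibble(elevation = seq(2000, 3000, 100),
                           presence = c(1L, 1L, rep(0L, 9)))
  expect_error(fit_hof(sparse, 2), class = "uelshift_unfittable")
})

test_that("AIC selection returns the family minimum, ties to simplicity", {
  pa <- step_pa(n = 200)
  sel <- select_hof(pa, seed = 3)
  expect_true(sel$model %in% c("II", "III", "V"))
  expect_equal(sel$AIC, min(sel$aic_table$AIC))
  expect_equal(sel$AIC, 2 * sel$k - 2 * sel$logL)
  # i.i.d. coin-flip series: the flat model wins in the clear majority
  # (the non-flat shapes act as maximally selected change-point
  # statistics, so some spurious wins are inherent to ML + AIC)
  flat_wins <- sum(vapply(1:100, function(s) {
    pa0 <- withr::with_seed(s * 7 + 400, tibble::tibble(
      elevation = seq(1900, 3600, length.out = 400),
      presence = rbinom(400, 1, 0.5)))
    select_hof(pa0, seed = s)$model == "I"
  }, logical(1)))
  expect_gte(flat_wins, 70)
})

test_that("outer border sits at exp(-2) of the maximum response", {
  pa <- simulate_model2_pa(a = -6, b = 12, n = 400, seed = 6)
  fit <- fit_hof(pa, 2, seed = 1)
  ob <- outer_border(fit)
  expect_false(ob$censored)
  expect_equal(hof_response(fit, ob$ob) / ob$y_max, exp(-2),
               tolerance = 1e-3)
  # closed-form inversion for the fitted parameters
  u_star <- oracle_model2_ob_u(unname(fit$params["a"]),
                               unname(fit$params["b"]))
  expect_equal(ob$ob, 1900 + u_star * 1700, tolerance = 0.2)
  # flat model never crosses the threshold: censored at the top
  flat <- fit_hof(tibble::tibble(elevation = seq(2000, 3000, 50),
                                 presence = rep(c(1L, 0L), length.out = 21)),
                  1)
  obf <- outer_border(flat)
  expect_true(obf$censored)
  expect_equal(obf$ob, 3000)
})

test_that("outer border is monotone under thinning of low absences", {
  elev <- seq(1900, 3600, length.out = 300)
  pa <- tibble::tibble(elevation = elev,
                       presence = as.integer(elev >= 2300 & elev <= 2800))
  fit <- fit_hof(pa, 5, seed = 2)
  ob_full <- outer_border(fit)$ob
  thinned <- pa[!(pa$presence == 0 & pa$elevation < 2300), ]
  refit <- fit_hof(thinned, 5, seed = 2, warm_starts = fit$params)
  ob_thin <- outer_border(refit)$ob
  # the refit may sharpen the descent (absences below the presence band no
  # longer constrain it), tightening the border toward the data edge by at
  # most the full fit's descent width 2/b * span, but never beyond it
  descent_width <- 2 / unname(fit$params["b"]) * diff(fit$x_scaling)
  expect_gte(ob_thin, ob_full - descent_width - 1)
})
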