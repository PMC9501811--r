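# Independent reference implementations used as oracles. Written directly
# from the model formulas in plain R, deliberately sharing no code with the
# package internals.

oracle_sigmoid <- function(t) 1 / (1 + exp(t))

oracle_hump <- function(u, a, b, c, d) {
  oracle_sigmoid(a + b * u) * oracle_sigmoid(c - d * u)
}

oracle_hof_response <- function(type, p, u) {
  y <- switch(type,
    rep(oracle_sigmoid(p[1]), length(u)),
    oracle_sigmoid(p[1] + p[2] * u),
    oracle_sigmoid(p[1] + p[2] * u) * oracle_sigmoid(p[3]),
    oracle_hump(u, p[1], p[2], p[3], p[2]),
    oracle_hump(u, p[1], p[2], p[3], p[4]),
    oracle_hump(u, p[1], p[2], p[3], p[2]) +
      oracle_hump(u - p[4], p[1], p[2], p[3], p[2]),
    oracle_hump(u, p[1], p[2], p[3], p[2]) +
      p[5] * oracle_hump(u - p[4], p[1], p[2], p[3], p[2]))
  pmin(pmax(y, 0), 1)
}

# brute-force per-observation Bernoulli negative log-likelihood
oracle_nll <- function(type, p, u, y, eps = 1e-9) {
  total <- 0
  for (i in seq_along(u)) {
    pr <- oracle_hof_response(type, p, u[i])
    pr <- min(max(pr, eps), 1 - eps)
    total <- total - (y[i] * log(pr) + (1 - y[i]) * log(1 - pr))
  }
  total
}

# random admissible parameter vector for a model type
oracle_random_params <- function(type) {
  k <- c(1, 2, 3, 3, 4, 4, 5)[type]
  nm <- list("a", c("a", "b"), c("a", "b", "c"), c("a", "b", "c"),
             c("a", "b", "c", "d"), c("a", "b", "c", "f"),
             c("a", "b", "c", "f", "r"))[[type]]
  unname(vapply(nm, function(p) switch(p,
    a = runif(1, -25, 25), b = runif(1, 0.01, 200),
    c = runif(1, -25, 25), d = runif(1, 0.01, 200),
    f = runif(1, 0, 1), r = runif(1, 0, 1)), numeric(1)))
}

# closed-form outer border of a decreasing model II on the scaled gradient:
# solve 1/(1+e^(a+bu)) = exp(-2) * y_max with y_max = 1/(1+e^a)
oracle_model2_ob_u <- function(a, b) {
  (log((1 + exp(a)) * exp(2) - 1) - a) / b
}
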