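test_that("marginal_loglik matches exact Gaussian densities", {
  # single observation, gamma 0: plain normal density at zero residual,
  # -log(sqrt(2 pi) * 0.1)
  o1 <- make_obs(0.5, 0.1)
  expect_equal(marginal_loglik(0.5, 0, o1), -log(sqrt(2 * pi) * 0.1))

  # gamma = 0 reduces to the independent weighted-least-squares loglik
  set.seed(11)
  o <- make_obs(rnorm(8), runif(8, 0.1, 0.5), study = c(1, 1, 2, 3, 3, 3, 4, 5))
  beta <- 0.2
  expect_equal(marginal_loglik(beta, 0, o),
    sum(dnorm(o$log_effect, beta, o$log_se, log = TRUE)))

  # random multi-observation blocks against a dense MVN oracle
  for (gamma in c(0.02, 0.3)) {
    expect_equal(marginal_loglik(beta, gamma, o),
      dense_mvn_loglik(beta, gamma, o))
  }

  # invariant to observation order and study relabeling
  perm <- sample(nrow(o))
  operm <- o[perm, ]
  expect_equal(marginal_loglik(beta, 0.1, operm),
    marginal_loglik(beta, 0.1, o))
  orel <- o
  orel$study_id <- chartr("12345", "zyxwv", orel$study_id)
  expect_equal(marginal_loglik(beta, 0.1, orel),
    marginal_loglik(beta, 0.1, o))

  expect_error(marginal_loglik(0, -0.1, o), "non-negative")
  expect_error(marginal_loglik(0, 0.1, o, weights = rep(0, nrow(o))),
    "no observations")
})

test_that("fit recovers the trivial and two-study closed forms", {
  o1 <- make_obs(0.5, 0.1)
  f1 <- suppressWarnings(fit_model(o1))
  expect_equal(f1$beta0, 0.5)
  expect_equal(f1$gamma_hat, 0)
  expect_equal(f1$se_beta0, 0.1)

  # two studies, equal s, y in {0, 1}: beta0 = 1/2 and the ML solution for
  # gamma is mean squared residual minus s^2 (grid-search oracle)
  o2 <- make_obs(c(0, 1), c(0.2, 0.2))
  f2 <- fit_model(o2)
  expect_equal(f2$beta0, 0.5)
  grid <- seq(0, 2, by = 1e-4)
  ll <- vapply(grid, function(g) marginal_loglik(0.5, g, o2), numeric(1))
  expect_equal(f2$gamma_hat, grid[which.max(ll)], tolerance = 1e-3)
  expect_equal(f2$gamma_hat, 0.25 - 0.2^2, tolerance = 1e-6)
})

test_that("gamma fixed at 0 gives the inverse-variance weighted mean", {
  set.seed(21)
  o <- make_obs(rnorm(9, 0.4, 0.3), runif(9, 0.05, 0.5))
  f <- fit_model(o, gamma_fixed = 0)
  w <- 1 / o$log_se^2
  expect_equal(f$beta0, sum(w * o$log_effect) / sum(w))
  expect_equal(f$se_beta0, 1 / sqrt(sum(w)))
})

test_that("fit is equivariant under constant shifts of y", {
  set.seed(31)
  o <- make_obs(rnorm(12, 0.2, 0.4), runif(12, 0.1, 0.5),
    study = rep(1:6, each = 2))
  f <- fit_model(o)
  oc <- o
  oc$log_effect <- oc$log_effect + 1.3
  oc$effect <- exp(oc$log_effect)
  oc$ci_lower <- oc$ci_lower * exp(1.3)
  oc$ci_upper <- oc$ci_upper * exp(1.3)
  fc <- fit_model(oc)
  expect_equal(fc$beta0, f$beta0 + 1.3, tolerance = 1e-6)
  expect_equal(fc$gamma_hat, f$gamma_hat, tolerance = 1e-6)
  expect_equal(fc$se_beta0, f$se_beta0, tolerance = 1e-8)
})

test_that("single-study sets return gamma 0 with a warning", {
  o <- make_obs(c(0.1, 0.3), c(0.1, 0.1), study = c(1, 1))
  expect_warning(f <- fit_model(o), "not identifiable")
  expect_equal(f$gamma_hat, 0)
})

test_that("LTS trims the gross outlier and spares small models", {
  set.seed(41)
  y <- c(rnorm(11, 0, 0.05), 10)
  o <- make_obs(y, rep(0.1, 12))
  w <- lts_trim(o, 0.1)
  expect_equal(sum(w), 11)
  expect_equal(unname(w[12]), 0)

  # n = 10: ineligible, all weights 1
  o10 <- make_obs(c(rnorm(9, 0, 0.05), 10), rep(0.1, 10))
  expect_message(w10 <- lts_trim(o10, 0.1), "skipped")
  expect_true(all(w10 == 1))

  f <- fit_model(o10, trim_fraction = 0.1) |> suppressMessages()
  expect_true(all(f$trim_weights == 1))
})

test_that("LTS matches exhaustive subset enumeration at n = 12", {
  # independent oracle: refit every C(12, 11) subset and score the trimmed
  # SSR of standardized residuals
  for (seed in c(7, 19, 33)) {
    set.seed(seed)
    o <- make_obs(rnorm(12, 0.3, 0.6), runif(12, 0.1, 0.4))
    h <- ceiling(0.9 * 12)
    subsets <- utils::combn(12, h)
    score <- apply(subsets, 2, function(idx) {
      f <- fit_model(o[idx, ], gamma_fixed = NULL)
      r2 <- (o$log_effect[idx] - f$beta0)^2 /
        (o$log_se[idx]^2 + f$gamma_hat)
      sum(r2)
    })
    best <- sort(subsets[, which.min(score)])
    w <- lts_trim(o, 0.1)
    expect_identical(unname(which(w == 1)), best)
  }
})

test_that("print method summarizes a fit", {
  o <- make_obs(c(0, 1), c(0.2, 0.2))
  expect_output(print(fit_model(o)), "pooled log RR")
})
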