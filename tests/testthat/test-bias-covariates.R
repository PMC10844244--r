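test_that("covariate registry construction and validation", {
  reg <- default_covariate_registry()
  expect_length(reg, 10L)
  expect_true(all(vapply(reg, inherits, logical(1), "bop_covariate")))
  expect_identical(reg$cv_adjusted_smoking_age_sex$cascade_parent,
    "cv_adjusted_age_sex")

  expect_error(bias_covariate("x", gold_standard_value = 2), "0 or 1")
  expect_error(bias_covariate("x", prior_sd = 0), "positive")

  # JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    cv_a = list(gold_standard_value = 1, prior_sd = 0.5),
    cv_b = list(gold_standard_value = 0, cascade_parent = "cv_a")
  ), path, auto_unbox = TRUE)
  reg2 <- read_covariate_registry(path)
  expect_identical(reg2$cv_a$prior_sd, 0.5)
  expect_identical(reg2$cv_b$cascade_parent, "cv_a")
})

test_that("eligibility needs two observations per level", {
  o <- make_obs(rnorm(4), rep(0.2, 4), cv_x = c(0, 0, 1, 1))
  expect_true(covariate_eligibility("cv_x", o))
  o2 <- make_obs(rnorm(4), rep(0.2, 4), cv_x = c(0, 0, 0, 1))
  expect_false(covariate_eligibility("cv_x", o2))
  o3 <- make_obs(rnorm(4), rep(0.2, 4), cv_x = rep(0, 4))
  expect_false(covariate_eligibility("cv_x", o3))
  expect_error(covariate_eligibility("cv_missing", o), "not present")
})

test_that("selection keeps a strong bias covariate (50 replicates)", {
  hits <- vapply(1:50, function(r) {
    sim <- simulate_observations(sim_config(
      n_studies = 40, true_beta0 = log(2), gamma = 0,
      covariate_effects = c(cv_shift = 0.8),
      se_range = c(0.12, 0.18), seed = 3000 + r))
    sel <- select_bias_covariates(sim$observations,
      list(cv_shift = bias_covariate("cv_shift")))
    "cv_shift" %in% sel$selected
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("selection rarely fires under the null (200 replicates)", {
  cands <- stats::setNames(
    lapply(sprintf("cv_c%02d", 1:10), bias_covariate),
    sprintf("cv_c%02d", 1:10))
  prev <- stats::setNames(rep(0.5, 10), names(cands))
  n_sel <- matrix(FALSE, 200, 10, dimnames = list(NULL, names(cands)))
  for (r in 1:200) {
    sim <- simulate_observations(sim_config(
      n_studies = 40, true_beta0 = log(2), gamma = 0,
      covariate_effects = stats::setNames(rep(0, 10), names(cands)),
      covariate_prevalence = prev, seed = 4000 + r))
    sel <- select_bias_covariates(sim$observations, cands)
    n_sel[r, sel$selected] <- TRUE
  }
  expect_true(all(colMeans(n_sel) <= 0.10))
})

test_that("degenerate candidate sets", {
  expect_identical(
    select_bias_covariates(make_obs(rnorm(5), rep(0.2, 5)), list())$selected,
    character())
  # constant columns: nothing eligible, fit reduces to covariate-free model
  o <- make_obs(rnorm(12, 0.3, 0.2), rep(0.2, 12), cv_const = 0L)
  sel <- select_bias_covariates(o,
    list(cv_const = bias_covariate("cv_const")))
  expect_identical(sel$selected, character())
  expect_identical(sel$eligible, character())
  f0 <- fit_model(o)
  f1 <- fit_model(o, covariates = sel$selected)
  expect_equal(f1$beta0, f0$beta0)
  expect_equal(f1$loglik, f0$loglik)
})

test_that("cascade children are dropped without their parent", {
  # child column strongly predictive, parent pure noise: the child alone
  # passes the z-test but the cascade rule removes it
  set.seed(55)
  sim <- simulate_observations(sim_config(
    n_studies = 40, true_beta0 = log(2), gamma = 0,
    covariate_effects = c(cv_parent = 0, cv_child = 0.9),
    se_range = c(0.12, 0.18), seed = 555))
  cands <- list(
    cv_parent = bias_covariate("cv_parent"),
    cv_child = bias_covariate("cv_child", cascade_parent = "cv_parent"))
  sel <- select_bias_covariates(sim$observations, cands)
  expect_false("cv_child" %in% sel$selected)
  # without the cascade constraint the child is selected
  sel2 <- select_bias_covariates(sim$observations,
    list(cv_child = bias_covariate("cv_child")))
  expect_true("cv_child" %in% sel2$selected)
})

test_that("selection is invariant to observation order", {
  sim <- simulate_observations(sim_config(
    n_studies = 30, true_beta0 = log(2), gamma = 0.05,
    covariate_effects = c(cv_a = 0.7, cv_b = 0), seed = 66))
  cands <- list(cv_a = bias_covariate("cv_a"),
    cv_b = bias_covariate("cv_b"))
  s1 <- select_bias_covariates(sim$observations, cands)
  set.seed(1)
  s2 <- select_bias_covariates(
    sim$observations[sample(nrow(sim$observations)), ], cands)
  expect_identical(s1$selected, s2$selected)
})

test_that("gold-standard adjustment shifts observations correctly", {
  o <- make_obs(c(0.2, 0.9, 0.3, 1.0), rep(0.1, 4), cv_x = c(0, 1, 0, 1))
  fit <- fit_model(o, covariates = "cv_x", gamma_fixed = 0)
  cv <- bias_covariate("cv_x", gold_standard_value = 0)
  adj <- apply_bias_adjustment(o, fit, list(cv))
  # gold-standard rows unchanged, flagged rows shifted by -beta_cov
  expect_equal(adj$log_effect[c(1, 3)], o$log_effect[c(1, 3)])
  expect_equal(adj$log_effect[c(2, 4)],
    o$log_effect[c(2, 4)] - fit$beta_cov[["cv_x"]])
  expect_equal(adj$effect, exp(adj$log_effect))

  # direct formula: x = 1, gold 0, coefficient 0.3 -> decrease by 0.3
  fit2 <- fit
  fit2$beta_cov <- c(cv_x = 0.3)
  adj2 <- apply_bias_adjustment(o, fit2, list(cv))
  expect_equal(adj2$log_effect[2], o$log_effect[2] - 0.3)

  # self-consistency: after adjustment the refitted coefficient is ~0
  sim <- simulate_observations(sim_config(
    n_studies = 40, true_beta0 = log(2), gamma = 0.05,
    covariate_effects = c(cv_x = 0.6), seed = 77))
  f <- fit_model(sim$observations, covariates = "cv_x")
  a <- apply_bias_adjustment(sim$observations, f,
    list(bias_covariate("cv_x")))
  fa <- fit_model(a, covariates = "cv_x")
  se_cv <- sqrt(fa$cov_beta["cv_x", "cv_x"])
  expect_lt(abs(fa$beta_cov[["cv_x"]]), 2 * se_cv)

  expect_error(apply_bias_adjustment(o, fit_model(o),
    list(cv)), "lacks coefficients")
})
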