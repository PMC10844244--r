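# In-code fixtures shared by the suite.

# Minimal observation set from log-scale inputs.
make_obs <- function(y, s, study = seq_along(y),
                     obs_id = sprintf("o%03d", seq_along(y)), ...) {
  harmonize_observations(data.frame(
    obs_id = obs_id,
    study_id = sprintf("s%03d", study),
    log_effect = y, log_se = s, ...,
    stringsAsFactors = FALSE))
}

# A small well-formed ratio-scale table exercising the full CSV schema.
make_schema_table <- function() {
  data.frame(
    obs_id = c("a1", "a2", "b1", "c1"),
    study_id = c("sA", "sA", "sB", "sC"),
    measure = c("OR", "OR", "RR", "HR"),
    effect = c(1.5, 1.8, 1.2, 2.2),
    ci_lower = c(1.1, 1.2, 0.9, 1.4),
    ci_upper = c(2.05, 2.7, 1.6, 3.46),
    overlap_group = c("gA", "gA", NA, NA),
    sex = c("both", "male", "both", "female"),
    exposure_definition = c("chewing tobacco", "gutkha",
      "betel quid with tobacco", "chewing tobacco"),
    exposure_temporality = c("current", "ever", "current", "unspecified"),
    outcome_aggregate = c(0L, 0L, 1L, 0L),
    sample_size = c(430596L, 430596L, 160L, 1200L),
    design = c("case_control", "case_control", "case_control",
      "prospective_cohort"),
    cv_maximally_adjusted = c(1L, 0L, 0L, 1L),
    cv_aggregate_outcome = c(0L, 0L, 1L, 0L),
    stringsAsFactors = FALSE
  )
}

# The published per-outcome summary numbers used by desk-scale checks.
published_fixture <- function() published_estimates()

# Dense multivariate-normal marginal log-likelihood (independent oracle,
# no Woodbury): block covariance diag(s^2) + gamma * J per study.
dense_mvn_loglik <- function(beta, gamma, obs, covariates = character()) {
  X <- cbind(1, as.matrix(as.data.frame(obs)[, covariates, drop = FALSE]))
  mu <- drop(X %*% beta)
  ll <- 0
  for (st in unique(obs$study_id)) {
    i <- obs$study_id == st
    V <- diag(obs$log_se[i]^2, sum(i)) + gamma
    r <- obs$log_effect[i] - mu[i]
    ll <- ll - 0.5 * (sum(i) * log(2 * pi) +
      as.numeric(determinant(V)$modulus) +
      drop(t(r) %*% solve(V, r)))
  }
  ll
}
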