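#' Synthetic observation sets with known truth
#'
#' Emulates the structure of extracted case-control / cohort effect sizes:
#' study-level true log relative risks drawn around a global mean with
#' between-study variance gamma, observation-level sampling noise at
#' log-uniform standard errors spanning the precision range of real
#' studies, binary bias-covariate shifts, non-mutually-exclusive
#' overlapping observations within a study, gross outliers, and optional
#' significance-based selective reporting (censoring). Every set is
#' reproducible bit-exactly from its configuration and seed.
#'
#' @name synthetic_data
#' @keywords internal
NULL

#' Simulation configuration
#'
#' @param n_studies number of studies.
#' @param obs_per_study observations per study: a single count, a
#'   `c(lo, hi)` range sampled uniformly, or an explicit vector of length
#'   `n_studies`.
#' @param true_beta0 true pooled mean log RR.
#' @param gamma true between-study variance.
#' @param covariate_effects named vector of true log-RR shifts per `cv_`
#'   covariate (NULL for none).
#' @param covariate_prevalence named vector of Bernoulli prevalences, same
#'   names; defaults to 0.5 for each effect.
#' @param se_range `(low, high)` bounds of the log-uniform SE draw.
#'   Default (0.05, 0.6), spanning precisions from very large cohorts to
#'   small case-control studies.
#' @param overlap_fraction share of studies emitting k > 1 overlapping
#'   observations (one shared overlap group per such study).
#' @param outlier_fraction share of observations shifted by
#'   `outlier_shift`.
#' @param outlier_shift gross-outlier shift on the log scale.
#' @param censor_nonsignificant_prob probability that a non-significant
#'   observation (|y|/s < 1.96) is dropped (selective reporting).
#' @param seed integer seed; the generator draws all randomness from it.
#' @return list of class `bop_sim_config`.
#' @export
sim_config <- function(n_studies = 50L, obs_per_study = 1L,
                       true_beta0 = log(2), gamma = 0.1,
                       covariate_effects = NULL,
                       covariate_prevalence = NULL,
                       se_range = c(0.05, 0.6),
                       overlap_fraction = 0, outlier_fraction = 0,
                       outlier_shift = 0,
                       censor_nonsignificant_prob = 0, seed = 1L) {
  stopifnot(
    n_studies >= 1, gamma >= 0,
    length(se_range) == 2, all(se_range > 0), se_range[1] <= se_range[2],
    overlap_fraction >= 0, overlap_fraction <= 1,
    outlier_fraction >= 0, outlier_fraction <= 1,
    censor_nonsignificant_prob >= 0, censor_nonsignificant_prob <= 1
  )
  if (!is.null(covariate_effects) && is.null(covariate_prevalence)) {
    covariate_prevalence <- stats::setNames(
      rep(0.5, length(covariate_effects)), names(covariate_effects))
  }
  if (!is.null(covariate_prevalence)) {
    stopifnot(all(covariate_prevalence > 0 & covariate_prevalence < 1))
  }
  structure(list(
    n_studies = as.integer(n_studies), obs_per_study = obs_per_study,
    true_beta0 = true_beta0, gamma = gamma,
    covariate_effects = covariate_effects,
    covariate_prevalence = covariate_prevalence,
    se_range = se_range, overlap_fraction = overlap_fraction,
    outlier_fraction = outlier_fraction, outlier_shift = outlier_shift,
    censor_nonsignificant_prob = censor_nonsignificant_prob,
    seed = as.integer(seed)
  ), class = "bop_sim_config")
}

#' Generate a synthetic observation set
#'
#' Draws `u_i ~ N(0, gamma)` per study, covariates `x ~ Bernoulli(prev)`,
#' SEs log-uniform over `se_range`, observations
#' `y ~ N(beta0 + sum(beta_k x_k) + u_i, s^2)`; applies outlier shifts,
#' overlap-group labels and optional significance censoring; and returns
#' both the harmonized observation set and the generating truth.
#'
#' @param config a `bop_sim_config`.
#' @param outcome outcome label for the emitted set.
#' @return list with `observations` (a `bop_obs`) and `truth` (class
#'   `bop_sim_truth`: config echo, per-study random effects, per-observation
#'   true means, outlier and censoring flags).
#' @export
simulate_observations <- function(config, outcome = "synthetic") {
  stopifnot(inherits(config, "bop_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  K <- config$n_studies
  ops <- config$obs_per_study
  k <- if (length(ops) == K && K > 2) {
    as.integer(ops)
  } else if (length(ops) == 1L) {
    rep(as.integer(ops), K)
  } else if (length(ops) == 2L) {
    sample(seq(ops[1], ops[2]), K, replace = TRUE)
  } else {
    stop("obs_per_study must be a count, a range, or one count per study",
      call. = FALSE)
  }

  # overlap studies emit at least two observations from one shared sample;
  # prefer studies already emitting several so stated counts are preserved
  n_ov <- round(config$overlap_fraction * K)
  ov_studies <- if (n_ov > 0) order(-k, seq_len(K))[seq_len(n_ov)] else
    integer(0)
  k[ov_studies] <- pmax(k[ov_studies], 2L)

  u <- stats::rnorm(K, 0, sqrt(config$gamma))
  study <- rep(seq_len(K), k)
  n <- length(study)
  s <- exp(stats::runif(n, log(config$se_range[1]), log(config$se_range[2])))

  mu <- config$true_beta0 + u[study]
  cv_cols <- list()
  if (!is.null(config$covariate_prevalence)) {
    for (nm in names(config$covariate_prevalence)) {
      x <- stats::rbinom(n, 1, config$covariate_prevalence[[nm]])
      cv_cols[[nm]] <- x
      eff <- config$covariate_effects[[nm]] %||% 0
      mu <- mu + eff * x
    }
  }
  y <- stats::rnorm(n, mu, s)

  n_out <- round(config$outlier_fraction * n)
  out_idx <- if (n_out > 0) sample(n, n_out) else integer(0)
  y[out_idx] <- y[out_idx] + config$outlier_shift

  censored <- rep(FALSE, n)
  p <- config$censor_nonsignificant_prob
  if (p > 0) {
    nonsig <- abs(y) / s < stats::qnorm(0.975)
    censored <- nonsig & (stats::runif(n) < p)
  }

  df <- data.frame(
    obs_id = sprintf("obs%04d", seq_len(n)),
    study_id = sprintf("study%03d", study),
    measure = "RR",
    log_effect = y,
    log_se = s,
    overlap_group = ifelse(study %in% ov_studies,
      sprintf("og%03d", study), NA_character_),
    sex = "both",
    exposure_definition = "chewing tobacco",
    exposure_temporality = "current",
    outcome_aggregate = 0L,
    sample_size = pmax(20L, as.integer(round(4 / s^2))),
    design = "case_control",
    stringsAsFactors = FALSE
  )
  for (nm in names(cv_cols)) df[[nm]] <- cv_cols[[nm]]

  truth <- structure(list(
    config = config,
    u = u,
    obs = data.frame(
      obs_id = df$obs_id, study_id = df$study_id, true_mean = mu,
      outlier = seq_len(n) %in% out_idx, censored = censored,
      stringsAsFactors = FALSE
    )
  ), class = "bop_sim_truth")

  df <- df[!censored, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("censoring removed every observation", call. = FALSE)
  }
  obs <- harmonize_observations(df, outcome = outcome,
    provenance = sprintf("simulated (seed %d)", config$seed))
  list(observations = obs, truth = truth)
}

#' Seeded fixtures mimicking published per-outcome data shapes
#'
#' Synthetic observation sets whose study/observation counts and
#' between-study heterogeneity match named profiles of the chewing-tobacco
#' evidence base (effect sizes are synthetic, not extracted): sparse and
#' consistent ("stroke-like", 3 studies / 4 observations, negligible
#' gamma), moderate ("esophageal-like", 22 / 31, gamma 0.09), and large
#' and heterogeneous ("lip-oral-like", 70 / 106, gamma 0.53).
#'
#' @param profile one of `"stroke-like"`, `"esophageal-like"`,
#'   `"lip-oral-like"`.
#' @param seed integer seed.
#' @return a `bop_obs` data frame.
#' @export
make_profile_fixture <- function(profile = c("stroke-like",
                                             "esophageal-like",
                                             "lip-oral-like"),
                                 seed = 20240205L) {
  profile <- match.arg(profile)
  spec <- switch(profile,
    "stroke-like" = list(
      K = 3L, counts = c(2L, 1L, 1L), beta0 = log(1.5), gamma = 1e-6,
      se = c(0.10, 0.45), overlap = 1 / 3
    ),
    "esophageal-like" = list(
      K = 22L, counts = c(rep(2L, 9), rep(1L, 13)), beta0 = log(2.1),
      gamma = 0.09, se = c(0.08, 0.6), overlap = 0.2
    ),
    "lip-oral-like" = list(
      K = 70L, counts = c(rep(2L, 36), rep(1L, 34)), beta0 = log(3.6),
      gamma = 0.53, se = c(0.08, 0.6), overlap = 0.25
    )
  )
  cfg <- sim_config(
    n_studies = spec$K, obs_per_study = spec$counts,
    true_beta0 = spec$beta0, gamma = spec$gamma, se_range = spec$se,
    overlap_fraction = spec$overlap, seed = seed
  )
  sim <- simulate_observations(cfg, outcome = profile)
  obs <- sim$observations
  if (nrow(obs) != sum(spec$counts)) {
    stop("internal error: fixture size drifted", call. = FALSE)
  }
  obs
}

#' @export
print.bop_sim_truth <- function(x, ...) {
  cat(sprintf(
    "<bop_sim_truth> %d studies, %d observations (%d censored), seed %d\n",
    x$config$n_studies, nrow(x$obs), sum(x$obs$censored), x$config$seed))
  invisible(x)
}
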