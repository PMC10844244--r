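#' Binary bias covariates and their selection
#'
#' Candidate covariates flag study characteristics that may bias reported
#' effect sizes away from a "gold standard" design: representativeness of
#' the study population, exposure and outcome ascertainment, deviations in
#' exposure/outcome definitions, use of a study subpopulation, and the
#' degree of confounder adjustment (including smoking). Selection runs in
#' two stages on the fixed-effects (gamma = 0) log-RR regression: an L1
#' path on the standardized covariate columns determines the order in
#' which candidates acquire non-zero coefficients, and each candidate is
#' retained only if its penalty-free refit (with its Gaussian prior) is
#' significant at |z| >= 1.96. Cascade children (refinements of a coarser
#' flag) are retained only together with their parent.
#'
#' @name bias_covariates
#' @keywords internal
NULL

#' Define a candidate bias covariate
#'
#' @param name column name (a `cv_` prefix is added when absent from the
#'   observation table lookup).
#' @param gold_standard_value the covariate level observations are adjusted
#'   toward (0 or 1).
#' @param cascade_parent optional name of the coarser covariate this one
#'   refines.
#' @param prior_sd Gaussian prior SD for the coefficient, default 1.
#' @return list of class `bop_covariate`.
#' @export
bias_covariate <- function(name, gold_standard_value = 0,
                           cascade_parent = NA_character_, prior_sd = 1) {
  if (!gold_standard_value %in% c(0, 1)) {
    stop("gold_standard_value must be 0 or 1", call. = FALSE)
  }
  if (!is.finite(prior_sd) || prior_sd <= 0) {
    stop("prior_sd must be positive", call. = FALSE)
  }
  structure(list(
    name = name,
    gold_standard_value = gold_standard_value,
    cascade_parent = cascade_parent,
    prior_sd = prior_sd
  ), class = "bop_covariate")
}

#' The default ten-candidate registry
#'
#' The ten dimensions of systematic bias screened in the chewing-tobacco
#' analyses: confounder-adjustment level (maximal; age/sex; smoking on top
#' of age/sex, cascading from the age/sex flag), aggregate outcome
#' definitions, product-specific exposure definitions, ever- rather than
#' current-exposure comparisons, study subpopulations, population
#' representativeness, and self-reported exposure / unverified outcome
#' ascertainment. Gold-standard levels point at the better design.
#'
#' @return named list of `bop_covariate` objects.
#' @export
default_covariate_registry <- function() {
  reg <- list(
    bias_covariate("cv_maximally_adjusted", gold_standard_value = 1),
    bias_covariate("cv_adjusted_age_sex", gold_standard_value = 1),
    bias_covariate("cv_adjusted_smoking_age_sex", gold_standard_value = 1,
      cascade_parent = "cv_adjusted_age_sex"),
    bias_covariate("cv_aggregate_outcome", gold_standard_value = 0),
    bias_covariate("cv_specific_product", gold_standard_value = 0),
    bias_covariate("cv_subpopulation", gold_standard_value = 0),
    bias_covariate("cv_representative_population", gold_standard_value = 1),
    bias_covariate("cv_self_reported_exposure", gold_standard_value = 0),
    bias_covariate("cv_unverified_outcome", gold_standard_value = 0),
    bias_covariate("cv_ever_exposure", gold_standard_value = 0)
  )
  stats::setNames(reg, vapply(reg, `[[`, "", "name"))
}

#' Read a covariate registry from JSON
#'
#' The file maps covariate name to
#' `{gold_standard_value, cascade_parent, prior_sd}`.
#'
#' @param path JSON file.
#' @return named list of `bop_covariate` objects.
#' @export
read_covariate_registry <- function(path) {
  raw <- jsonlite::read_json(path)
  reg <- lapply(names(raw), function(nm) {
    spec <- raw[[nm]]
    bias_covariate(
      name = nm,
      gold_standard_value = spec$gold_standard_value %||% 0,
      cascade_parent = spec$cascade_parent %||% NA_character_,
      prior_sd = spec$prior_sd %||% 1
    )
  })
  reg <- stats::setNames(reg, vapply(reg, `[[`, "", "name"))
  .check_registry(reg)
  reg
}

.check_registry <- function(registry) {
  nms <- vapply(registry, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("covariate names must be unique", call. = FALSE)
  # cascade graph must be acyclic
  for (nm in nms) {
    seen <- character()
    cur <- nm
    while (!is.na(registry[[cur]]$cascade_parent)) {
      cur <- registry[[cur]]$cascade_parent
      if (!cur %in% nms) break
      if (cur %in% seen) stop("cascade cycle at '", nm, "'", call. = FALSE)
      seen <- c(seen, cur)
    }
  }
  invisible(registry)
}

#' Eligibility of a covariate for testing
#'
#' A covariate is eligible only when both its levels are informed by at
#' least two observations.
#'
#' @param covariate a `bop_covariate` or a column name.
#' @param obs_set a `bop_obs` data frame.
#' @return TRUE or FALSE.
#' @export
covariate_eligibility <- function(covariate, obs_set) {
  nm <- if (inherits(covariate, "bop_covariate")) covariate$name else covariate
  if (is.null(obs_set[[nm]])) {
    stop("covariate column '", nm, "' not present", call. = FALSE)
  }
  x <- obs_set[[nm]]
  sum(x == 0) >= 2L && sum(x == 1) >= 2L
}

# Order in which candidates acquire non-zero coefficients on a decreasing
# L1 path (fixed effects, inverse-variance weights, standardized columns).
.l1_entry_order <- function(y, Z, w) {
  p <- ncol(Z)
  if (p == 1L) {
    return(data.frame(name = colnames(Z), entry_lambda = NA_real_,
      stringsAsFactors = FALSE))
  }
  fitnet <- glmnet::glmnet(Z, y, weights = w, family = "gaussian",
    alpha = 1, standardize = FALSE, intercept = TRUE, nlambda = 200)
  B <- as.matrix(fitnet$beta)
  entry <- apply(B != 0, 1, function(nz) {
    if (any(nz)) which(nz)[1] else NA_integer_
  })
  lam <- fitnet$lambda[entry]
  ord <- order(entry, na.last = TRUE)
  data.frame(name = rownames(B)[ord], entry_lambda = lam[ord],
    stringsAsFactors = FALSE)
}

#' Select bias covariates
#'
#' @param obs_set a `bop_obs` data frame.
#' @param candidates list of `bop_covariate` objects (e.g.
#'   [default_covariate_registry()]); ineligible candidates are dropped
#'   before testing.
#' @param seed retained for interface stability; the path and refit are
#'   deterministic.
#' @param z_crit retention threshold on |coefficient| / SE, default 1.96.
#' @return list of class `bop_selection`: `selected` (ordered by path
#'   entry), `path` (per-candidate entry lambda, refit coefficient, SE, z),
#'   `eligible`.
#' @export
select_bias_covariates <- function(obs_set, candidates, seed = 1L,
                                   z_crit = stats::qnorm(0.975)) {
  if (length(candidates) == 0L) {
    return(structure(list(selected = character(), path = NULL,
      eligible = character()), class = "bop_selection"))
  }
  .check_registry(candidates)
  elig <- Filter(function(cv) covariate_eligibility(cv, obs_set), candidates)
  elig_names <- vapply(elig, `[[`, "", "name")
  if (length(elig) == 0L) {
    return(structure(list(selected = character(), path = NULL,
      eligible = character()), class = "bop_selection"))
  }

  y <- obs_set$log_effect
  w <- 1 / obs_set$log_se^2
  Z <- as.matrix(obs_set[, elig_names, drop = FALSE])
  sds <- apply(Z, 2, stats::sd)
  Zs <- sweep(Z, 2, ifelse(sds > 0, sds, 1), "/")
  path <- .l1_entry_order(y, Zs, w)

  # penalty-free refit of all eligible candidates with Gaussian priors,
  # fixed effects (gamma profiled at 0 during selection)
  prior_sd <- vapply(elig, `[[`, 1.0, "prior_sd")
  f <- .gls_profile(y, obs_set$log_se^2, factor(obs_set$study_id),
    .design_matrix(obs_set, elig_names), 0,
    .prior_prec_for(elig_names, prior_sd))
  if (is.null(f)) stop("selection refit is singular", call. = FALSE)
  coefs <- f$beta[-1]
  ses <- sqrt(diag(f$cov))[-1]
  z <- coefs / ses
  names(z) <- elig_names

  retained <- elig_names[abs(z) >= z_crit]
  # cascade: a child stays only while its parent stays
  repeat {
    drop <- vapply(retained, function(nm) {
      par <- candidates[[nm]]$cascade_parent
      !is.na(par) && par %in% names(candidates) && !(par %in% retained)
    }, logical(1))
    if (!any(drop)) break
    retained <- retained[!drop]
  }

  path$coef <- coefs[path$name]
  path$se <- ses[path$name]
  path$z <- z[path$name]
  path$retained <- path$name %in% retained
  selected <- path$name[path$retained]  # ordered by path entry

  structure(list(selected = selected, path = path, eligible = elig_names),
    class = "bop_selection")
}

#' Shift observations toward the gold-standard covariate levels
#'
#' Each observation's `log_effect` is adjusted by
#' `-beta_c (x_c - gold_c)` for every selected covariate c, so that
#' gold-standard observations are unchanged and the refitted covariate
#' coefficients are approximately zero.
#'
#' @param obs_set a `bop_obs` data frame.
#' @param fit a `bop_fit` whose `beta_cov` covers every selected covariate.
#' @param selected list of `bop_covariate` objects to adjust for.
#' @return the adjusted observation set (ratio-scale fields updated too).
#' @export
apply_bias_adjustment <- function(obs_set, fit, selected) {
  if (length(selected) == 0L) return(obs_set)
  nms <- vapply(selected, `[[`, "", "name")
  miss <- setdiff(nms, names(fit$beta_cov))
  if (length(miss)) {
    stop("fit lacks coefficients for: ", paste(miss, collapse = ", "),
      call. = FALSE)
  }
  shift <- rep(0, nrow(obs_set))
  for (cv in selected) {
    shift <- shift - fit$beta_cov[[cv$name]] *
      (obs_set[[cv$name]] - cv$gold_standard_value)
  }
  obs_set$log_effect <- obs_set$log_effect + shift
  obs_set$effect <- exp(obs_set$log_effect)
  obs_set$ci_lower <- obs_set$ci_lower * exp(shift)
  obs_set$ci_upper <- obs_set$ci_upper * exp(shift)
  obs_set
}

#' @export
print.bop_selection <- function(x, ...) {
  cat("<bop_selection>\n")
  cat("  eligible:", if (length(x$eligible)) paste(x$eligible,
    collapse = ", ") else "(none)", "\n")
  cat("  selected:", if (length(x$selected)) paste(x$selected,
    collapse = ", ") else "(none)", "\n")
  invisible(x)
}
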