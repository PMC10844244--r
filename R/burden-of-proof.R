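#' Burden-of-Proof Risk Function, risk-outcome score and star rating
#'
#' The BPRF is the 5th-quantile relative risk closest to the null, taken
#' from the log-normal summary `N(beta0, se_beta0^2 + gamma_q95)` that
#' includes both sampling uncertainty and the conservative upper quantile
#' of between-study heterogeneity. It is the most conservative effect
#' consistent with the data: for a harmful exposure (`beta0 > 0`) it is the
#' lower 5th percentile, for a protective one the upper 95th. The
#' risk-outcome score is the signed half-log of the BPRF, and the star
#' rating bins the ROS into an ordinal 0-5 evidence grade. No BPRF/ROS is
#' assigned when the heterogeneity-free interval crosses the null.
#'
#' @name burden_of_proof
#' @keywords internal
NULL

#' Burden-of-Proof Risk Function
#'
#' @param beta0 pooled mean log relative risk.
#' @param se_beta0 its standard error.
#' @param gamma_q95 conservative upper-quantile between-study variance.
#' @return the BPRF on the ratio scale (1 when `beta0 == 0`).
#' @examples
#' bprf(0.3784, 0.0694, 0.0151) # 1.16: risk raised by a conservative 16%
#' @export
bprf <- function(beta0, se_beta0, gamma_q95 = 0) {
  if (se_beta0 < 0 || gamma_q95 < 0) {
    stop("variance inputs must be non-negative", call. = FALSE)
  }
  if (beta0 == 0) return(1)
  shift <- stats::qnorm(0.95) * sqrt(se_beta0^2 + gamma_q95)
  exp(beta0 - sign(beta0) * shift)
}

#' Risk-outcome score
#'
#' Signed `log(BPRF) / 2` for a dichotomous risk factor; the sign is the
#' direction of the pooled effect so that consistent evidence in either
#' direction scores positive, and negative values flag weak, inconsistent
#' evidence.
#'
#' @param bprf_value a positive BPRF.
#' @param direction_sign +1 for harmful (`beta0 > 0`), -1 for protective.
#' @return the ROS.
#' @export
ros <- function(bprf_value, direction_sign = 1) {
  if (!is.finite(bprf_value) || bprf_value <= 0) {
    stop("bprf_value must be positive", call. = FALSE)
  }
  if (!direction_sign %in% c(-1, 1)) {
    stop("direction_sign must be -1 or +1", call. = FALSE)
  }
  direction_sign * log(bprf_value) / 2
}

#' Star rating from the risk-outcome score
#'
#' 0 stars when the fixed-effects (no-gamma) interval crosses the null (no
#' ROS is assigned); otherwise 1 star for ROS < 0, 2 for ROS in [0, 0.14],
#' 3 for (0.14, 0.41], 4 for (0.41, 0.62], 5 above 0.62. Boundaries are
#' inclusive on the lower category's upper bound.
#'
#' @param ros_value the ROS (may be NA when not assigned).
#' @param fixed_ui_excludes_null does the no-gamma 95% interval exclude 1?
#' @return integer 0-5.
#' @export
star_rating <- function(ros_value, fixed_ui_excludes_null) {
  if (!isTRUE(fixed_ui_excludes_null)) return(0L)
  if (is.na(ros_value)) stop("ros_value required when the gate passes",
    call. = FALSE)
  if (ros_value < 0) 1L
  else if (ros_value <= 0.14) 2L
  else if (ros_value <= 0.41) 3L
  else if (ros_value <= 0.62) 4L
  else 5L
}

#' Assemble a per-outcome risk summary
#'
#' Combines a fitted model, its heterogeneity summary and the
#' publication-bias test into one reportable record: pooled RR with both
#' 95% uncertainty intervals, BPRF/ROS/stars (gated on fixed-effects
#' significance), and bookkeeping fields. Full-precision values are stored;
#' rounding to 2 decimals happens only in the report writers.
#'
#' @param fit a `bop_fit`.
#' @param het a `bop_het` for the same fit.
#' @param pub a `bop_egger` result, or NULL if not computed.
#' @param outcome outcome label.
#' @param selected_covariates names of bias covariates adjusted for.
#' @param level interval coverage, default 0.95.
#' @return an object of class `bop_risk_summary`.
#' @export
summarize_risk <- function(fit, het, pub = NULL, outcome = "outcome",
                           selected_covariates = fit$covariates,
                           level = 0.95) {
  if (!inherits(fit, "bop_fit")) stop("fit must be a bop_fit", call. = FALSE)
  if (!inherits(het, "bop_het")) stop("het must be a bop_het", call. = FALSE)
  if (abs(het$gamma_hat - fit$gamma_hat) > 1e-8) {
    stop("het was not computed from this fit", call. = FALSE)
  }
  ui0 <- uncertainty_interval(fit$beta0, fit$se_beta0, level = level)
  uig <- uncertainty_interval(fit$beta0, fit$se_beta0, het$gamma_q95,
    include_gamma = TRUE, level = level)
  gate <- ui0[1] > 1 || ui0[2] < 1
  if (gate) {
    b <- bprf(fit$beta0, fit$se_beta0, het$gamma_q95)
    r <- ros(b, if (fit$beta0 >= 0) 1 else -1)
  } else {
    b <- NA_real_
    r <- NA_real_
  }
  structure(list(
    outcome = outcome,
    rr = exp(fit$beta0),
    ui_no_gamma = ui0,
    ui_with_gamma = uig,
    gamma_hat = fit$gamma_hat,
    gamma_sd = het$gamma_sd,
    gamma_q95 = het$gamma_q95,
    bprf = b,
    ros = r,
    stars = star_rating(r, gate),
    pub_bias = if (is.null(pub)) NA else pub$flagged,
    n_studies = fit$n_studies_used,
    n_obs = fit$n_obs_used,
    selected_covariates = selected_covariates,
    fit = fit, het = het, egger = pub
  ), class = "bop_risk_summary")
}

#' One-row data frame form of a risk summary (report precision, 2 dp)
#'
#' @param x a `bop_risk_summary`.
#' @return a one-row data frame mirroring the published summary-table
#'   columns.
#' @export
risk_summary_row <- function(x) {
  r2 <- function(v) round(v, 2)
  data.frame(
    outcome = x$outcome,
    rr = r2(x$rr),
    ui_no_gamma_lower = r2(x$ui_no_gamma[1]),
    ui_no_gamma_upper = r2(x$ui_no_gamma[2]),
    ui_with_gamma_lower = r2(x$ui_with_gamma[1]),
    ui_with_gamma_upper = r2(x$ui_with_gamma[2]),
    bprf = r2(x$bprf),
    ros = r2(x$ros),
    stars = x$stars,
    pub_bias = x$pub_bias,
    n_studies = x$n_studies,
    n_obs = x$n_obs,
    selected_covariates = paste(x$selected_covariates, collapse = "; "),
    stringsAsFactors = FALSE
  )
}

#' @export
print.bop_risk_summary <- function(x, ...) {
  cat(sprintf("<bop_risk_summary> %s\n", x$outcome))
  cat(sprintf("  RR %.2f (95%% UI without gamma %.2f-%.2f; with gamma %.2f-%.2f)\n",
    x$rr, x$ui_no_gamma[1], x$ui_no_gamma[2],
    x$ui_with_gamma[1], x$ui_with_gamma[2]))
  if (is.na(x$bprf)) {
    cat("  BPRF/ROS not assigned (no-gamma UI crosses 1); 0 stars\n")
  } else {
    cat(sprintf("  BPRF %.2f, ROS %.2f, %d star%s\n", x$bprf, x$ros,
      x$stars, if (x$stars == 1) "" else "s"))
  }
  cat(sprintf("  gamma %.4g (Fisher SD %.4g), %d studies / %d observations\n",
    x$gamma_hat, x$gamma_sd, x$n_studies, x$n_obs))
  if (!is.na(x$pub_bias)) {
    cat(sprintf("  publication bias flagged: %s\n", x$pub_bias))
  }
  invisible(x)
}
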