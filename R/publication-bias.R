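#' Publication-bias diagnostics
#'
#' Egger's regression adapted to the mixed-effects residual scale: model
#' residuals are regressed on the total standard error
#' `sqrt(log_se^2 + gamma_hat)` with inverse-total-variance weights. A
#' significant slope indicates funnel asymmetry consistent with small-study
#' or selective-reporting effects. The companion funnel table holds the
#' per-observation (residual, total SE) pairs plus the reference lines of
#' the modified funnel plot.
#'
#' @name publication_bias
#' @keywords internal
NULL

.fitted_values <- function(obs_set, fit) {
  X <- .design_matrix(obs_set, fit$covariates)
  drop(X %*% c(fit$beta0, fit$beta_cov))
}

#' Egger's regression test
#'
#' Weighted linear regression of untrimmed-observation residuals on total
#' SE; two-sided test of zero slope.
#'
#' @param obs_set a `bop_obs` data frame (the set the model was fitted to).
#' @param fit a `bop_fit`.
#' @param alpha flagging level, default 0.05.
#' @return list of class `bop_egger`: `slope`, `slope_se`, `p_value`,
#'   `flagged`, `alpha`, `n`.
#' @export
eggers_test <- function(obs_set, fit, alpha = 0.05) {
  keep <- fit$trim_weights[obs_set$obs_id] > 0
  obs <- obs_set[keep, , drop = FALSE]
  if (nrow(obs) < 3L) {
    stop("Egger's test needs at least 3 untrimmed observations",
      call. = FALSE)
  }
  resid <- obs$log_effect - .fitted_values(obs, fit)
  tot_se <- sqrt(obs$log_se^2 + fit$gamma_hat)
  m <- stats::lm(resid ~ tot_se, weights = 1 / tot_se^2)
  co <- suppressWarnings(summary(m))$coefficients
  slope <- co["tot_se", "Estimate"]
  se <- co["tot_se", "Std. Error"]
  p <- co["tot_se", "Pr(>|t|)"]
  if (!is.finite(p)) {  # degenerate regression (e.g. all residuals zero)
    slope <- unname(slope)
    p <- 1
  }
  structure(list(
    slope = slope, slope_se = se, p_value = p,
    flagged = p < alpha, alpha = alpha, n = nrow(obs)
  ), class = "bop_egger")
}

#' Funnel-plot point table
#'
#' Per-observation residual mean `y - yhat` and total residual SD
#' `sqrt(log_se^2 + gamma_hat)`, with trimmed rows flagged as outlier
#' markers. When a heterogeneity summary is supplied the reference lines
#' of the modified funnel plot (null, mean effect, BPRF and both interval
#' bands, all on the log scale) are attached as the `"lines"` attribute.
#'
#' @inheritParams eggers_test
#' @param het optional `bop_het`; enables the BPRF and interval lines.
#' @return data frame with `obs_id`, `residual_mean`, `residual_sd`,
#'   `trimmed`.
#' @export
funnel_points <- function(obs_set, fit, het = NULL) {
  pts <- data.frame(
    obs_id = obs_set$obs_id,
    residual_mean = obs_set$log_effect - .fitted_values(obs_set, fit),
    residual_sd = sqrt(obs_set$log_se^2 + fit$gamma_hat),
    trimmed = fit$trim_weights[obs_set$obs_id] == 0,
    stringsAsFactors = FALSE
  )
  lines <- list(null = 0, mean = fit$beta0)
  if (!is.null(het)) {
    ui0 <- uncertainty_interval(fit$beta0, fit$se_beta0)
    uig <- uncertainty_interval(fit$beta0, fit$se_beta0, het$gamma_q95,
      include_gamma = TRUE)
    gate <- ui0[1] > 1 || ui0[2] < 1
    lines$ui_no_gamma <- log(ui0)
    lines$ui_with_gamma <- log(uig)
    if (gate) {
      lines$bprf <- log(bprf(fit$beta0, fit$se_beta0, het$gamma_q95))
    }
  }
  attr(pts, "lines") <- lines
  pts
}

#' @export
print.bop_egger <- function(x, ...) {
  cat(sprintf(
    "<bop_egger> slope %.4f (SE %.4f), p = %.4g, flagged: %s (alpha %.2f, n %d)\n",
    x$slope, x$slope_se, x$p_value, x$flagged, x$alpha, x$n))
  invisible(x)
}
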