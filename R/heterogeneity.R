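#' Uncertainty in the between-study heterogeneity estimate
#'
#' With few studies the point estimate of the between-study variance gamma
#' is itself uncertain, and ignoring that uncertainty understates the width
#' of heterogeneity-aware intervals. The Fisher information of gamma under
#' the Gaussian marginal model is `I(gamma) = 1/2 sum_i tr[(V_i^-1 J_i)^2]`
#' per study block (`V_i = diag(s_i^2) + gamma J_i`); its inverse square
#' root is the SD attached to gamma-hat, and downstream intervals use a
#' conservative upper quantile of gamma rather than the point estimate.
#'
#' @name heterogeneity_uncertainty
#' @keywords internal
NULL

#' Fisher-information standard deviation of the heterogeneity estimate
#'
#' For a study block, `1' V^-1 1 = t / (1 + gamma t)` with `t = sum(1/s^2)`,
#' so `I(gamma) = 1/2 sum_g (t_g / (1 + gamma t_g))^2` and the returned SD
#' is `I(gamma-hat)^(-1/2)`. Trimmed rows are excluded.
#'
#' @param obs_set a `bop_obs` data frame.
#' @param fit a `bop_fit` from [fit_model()].
#' @return the Fisher SD of gamma-hat.
#' @export
gamma_fisher_sd <- function(obs_set, fit) {
  keep <- fit$trim_weights[obs_set$obs_id] > 0
  obs <- obs_set[keep, , drop = FALSE]
  if (nrow(obs) == 0L) stop("no untrimmed observations", call. = FALSE)
  tg <- rowsum(1 / obs$log_se^2, factor(obs$study_id))[, 1]
  info <- 0.5 * sum((tg / (1 + fit$gamma_hat * tg))^2)
  1 / sqrt(info)
}

#' Conservative quantile of the heterogeneity variance
#'
#' Default is the closed form `max(0, gamma_hat + z_q * gamma_sd)`. A seeded
#' sampling mode (quantile of normal draws, floored at zero after the
#' quantile is taken) is provided for comparison.
#'
#' @param gamma_hat,gamma_sd estimate and Fisher SD of gamma.
#' @param q quantile, default 0.95.
#' @param method `"closed_form"` (default) or `"sample"`.
#' @param n_draws,seed used by the sampling mode only.
#' @return the non-negative q-quantile of gamma.
#' @export
gamma_quantile <- function(gamma_hat, gamma_sd, q = 0.95,
                           method = c("closed_form", "sample"),
                           n_draws = 1e4, seed = 1L) {
  if (q <= 0 || q >= 1) stop("q must be in (0,1)", call. = FALSE)
  method <- match.arg(method)
  if (method == "closed_form") {
    return(max(0, gamma_hat + stats::qnorm(q) * gamma_sd))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draws <- stats::rnorm(n_draws, gamma_hat, gamma_sd)
  max(0, unname(stats::quantile(draws, q, type = 7)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Summarize heterogeneity with Fisher uncertainty
#'
#' @inheritParams gamma_fisher_sd
#' @param q upper quantile used downstream (default 0.95).
#' @return list of class `bop_het`: `gamma_hat`, `gamma_sd`, `gamma_q95`,
#'   `method`.
#' @export
heterogeneity_summary <- function(obs_set, fit, q = 0.95) {
  sd <- gamma_fisher_sd(obs_set, fit)
  structure(list(
    gamma_hat = fit$gamma_hat,
    gamma_sd = sd,
    gamma_q95 = gamma_quantile(fit$gamma_hat, sd, q),
    method = "fisher_information_closed_form"
  ), class = "bop_het")
}

#' 95% uncertainty interval for the pooled relative risk
#'
#' Without gamma: `exp(beta0 -+ z se_beta0)`, the traditional fixed-effects
#' interval. With gamma: the between-study component enters in quadrature,
#' `exp(beta0 -+ z sqrt(se_beta0^2 + gamma_q95))`, using the conservative
#' upper quantile of gamma.
#'
#' @param beta0,se_beta0 pooled mean log RR and its SE.
#' @param gamma_q95 upper-quantile heterogeneity variance (ignored unless
#'   `include_gamma`).
#' @param include_gamma include the between-study component?
#' @param level interval coverage, default 0.95.
#' @return `c(lower, upper)` on the ratio scale.
#' @examples
#' uncertainty_interval(0.3784, 0.0694)                       # (1.28, 1.68)
#' uncertainty_interval(0.3784, 0.0694, 0.0151, TRUE)         # (1.11, 1.93)
#' @export
uncertainty_interval <- function(beta0, se_beta0, gamma_q95 = 0,
                                 include_gamma = FALSE, level = 0.95) {
  if (se_beta0 < 0 || gamma_q95 < 0) {
    stop("variance inputs must be non-negative", call. = FALSE)
  }
  z <- stats::qnorm((1 + level) / 2)
  half <- if (include_gamma) {
    z * sqrt(se_beta0^2 + gamma_q95)
  } else {
    z * se_beta0
  }
  exp(c(beta0 - half, beta0 + half))
}

#' @export
print.bop_het <- function(x, ...) {
  cat(sprintf(
    "<bop_het> gamma_hat %.6g, Fisher SD %.6g, 95th quantile %.6g (%s)\n",
    x$gamma_hat, x$gamma_sd, x$gamma_q95, x$method))
  invisible(x)
}
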