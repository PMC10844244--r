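#' Mixed-effects meta-regression on the log relative-risk scale
#'
#' The model is `y_ij = x_ij' beta + u_i + e_ij` with a single study-level
#' random effect `u_i ~ N(0, gamma)` shared by all observations of study i
#' (block all-ones covariance) and independent sampling noise
#' `e_ij ~ N(0, s_ij^2)` at the reported (possibly overlap-inflated) SEs.
#' The intercept is the exposure effect beta0 (pooled mean log RR); optional
#' binary bias covariates enter as fixed effects with Gaussian ridge priors.
#' gamma is estimated by bounded maximum marginal likelihood.
#'
#' @name meta_model
#' @keywords internal
NULL

# Design matrix: intercept-as-exposure plus selected cv_ columns.
.design_matrix <- function(obs_set, covariates = character()) {
  n <- nrow(obs_set)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(exposure)"))
  if (length(covariates)) {
    miss <- setdiff(covariates, names(obs_set))
    if (length(miss)) {
      stop("covariate column(s) missing: ", paste(miss, collapse = ", "),
        call. = FALSE)
    }
    X <- cbind(X, as.matrix(obs_set[, covariates, drop = FALSE]))
    colnames(X) <- c("(exposure)", covariates)
  }
  X
}

# Penalized GLS at fixed gamma via the Woodbury identity on each study block
# V = diag(s^2) + gamma * 11'.  Returns the profile (penalized) likelihood,
# the unpenalized marginal log-likelihood at beta-hat, and (X'V^-1 X + P)^-1.
.gls_profile <- function(y, s2, study, X, gamma, prior_prec) {
  w <- 1 / s2
  tg <- rowsum(w, study)                       # per-study total information
  si <- as.integer(study)
  cg <- gamma / (1 + gamma * tg[si, 1])        # Woodbury scalar per row
  vinv <- function(z) {
    wz <- w * z
    sums <- rowsum(wz, study)
    wz - (cg * w) * sums[si, , drop = FALSE]
  }
  ViX <- vinv(X)
  Viy <- vinv(matrix(y, ncol = 1))
  A <- crossprod(X, ViX)
  P <- diag(prior_prec, nrow = ncol(X))
  beta <- tryCatch(
    solve(A + P, crossprod(X, Viy)),
    error = function(e) NULL
  )
  if (is.null(beta)) return(NULL)
  r <- y - drop(X %*% beta)
  quad <- sum(r * vinv(matrix(r, ncol = 1)))
  logdet <- sum(log(s2)) + sum(log1p(gamma * tg))
  ll <- -0.5 * (length(y) * log(2 * pi) + logdet + quad)
  pll <- ll - 0.5 * sum(prior_prec * drop(beta)^2)
  list(beta = drop(beta), cov = solve(A + P), loglik = ll, pll = pll)
}

.prior_prec_for <- function(covariates, prior_sd) {
  if (length(covariates) == 0L) return(0)
  if (is.null(prior_sd)) prior_sd <- rep(1, length(covariates))
  if (length(prior_sd) == 1L) prior_sd <- rep(prior_sd, length(covariates))
  c(0, 1 / prior_sd^2)  # exposure effect unpenalized
}

#' Marginal log-likelihood of the mixed-effects model
#'
#' Sum over studies of the multivariate-normal log density
#' `log N(y_i; X_i beta, diag(s_i^2) + gamma J_i)` using only weight-1 rows,
#' where `J_i` is the all-ones matrix over study i's included rows.
#'
#' @param beta coefficient vector (exposure effect first, then `covariates`
#'   in order).
#' @param gamma non-negative between-study variance.
#' @param obs_set a `bop_obs` data frame.
#' @param weights optional 0/1 inclusion vector (default all 1).
#' @param covariates names of `cv_` columns entering the fixed effects.
#' @return the marginal log-likelihood (a scalar).
#' @export
marginal_loglik <- function(beta, gamma, obs_set, weights = NULL,
                            covariates = character()) {
  if (!is.finite(gamma) || gamma < 0) {
    stop("gamma must be non-negative", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, nrow(obs_set))
  keep <- weights > 0
  if (!any(keep)) stop("no observations included", call. = FALSE)
  obs <- obs_set[keep, , drop = FALSE]
  X <- .design_matrix(obs, covariates)
  if (length(beta) != ncol(X)) {
    stop("beta has length ", length(beta), ", expected ", ncol(X),
      call. = FALSE)
  }
  y <- obs$log_effect
  s2 <- obs$log_se^2
  study <- factor(obs$study_id)
  w <- 1 / s2
  tg <- rowsum(w, study)
  si <- as.integer(study)
  cg <- gamma / (1 + gamma * tg[si, 1])
  r <- y - drop(X %*% beta)
  wr <- w * r
  sums <- rowsum(wr, study)
  quad <- sum(r * (wr - (cg * w) * sums[si, 1]))
  logdet <- sum(log(s2)) + sum(log1p(gamma * tg))
  -0.5 * (length(y) * log(2 * pi) + logdet + quad)
}

# Maximize the gamma-profile penalized likelihood: coarse log-spaced scan,
# golden-section refinement, explicit gamma = 0 boundary check.
.fit_ml <- function(obs, covariates, prior_sd, gamma_fixed = NULL) {
  y <- obs$log_effect
  s2 <- obs$log_se^2
  study <- factor(obs$study_id)
  X <- .design_matrix(obs, covariates)
  pp <- .prior_prec_for(covariates, prior_sd)

  if (!is.null(gamma_fixed)) {
    f <- .gls_profile(y, s2, study, X, gamma_fixed, pp)
    if (is.null(f)) stop("fixed-effects system is singular", call. = FALSE)
    beta <- f$beta
    names(beta) <- colnames(X)
    return(list(beta = beta, gamma = gamma_fixed, cov_beta = f$cov,
      loglik = f$loglik, converged = TRUE))
  }

  prof <- function(g) {
    f <- .gls_profile(y, s2, study, X, g, pp)
    if (is.null(f)) -Inf else f$pll
  }

  n_study <- nlevels(study)
  converged <- TRUE
  if (n_study < 2L) {
    # gamma not identifiable from a single random-effect level
    warning("single study: between-study variance not identifiable, ",
      "returning gamma = 0", call. = FALSE)
    ghat <- 0
  } else {
    gmax <- max(1, 10 * stats::var(y))
    grid <- c(0, 10^seq(-8, log10(gmax), length.out = 40))
    vals <- vapply(grid, prof, numeric(1))
    if (all(!is.finite(vals))) {
      converged <- FALSE
      ghat <- 0
    } else {
      i <- which.max(vals)
      lo <- grid[max(1L, i - 1L)]
      hi <- grid[min(length(grid), i + 1L)]
      ghat <- if (hi > lo) {
        opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE,
          tol = 1e-10)
        if (opt$objective >= vals[i]) opt$maximum else grid[i]
      } else {
        grid[i]
      }
      if (prof(0) >= prof(ghat)) ghat <- 0
    }
  }
  f <- .gls_profile(y, s2, study, X, ghat, pp)
  if (is.null(f)) {
    stop("fixed-effects system is singular", call. = FALSE)
  }
  beta <- f$beta
  names(beta) <- colnames(X)
  list(
    beta = beta, gamma = ghat, cov_beta = f$cov,
    loglik = f$loglik, converged = converged
  )
}

#' Fit the mixed-effects log relative-risk meta-regression
#'
#' Maximum-marginal-likelihood fit with optional least-trimmed-squares
#' outlier removal. Trimming is applied only when there are more than 10
#' observations; smaller models keep every row (the data are too sparse for
#' outliers to be identified reliably).
#'
#' @param obs_set a `bop_obs` data frame (already overlap-downweighted if
#'   applicable).
#' @param covariates names of `cv_` columns to adjust for.
#' @param trim_fraction fraction of observations to trim (default 0; the
#'   pipeline default is 0.10). Must lie in `[0, 0.5)`.
#' @param seed retained for interface stability; the profile-likelihood
#'   optimizer is deterministic and does not consume it.
#' @param prior_sd Gaussian prior SD(s) for the covariate coefficients
#'   (scalar or one per covariate, default 1).
#' @param gamma_fixed optionally hold the between-study variance fixed at
#'   this value instead of estimating it (e.g. 0 for a fixed-effects fit).
#' @return an object of class `bop_fit`: `beta0`, `beta_cov`, `se_beta0`,
#'   `gamma_hat`, `gamma_sd` (NA until filled by
#'   [heterogeneity_summary()]), `trim_weights`, `loglik`, `n_obs_used`,
#'   `converged`.
#' @examples
#' obs <- harmonize_observations(data.frame(
#'   obs_id = c("a", "b"), study_id = c("s1", "s2"),
#'   log_effect = c(0, 1), log_se = c(0.2, 0.2)))
#' fit_model(obs)
#' @export
fit_model <- function(obs_set, covariates = character(),
                      trim_fraction = 0, seed = 1L, prior_sd = NULL,
                      gamma_fixed = NULL) {
  n <- nrow(obs_set)
  if (n < 1L) stop("need at least one observation", call. = FALSE)
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop("trim_fraction must be in [0, 0.5)", call. = FALSE)
  }
  w <- stats::setNames(rep(1, n), obs_set$obs_id)
  if (trim_fraction > 0 && n > 10L) {
    w <- lts_trim(obs_set, trim_fraction, covariates, prior_sd = prior_sd)
  } else if (trim_fraction > 0) {
    message("trimming skipped: ", n, " observations (<= 10)")
  }
  kept <- obs_set[w[obs_set$obs_id] > 0, , drop = FALSE]
  f <- .fit_ml(kept, covariates, prior_sd, gamma_fixed)
  structure(list(
    beta0 = unname(f$beta[1]),
    beta_cov = if (length(covariates)) f$beta[-1] else
      stats::setNames(numeric(0), character(0)),
    se_beta0 = sqrt(f$cov_beta[1, 1]),
    cov_beta = f$cov_beta,
    gamma_hat = f$gamma,
    gamma_sd = NA_real_,
    trim_weights = w,
    loglik = f$loglik,
    n_obs_used = nrow(kept),
    n_studies_used = length(unique(kept$study_id)),
    covariates = covariates,
    converged = f$converged
  ), class = "bop_fit")
}

#' Least-trimmed-squares outlier identification
#'
#' Concentrated LTS: starting from the full set, refit, rank all
#' observations by squared standardized residual
#' `((y - x'beta) / sqrt(log_se^2 + gamma))^2`, retain the
#' `h = ceiling((1 - trim_fraction) n)` best, and iterate until the retained
#' set is stable (at most 100 iterations). Ties are broken toward the
#' lexicographically smaller `obs_id`. Models with 10 or fewer observations
#' are ineligible and keep every row.
#'
#' @inheritParams fit_model
#' @return named 0/1 vector over `obs_id` (1 = retained).
#' @export
lts_trim <- function(obs_set, trim_fraction, covariates = character(),
                     prior_sd = NULL) {
  n <- nrow(obs_set)
  ids <- obs_set$obs_id
  if (n <= 10L) {
    message("trimming skipped: ", n, " observations (<= 10)")
    return(stats::setNames(rep(1, n), ids))
  }
  h <- ceiling((1 - trim_fraction) * n)
  X <- .design_matrix(obs_set, covariates)

  std_r2 <- function(f) {
    (obs_set$log_effect - drop(X %*% f$beta))^2 /
      (obs_set$log_se^2 + f$gamma)
  }
  # refitted trimmed SSR of a candidate retained set
  obj <- function(set) {
    f <- .fit_ml(obs_set[set, , drop = FALSE], covariates, prior_sd)
    sum(std_r2(f)[set])
  }

  retained <- seq_len(n)
  seen <- list()
  for (iter in seq_len(100L)) {
    f <- .fit_ml(obs_set[retained, , drop = FALSE], covariates, prior_sd)
    r2 <- std_r2(f)
    ord <- order(r2, ids)            # tie-break: smaller obs_id first
    new_set <- sort(ord[seq_len(h)])
    if (identical(new_set, retained)) break
    key <- paste(new_set, collapse = ",")
    if (key %in% seen) break         # cycle guard
    seen[[length(seen) + 1L]] <- key
    retained <- new_set
  }

  # local swap refinement: C-steps can stall in a nearby local optimum, so
  # trade the worst-ranked retained rows against the best-ranked trimmed
  # rows while the refitted trimmed SSR improves
  q_out <- min(5L, n - h)
  q_in <- if (n <= 20L) h else min(8L, h)  # full neighborhood at small n
  if (q_out > 0L) {
    best_obj <- obj(retained)
    for (round in seq_len(20L)) {
      f <- .fit_ml(obs_set[retained, , drop = FALSE], covariates, prior_sd)
      r2 <- std_r2(f)
      out <- setdiff(seq_len(n), retained)
      worst_in <- retained[order(-r2[retained], ids[retained])][seq_len(q_in)]
      best_out <- out[order(r2[out], ids[out])][seq_len(q_out)]
      best_cand <- NULL
      for (i in worst_in) {
        for (j in best_out) {
          cand <- sort(c(setdiff(retained, i), j))
          v <- obj(cand)
          if (v < best_obj - 1e-12) {
            best_obj <- v
            best_cand <- cand
          }
        }
      }
      if (is.null(best_cand)) break
      retained <- best_cand
    }
  }

  w <- stats::setNames(rep(0, n), ids)
  w[retained] <- 1
  w
}

#' @export
print.bop_fit <- function(x, ...) {
  cat("<bop_fit>\n")
  cat(sprintf("  pooled log RR (beta0): %.4f  (RR %.4f), SE %.4f\n",
    x$beta0, exp(x$beta0), x$se_beta0))
  cat(sprintf("  between-study variance gamma: %.6g\n", x$gamma_hat))
  if (length(x$beta_cov)) {
    cat("  bias-covariate coefficients:\n")
    for (nm in names(x$beta_cov)) {
      cat(sprintf("    %s: %.4f\n", nm, x$beta_cov[[nm]]))
    }
  }
  cat(sprintf("  observations used: %d of %d; converged: %s\n",
    x$n_obs_used, length(x$trim_weights), x$converged))
  invisible(x)
}
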