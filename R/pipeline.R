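#' Per-outcome analysis pipeline
#'
#' `run_model()` orchestrates a full per-outcome run: validation, overlap
#' downweighting, covariate eligibility and selection, the trimmed
#' mixed-effects fit, Fisher uncertainty for gamma, both uncertainty
#' intervals, BPRF/ROS/star scoring gated on fixed-effects significance,
#' and Egger's test. `run_sensitivity_grid()` repeats the run over data or
#' parameter variants, each with and without 10% trimming.
#'
#' @name pipeline_cli
#' @keywords internal
NULL

#' Build a run configuration
#'
#' @param input a `bop_obs` data frame or a CSV path readable by
#'   [read_observations()].
#' @param outcome outcome label.
#' @param trim_fraction default 0.10; trimming is auto-disabled for models
#'   with 10 or fewer observations.
#' @param registry named list of `bop_covariate` candidates (default
#'   [default_covariate_registry()] restricted to columns present in the
#'   data), or a JSON registry path.
#' @param select_covariates run the selection algorithm?
#' @param downweight apply overlap downweighting (factor `overlap_factor`)?
#' @param overlap_factor `"sqrt_k"` or `"k"`.
#' @param filters named list applied conjunctively before modelling:
#'   `sex`, `exposure_temporality`, `exposure_definition` (kept levels),
#'   `outcome_specific_only` (drop aggregate-outcome rows),
#'   `min_sample_size` (drop smaller samples).
#' @param alpha significance level for the Egger flag.
#' @param level interval coverage, default 0.95.
#' @param seed integer seed recorded with the run.
#' @param out_dir optional output directory for the report bundle.
#' @return list of class `bop_run_config`.
#' @export
run_config <- function(input, outcome = "outcome", trim_fraction = 0.10,
                       registry = NULL, select_covariates = TRUE,
                       downweight = TRUE,
                       overlap_factor = c("sqrt_k", "k"),
                       filters = list(), alpha = 0.05, level = 0.95,
                       seed = 1L, out_dir = NULL) {
  structure(list(
    input = input, outcome = outcome, trim_fraction = trim_fraction,
    registry = registry, select_covariates = select_covariates,
    downweight = downweight, overlap_factor = match.arg(overlap_factor),
    filters = filters, alpha = alpha, level = level,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "bop_run_config")
}

.load_input <- function(config) {
  if (inherits(config$input, "bop_obs")) return(config$input)
  if (is.character(config$input)) {
    return(read_observations(config$input, outcome = config$outcome))
  }
  harmonize_observations(config$input, outcome = config$outcome)
}

.apply_filters <- function(obs, filters) {
  keep <- rep(TRUE, nrow(obs))
  for (nm in names(filters)) {
    val <- filters[[nm]]
    keep <- keep & switch(nm,
      sex = obs$sex %in% val,
      exposure_temporality = obs$exposure_temporality %in% val,
      exposure_definition = obs$exposure_definition %in% val,
      outcome_specific_only = if (isTRUE(val)) obs$outcome_aggregate == 0
        else TRUE,
      min_sample_size = is.na(obs$sample_size) | obs$sample_size >= val,
      stop("unknown filter: ", nm, call. = FALSE)
    )
  }
  obs[keep, , drop = FALSE]
}

.resolve_registry <- function(config, obs) {
  reg <- config$registry
  if (is.character(reg)) reg <- read_covariate_registry(reg)
  if (is.null(reg)) reg <- default_covariate_registry()
  reg[vapply(reg, function(cv) cv$name %in% names(obs), logical(1))]
}

#' Run the full per-outcome pipeline
#'
#' @param config a `bop_run_config`.
#' @return a `bop_risk_summary` (the fitted model, heterogeneity summary,
#'   selection and Egger results are carried in its fields).
#' @export
run_model <- function(config) {
  stopifnot(inherits(config, "bop_run_config"))
  obs <- .load_input(config)
  issues <- validate_observations(obs)
  if (nrow(issues) > 0L) {
    stop("input validation failed:\n",
      paste(sprintf("  %s/%s: %s", issues$obs_id, issues$field,
        issues$rule), collapse = "\n"), call. = FALSE)
  }
  obs <- .apply_filters(obs, config$filters)
  if (nrow(obs) < 1L) stop("no observations after filtering", call. = FALSE)

  if (config$downweight) {
    obs <- downweight_overlaps(obs, factor = config$overlap_factor)
  }

  registry <- .resolve_registry(config, obs)
  sel <- if (config$select_covariates && length(registry)) {
    select_bias_covariates(obs, registry, seed = config$seed)
  } else {
    structure(list(selected = character(), path = NULL,
      eligible = character()), class = "bop_selection")
  }
  prior_sd <- vapply(sel$selected, function(nm) registry[[nm]]$prior_sd,
    numeric(1))

  fit <- fit_model(obs,
    covariates = sel$selected,
    trim_fraction = config$trim_fraction,
    seed = config$seed,
    prior_sd = if (length(prior_sd)) prior_sd else NULL
  )
  het <- heterogeneity_summary(obs, fit)
  pub <- if (fit$n_obs_used >= 3L) {
    eggers_test(obs, fit, alpha = config$alpha)
  } else NULL

  summary <- summarize_risk(fit, het, pub, outcome = config$outcome,
    selected_covariates = sel$selected, level = config$level)
  summary$selection <- sel
  summary$observations <- obs
  summary$config <- config

  if (!is.null(config$out_dir)) render_report(summary, config$out_dir)
  summary
}

#' Run a sensitivity grid
#'
#' Each variant is a named list of `run_config` field overrides (typically
#' `filters`, `select_covariates`, `downweight`). Every variant is run both
#' with 10% trimming and without; cells are infeasible when the variant
#' retains 3 or fewer observations, and the trimming cell is absent when
#' the variant has 10 or fewer observations.
#'
#' @param config the base `bop_run_config`.
#' @param grid named list of variants (include e.g. `base = list()` for the
#'   base cell).
#' @return data frame with one row per (variant, trimming) cell: `n_obs`,
#'   `feasible`, `ros` (NA when the fixed-effects interval crosses the
#'   null), `stars`.
#' @export
run_sensitivity_grid <- function(config, grid) {
  stopifnot(inherits(config, "bop_run_config"))
  if (length(grid) == 0L) stop("empty sensitivity grid", call. = FALSE)
  if (is.null(names(grid)) || any(names(grid) == "")) {
    stop("every grid variant must be named", call. = FALSE)
  }
  rows <- list()
  for (vn in names(grid)) {
    vcfg <- config
    for (fld in names(grid[[vn]])) vcfg[[fld]] <- grid[[vn]][[fld]]
    vcfg$out_dir <- NULL
    obs <- .apply_filters(.load_input(vcfg), vcfg$filters)
    n <- nrow(obs)
    for (trim in c(TRUE, FALSE)) {
      if (trim && n <= 10L) next  # trimming cell undefined at small n
      feasible <- n > 3L
      row <- data.frame(
        variant = vn, trimming = trim, n_obs = n, feasible = feasible,
        ros = NA_real_, stars = NA_integer_, stringsAsFactors = FALSE)
      if (feasible) {
        cfg_i <- vcfg
        cfg_i$trim_fraction <- if (trim) 0.10 else 0
        rs <- run_model(cfg_i)
        row$ros <- rs$ros
        row$stars <- rs$stars
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Forest plot of an analyzed observation set
#'
#' Per-observation effect and 95% CI on the ratio scale (log-spaced axis),
#' trimmed points marked, overlap-downweighted points marked, the pooled
#' mean line, both uncertainty-interval bands, and the BPRF line when
#' assigned.
#'
#' @param summary a `bop_risk_summary` from [run_model()].
#' @return a ggplot object.
#' @export
plot_forest <- function(summary) {
  obs <- summary$observations
  df <- data.frame(
    obs_id = obs$obs_id,
    effect = obs$effect,
    lower = obs$ci_lower,
    upper = obs$ci_upper,
    trimmed = summary$fit$trim_weights[obs$obs_id] == 0,
    overlap = !is.na(obs$overlap_group)
  )
  df$label <- ifelse(df$overlap, paste0(df$obs_id, "*"), df$obs_id)
  df$label <- factor(df$label, levels = rev(df$label))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$effect, y = .data$label)) +
    ggplot2::annotate("rect",
      xmin = summary$ui_with_gamma[1], xmax = summary$ui_with_gamma[2],
      ymin = -Inf, ymax = Inf, fill = "steelblue", alpha = 0.15) +
    ggplot2::annotate("rect",
      xmin = summary$ui_no_gamma[1], xmax = summary$ui_no_gamma[2],
      ymin = -Inf, ymax = Inf, fill = "steelblue", alpha = 0.30) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = summary$rr, colour = "blue") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
      height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$trimmed,
      colour = .data$trimmed), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4),
      guide = "none") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
      `TRUE` = "red"), guide = "none") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "relative risk (log scale)", y = NULL,
      title = sprintf("%s: RR %.2f", summary$outcome, summary$rr))
  if (!is.na(summary$bprf)) {
    p <- p + ggplot2::geom_vline(xintercept = summary$bprf, colour = "red")
  }
  p
}

#' Modified funnel plot of an analyzed observation set
#'
#' @inheritParams plot_forest
#' @return a ggplot object.
#' @export
plot_funnel <- function(summary) {
  pts <- funnel_points(summary$observations, summary$fit, summary$het)
  lines <- attr(pts, "lines")
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$residual_mean,
    y = .data$residual_sd)) +
    ggplot2::annotate("rect",
      xmin = lines$ui_with_gamma[1] - lines$mean,
      xmax = lines$ui_with_gamma[2] - lines$mean,
      ymin = -Inf, ymax = Inf, fill = "steelblue", alpha = 0.15) +
    ggplot2::annotate("rect",
      xmin = lines$ui_no_gamma[1] - lines$mean,
      xmax = lines$ui_no_gamma[2] - lines$mean,
      ymin = -Inf, ymax = Inf, fill = "steelblue", alpha = 0.30) +
    ggplot2::geom_vline(xintercept = -lines$mean, linetype = "dotted",
      colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "blue") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$trimmed,
      colour = .data$trimmed), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4),
      guide = "none") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
      `TRUE` = "red"), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "residual log RR", y = "total residual SD",
      title = sprintf("%s: modified funnel", summary$outcome))
  if (!is.null(lines$bprf)) {
    p <- p + ggplot2::geom_vline(xintercept = lines$bprf - lines$mean,
      colour = "red")
  }
  p
}

#' Write the report bundle for a completed run
#'
#' Emits the summary-table row as CSV and JSON, the funnel point table, a
#' config echo, a run log, and forest/funnel figures (PNG always; SVG when
#' the cairo device is available).
#'
#' @param summary a `bop_risk_summary` from [run_model()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
render_report <- function(summary, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  row <- risk_summary_row(summary)
  utils::write.csv(row, file.path(out_dir, "summary.csv"),
    row.names = FALSE)
  jsonlite::write_json(as.list(row), file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  pts <- funnel_points(summary$observations, summary$fit, summary$het)
  utils::write.csv(pts, file.path(out_dir, "funnel_points.csv"),
    row.names = FALSE)
  if (!is.null(summary$config)) {
    cfg <- summary$config
    cfg$input <- if (is.character(cfg$input)) cfg$input else "<in-memory>"
    cfg$registry <- if (is.character(cfg$registry)) cfg$registry else
      names(.resolve_registry(summary$config, summary$observations))
    jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
      auto_unbox = TRUE, pretty = TRUE, na = "null", force = TRUE)
  }
  log_lines <- c(
    sprintf("outcome: %s", summary$outcome),
    sprintf("n_obs: %d (used %d), n_studies: %d",
      length(summary$fit$trim_weights), summary$n_obs, summary$n_studies),
    sprintf("trimming: %s",
      if (any(summary$fit$trim_weights == 0)) sprintf("trimmed %d row(s)",
        sum(summary$fit$trim_weights == 0)) else "none"),
    sprintf("covariates eligible: %s",
      paste(summary$selection$eligible %||% character(), collapse = ", ")),
    sprintf("covariates selected: %s",
      paste(summary$selected_covariates, collapse = ", ")),
    sprintf("star gate (no-gamma UI excludes 1): %s", summary$stars > 0),
    sprintf("seed: %s", summary$config$seed %||% NA),
    sprintf("bopmeta version: %s",
      as.character(utils::packageVersion("bopmeta")))
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))

  save_plot <- function(plot, stem) {
    grDevices::png(file.path(out_dir, paste0(stem, ".png")),
      width = 900, height = 700, res = 110)
    print(plot)
    grDevices::dev.off()
    if (capabilities("cairo")) {
      grDevices::svg(file.path(out_dir, paste0(stem, ".svg")),
        width = 8, height = 6)
      print(plot)
      grDevices::dev.off()
    }
  }
  save_plot(plot_forest(summary), "forest")
  save_plot(plot_funnel(summary), "funnel")
  invisible(out_dir)
}

#' Published summary estimates for chewing tobacco and seven outcomes
#'
#' The published per-outcome summary table shipped with the package:
#' pooled RR with both 95% uncertainty intervals, BPRF, ROS, star rating,
#' publication-bias flag, study count and selected bias covariates for
#' stroke, ischemic heart disease and five head and neck cancers. Used as
#' the desk-scale input for consistency checks of the BPRF/ROS arithmetic.
#'
#' @return data frame of the published estimates.
#' @export
published_estimates <- function() {
  path <- system.file("extdata", "chewing_tobacco_published_estimates.csv",
    package = "bopmeta", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
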