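#' Observation tables for log-relative-risk meta-analysis
#'
#' An observation set is a plain data frame (class `bop_obs`) with one row per
#' extracted effect size, carrying the reported ratio-scale estimate and its
#' 95% interval, the harmonized log effect and standard error, binary bias
#' covariates (columns prefixed `cv_`), and study / overlap-group membership.
#' Relative risks, odds ratios and hazard ratios are pooled on the natural-log
#' scale without conversion; the `measure` column is retained so users can
#' filter by effect measure.
#'
#' @name bop_obs
#' @keywords internal
NULL

.MEASURES <- c("RR", "OR", "HR")
.SEXES <- c("both", "male", "female")
.TEMPORALITY <- c("current", "ever", "unspecified")
.DESIGNS <- c(
  "prospective_cohort", "retrospective_cohort", "case_cohort",
  "nested_case_control", "case_control"
)

.SCHEMA <- c(
  "obs_id", "study_id", "measure", "effect", "ci_lower", "ci_upper",
  "overlap_group", "sex", "exposure_definition", "exposure_temporality",
  "outcome_aggregate", "sample_size", "design"
)

#' Names of the bias-covariate columns of an observation set
#'
#' @param x an observation data frame.
#' @return character vector of `cv_`-prefixed column names.
#' @export
covariate_columns <- function(x) {
  grep("^cv_", names(x), value = TRUE)
}

#' Standard error of a log effect from a ratio-scale confidence interval
#'
#' Inverts the usual log-normal interval: `(log(upper) - log(lower)) / (2 z)`
#' with `z` the standard-normal quantile at `(1 + level) / 2`. A degenerate
#' interval (`lower == upper`) gives 0.
#'
#' @param lower,upper positive interval bounds on the ratio scale.
#' @param level interval coverage, default 0.95.
#' @return standard error of the log effect (vectorized).
#' @examples
#' se_from_interval(1.11, 1.93) # 0.1411
#' @export
se_from_interval <- function(lower, upper, level = 0.95) {
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower <= 0) || any(upper <= 0)) {
    stop("interval bounds must be positive and finite", call. = FALSE)
  }
  if (any(lower > upper)) stop("lower must not exceed upper", call. = FALSE)
  if (any(level <= 0 | level >= 1)) stop("level must be in (0,1)", call. = FALSE)
  z <- stats::qnorm((1 + level) / 2)
  (log(upper) - log(lower)) / (2 * z)
}

#' Log odds ratio and standard error from a 2x2 table
#'
#' Convenience helper for studies reporting only cell counts: returns the
#' standard `log(a d / (b c))` with SE `sqrt(1/a + 1/b + 1/c + 1/d)`.
#'
#' @param a,b,c,d positive cell counts (exposed case, exposed control,
#'   unexposed case, unexposed control).
#' @return list with `log_effect` and `log_se`.
#' @export
log_or_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop("all four cell counts must be positive", call. = FALSE)
  }
  list(
    log_effect = log(a * d / (b * c)),
    log_se = sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  )
}

#' Harmonize raw effect-size records into an observation set
#'
#' Each input row must carry either a ratio-scale estimate with 95% bounds
#' (`effect`, `ci_lower`, `ci_upper`) or a log-scale pair (`log_effect`,
#' `log_se`); whichever is absent is filled from the other. The harmonized
#' `log_se` equals `raw_log_se` until [downweight_overlaps()] is applied.
#'
#' @param df data frame of raw records; missing schema columns are filled
#'   with defaults (`measure` "RR", `sex` "both", `design` "case_control",
#'   `exposure_temporality` "unspecified", `outcome_aggregate` 0).
#' @param outcome outcome label attached to the set.
#' @param level CI coverage used for the inversion unless a per-row
#'   `ci_level` column is present.
#' @param provenance free-text metadata.
#' @return a `bop_obs` data frame.
#' @export
harmonize_observations <- function(df, outcome = "outcome", level = 0.95,
                                   provenance = "") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no observations to harmonize", call. = FALSE)

  defaults <- list(
    measure = "RR", sex = "both", design = "case_control",
    exposure_definition = "chewing tobacco",
    exposure_temporality = "unspecified",
    outcome_aggregate = 0L, overlap_group = NA_character_,
    sample_size = NA_integer_
  )
  for (nm in names(defaults)) {
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  }
  if (is.null(df$obs_id)) df$obs_id <- sprintf("obs%04d", seq_len(nrow(df)))
  if (is.null(df$study_id)) df$study_id <- df$obs_id
  df$obs_id <- as.character(df$obs_id)
  df$study_id <- as.character(df$study_id)
  df$overlap_group <- as.character(df$overlap_group)
  df$overlap_group[!is.na(df$overlap_group) & df$overlap_group == ""] <- NA

  lev <- if (!is.null(df$ci_level)) df$ci_level else rep(level, nrow(df))

  has_ratio <- !is.null(df$effect) && !is.null(df$ci_lower) &&
    !is.null(df$ci_upper)
  has_log <- !is.null(df$log_effect) && !is.null(df$log_se)
  if (!has_ratio && !has_log) {
    stop("need either (effect, ci_lower, ci_upper) or (log_effect, log_se)",
      call. = FALSE)
  }
  if (has_log) {
    # stored log fields are authoritative (they may carry overlap-inflated
    # SEs); ratio fields are only derived when absent
    if (!has_ratio) {
      z <- stats::qnorm((1 + lev) / 2)
      df$effect <- exp(df$log_effect)
      df$ci_lower <- exp(df$log_effect - z * df$raw_log_se %||% df$log_se)
      df$ci_upper <- exp(df$log_effect + z * df$raw_log_se %||% df$log_se)
    }
  } else {
    bad <- !is.finite(df$effect) | df$effect <= 0
    if (any(bad)) {
      stop("non-positive effect in rows: ",
        paste(df$obs_id[bad], collapse = ", "), call. = FALSE)
    }
    df$log_effect <- log(df$effect)
    df$log_se <- se_from_interval(df$ci_lower, df$ci_upper, lev)
  }
  if (is.null(df$raw_log_se)) df$raw_log_se <- df$log_se

  cv <- covariate_columns(df)
  keep <- c(.SCHEMA, cv, "log_effect", "log_se", "raw_log_se")
  df <- df[, keep]
  structure(df,
    outcome = outcome, provenance = provenance,
    class = c("bop_obs", "data.frame")
  )
}

#' Read an observation table from CSV
#'
#' @param path CSV file with the documented schema (header row, one column
#'   per bias covariate prefixed `cv_`).
#' @param outcome outcome label; defaults to the file name stem.
#' @inheritParams harmonize_observations
#' @return a `bop_obs` data frame.
#' @export
read_observations <- function(path, outcome = NULL, level = 0.95) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(outcome)) outcome <- sub("\\.[^.]*$", "", basename(path))
  harmonize_observations(df, outcome = outcome, level = level,
    provenance = path)
}

#' Write an observation table to CSV
#'
#' Emits the input schema plus `log_effect`, `log_se`, `raw_log_se`,
#' preserving numeric fields to full double precision.
#'
#' @param x a `bop_obs` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_observations <- function(x, path) {
  out <- as.data.frame(x)
  num <- vapply(out, is.numeric, logical(1))
  # format() at 17 digits keeps the ratio-scale round trip bit-exact
  out[num] <- lapply(out[num], function(v) {
    s <- formatC(v, digits = 17, format = "g")
    s[is.na(v)] <- NA
    trimws(s)
  })
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Inflate standard errors of overlapping observations
#'
#' Observations in one overlap group come from the same (non-mutually
#' exclusive) study sample; leaving them independent over-represents that
#' sample. For a group of size k each member's SE is inflated so the group's
#' combined inverse-variance information equals that of a single average
#' member: `log_se <- raw_log_se * sqrt(k)` (the default); `factor = "k"`
#' scales the SE by k instead. Singleton groups and ungrouped rows are
#' unchanged; `raw_log_se` is preserved.
#'
#' @param obs_set a `bop_obs` data frame.
#' @param factor `"sqrt_k"` (default) or `"k"`.
#' @return the observation set with adjusted `log_se`.
#' @export
downweight_overlaps <- function(obs_set, factor = c("sqrt_k", "k")) {
  factor <- match.arg(factor)
  g <- obs_set$overlap_group
  obs_set$log_se <- obs_set$raw_log_se
  grouped <- !is.na(g)
  if (!any(grouped)) return(obs_set)
  for (gid in unique(g[grouped])) {
    idx <- which(!is.na(g) & g == gid)
    if (length(unique(obs_set$study_id[idx])) > 1L) {
      stop("overlap group '", gid, "' spans multiple studies", call. = FALSE)
    }
    k <- length(idx)
    if (k > 1L) {
      mult <- if (factor == "sqrt_k") sqrt(k) else k
      obs_set$log_se[idx] <- obs_set$raw_log_se[idx] * mult
    }
  }
  obs_set
}

#' Validate an observation set
#'
#' Checks the row- and set-level invariants (positivity and ordering of the
#' ratio-scale interval, log/ratio consistency, SE positivity and the
#' downweighting direction, 0/1 covariates, enum levels, obs_id uniqueness,
#' overlap groups confined to one study). Issues are returned, never raised.
#'
#' @param obs_set a `bop_obs` data frame.
#' @return data frame with columns `obs_id`, `field`, `rule`; zero rows when
#'   the set is well formed.
#' @export
validate_observations <- function(obs_set) {
  issues <- list()
  add <- function(id, field, rule) {
    issues[[length(issues) + 1L]] <<- data.frame(
      obs_id = id, field = field, rule = rule, stringsAsFactors = FALSE)
  }
  x <- obs_set
  for (i in seq_len(nrow(x))) {
    id <- x$obs_id[i]
    if (!is.finite(x$effect[i]) || x$effect[i] <= 0 ||
        !is.finite(x$ci_lower[i]) || x$ci_lower[i] <= 0 ||
        !is.finite(x$ci_upper[i]) || x$ci_upper[i] <= 0) {
      add(id, "effect", "effect and CI bounds must be positive")
      next
    }
    if (x$ci_lower[i] > x$effect[i] || x$effect[i] > x$ci_upper[i]) {
      add(id, "ci", "must satisfy ci_lower <= effect <= ci_upper")
    }
    if (abs(x$log_effect[i] - log(x$effect[i])) > 1e-12) {
      add(id, "log_effect", "log_effect must equal log(effect)")
    }
    if (!is.finite(x$log_se[i]) || x$log_se[i] < 0) {
      add(id, "log_se", "log_se must be non-negative")
    } else if (x$log_se[i] < x$raw_log_se[i] - 1e-12) {
      add(id, "log_se", "log_se must not be below raw_log_se")
    }
    if (!x$measure[i] %in% .MEASURES) add(id, "measure", "unknown measure")
    if (!x$sex[i] %in% .SEXES) add(id, "sex", "unknown sex level")
    if (!x$exposure_temporality[i] %in% .TEMPORALITY) {
      add(id, "exposure_temporality", "unknown temporality level")
    }
    if (!x$design[i] %in% .DESIGNS) add(id, "design", "unknown design")
    if (!x$outcome_aggregate[i] %in% c(0, 1)) {
      add(id, "outcome_aggregate", "must be 0 or 1")
    }
    for (cv in covariate_columns(x)) {
      if (!x[[cv]][i] %in% c(0, 1)) add(id, cv, "covariate must be 0 or 1")
    }
  }
  dup <- x$obs_id[duplicated(x$obs_id)]
  for (id in unique(dup)) add(id, "obs_id", "obs_id must be unique")
  g <- x$overlap_group
  for (gid in unique(g[!is.na(g)])) {
    st <- unique(x$study_id[!is.na(g) & g == gid])
    if (length(st) > 1L) {
      add(gid, "overlap_group", "overlap group spans multiple studies")
    }
  }
  if (length(issues) == 0L) {
    return(data.frame(obs_id = character(), field = character(),
      rule = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' @export
print.bop_obs <- function(x, ...) {
  cat(sprintf(
    "<bop_obs> %d observations, %d studies, outcome '%s'\n",
    nrow(x), length(unique(x$study_id)),
    attr(x, "outcome") %||% "?"))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
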