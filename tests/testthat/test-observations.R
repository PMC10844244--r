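test_that("se_from_interval inverts the log-normal CI", {
  # (ln 1.93 - ln 1.11) / (2 * 1.959964)
  expect_equal(se_from_interval(1.11, 1.93), 0.141115, tolerance = 1e-5)
  expect_equal(se_from_interval(1, 1), 0)
  expect_equal(se_from_interval(exp(-qnorm(0.975)), exp(qnorm(0.975))), 1)

  # scale invariance: multiplying both bounds by c > 0 changes nothing
  for (c in c(0.01, 0.5, 7, 1e3)) {
    expect_equal(se_from_interval(1.11 * c, 1.93 * c),
      se_from_interval(1.11, 1.93))
  }
  expect_error(se_from_interval(-1, 2), "positive")
  expect_error(se_from_interval(0, 2), "positive")
  expect_error(se_from_interval(2, 1), "lower")
})

test_that("harmonize fills log fields from ratio fields and vice versa", {
  o <- harmonize_observations(data.frame(
    obs_id = c("a", "b", "c"), study_id = c("s1", "s2", "s3"),
    effect = c(2.0, 1.46, 1.0),
    ci_lower = c(1.0, 1.11, 0.5), ci_upper = c(4.0, 1.93, 2.0)))
  expect_equal(o$log_effect, c(log(2), log(1.46), 0))
  expect_equal(o$log_se, c(0.3536, 0.1411, 0.3536), tolerance = 1e-3)
  expect_equal(o$raw_log_se, o$log_se)

  # log route round-trips to a self-consistent ratio scale
  o2 <- make_obs(c(0.5, -0.2), c(0.1, 0.3))
  expect_equal(o2$effect, exp(o2$log_effect))
  expect_equal(se_from_interval(o2$ci_lower, o2$ci_upper), o2$log_se)

  expect_error(harmonize_observations(
    data.frame(obs_id = "a", study_id = "s", effect = 2)), "either")
  expect_error(harmonize_observations(data.frame(
    obs_id = "a", study_id = "s", effect = -1, ci_lower = 0.5,
    ci_upper = 2)), "non-positive")
})

test_that("2x2 helper matches the standard log-OR formulas", {
  r <- log_or_2x2(10, 20, 5, 40)
  expect_equal(r$log_effect, log(10 * 40 / (20 * 5)))
  expect_equal(r$log_se, sqrt(1 / 10 + 1 / 20 + 1 / 5 + 1 / 40))
  expect_error(log_or_2x2(0, 1, 1, 1), "positive")
})

test_that("overlap downweighting conserves group information", {
  # k = 1 unchanged
  o1 <- make_obs(0.1, 0.2, overlap_group = "g1")
  expect_equal(downweight_overlaps(o1)$log_se, 0.2)

  # k = 2 at raw 0.2 -> 0.2828...; k = 4 at raw 0.1 -> 0.2
  o2 <- make_obs(c(0, 0.1), c(0.2, 0.2), study = c(1, 1),
    overlap_group = "g")
  expect_equal(downweight_overlaps(o2)$log_se, rep(0.2 * sqrt(2), 2))
  o4 <- make_obs(rep(0, 4), rep(0.1, 4), study = rep(1, 4),
    overlap_group = "g")
  expect_equal(downweight_overlaps(o4)$log_se, rep(0.2, 4))

  # information identity: sum 1/se^2 after equals the mean single-member
  # information of the group, for heterogeneous raw SEs too
  set.seed(42)
  o <- make_obs(rnorm(6), runif(6, 0.05, 0.5),
    study = c(1, 1, 1, 2, 2, 3),
    overlap_group = c("gA", "gA", "gA", "gB", "gB", NA))
  d <- downweight_overlaps(o)
  for (g in c("gA", "gB")) {
    i <- !is.na(o$overlap_group) & o$overlap_group == g
    expect_equal(sum(1 / d$log_se[i]^2),
      mean(1 / o$raw_log_se[i]^2))
  }
  expect_equal(d$log_se[6], o$raw_log_se[6])
  expect_true(all(d$log_se >= d$raw_log_se - 1e-15))

  # the k-factor alternative scales variance by k^2
  dk <- downweight_overlaps(o, factor = "k")
  expect_equal(dk$log_se[1:3], o$raw_log_se[1:3] * 3)

  # a group spanning two studies is a hard error
  bad <- make_obs(c(0, 0), c(0.1, 0.1), study = c(1, 2),
    overlap_group = "g")
  expect_error(downweight_overlaps(bad), "spans multiple studies")
})

test_that("validate returns precise issue records, never raises", {
  ok <- harmonize_observations(make_schema_table())
  expect_identical(nrow(validate_observations(ok)), 0L)

  bad <- ok
  bad$ci_lower[2] <- bad$effect[2] * 1.5
  iss <- validate_observations(bad)
  expect_identical(iss$obs_id, "a2")
  expect_match(iss$rule, "ci_lower <= effect")

  dup <- ok
  dup$obs_id[2] <- dup$obs_id[1]
  iss <- validate_observations(dup)
  expect_true(any(grepl("unique", iss$rule)))

  cvbad <- ok
  cvbad$cv_aggregate_outcome[1] <- 2
  expect_true(any(grepl("0 or 1", validate_observations(cvbad)$rule)))
})

test_that("write/read round-trips the ratio scale to 12 significant digits", {
  obs <- harmonize_observations(make_schema_table())
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- read_observations(path, outcome = "roundtrip")
  for (col in c("effect", "ci_lower", "ci_upper", "log_effect", "log_se",
                "raw_log_se")) {
    expect_equal(back[[col]], obs[[col]], tolerance = 1e-12)
  }
  expect_identical(back$obs_id, obs$obs_id)
  expect_identical(back$overlap_group, obs$overlap_group)
  expect_identical(back$cv_maximally_adjusted, obs$cv_maximally_adjusted)
})
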