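test_that("coefficient of variation is exact, scale-invariant, and guarded", {
  expect_equal(cv_pct(c(1, 2, 3)), 50)
  expect_equal(cv_pct(rep(7, 5)), 0)
  x <- c(3, 9, 14, 2)
  expect_equal(cv_pct(x * 17), cv_pct(x), tolerance = 1e-12)
  expect_error(cv_pct(c(-1, 1)), "zero mean")
  expect_error(cv_pct(5), "at least 2")
})

test_that("ICC(2,1) equals the ANOVA mean-square formula on random tables", {
  set.seed(21)
  for (rep in 1:5) {
    y <- matrix(rnorm(20, 50, 5) + rep(rnorm(10, 0, 4), 2), 10, 2)
    r <- icc_2_1(y)
    df <- data.frame(y = as.vector(y), subj = factor(rep(1:10, 2)),
                     sess = factor(rep(1:2, each = 10)))
    ms <- summary(stats::aov(y ~ subj + sess, df))[[1]][, "Mean Sq"]
    oracle <- (ms[1] - ms[3]) /
      (ms[1] + (2 - 1) * ms[3] + (2 / 10) * (ms[2] - ms[3]))
    expect_equal(r$icc, oracle, tolerance = 1e-12)
  }
})

test_that("ICC(2,1) point estimate and CI reproduce an independently verified
           example", {
  # frozen after cross-checking this exact table against a second
  # implementation of the absolute-agreement ICC and its F-based interval
  rc <- build_reliability_cohort(10, 3, 0, 1, seed = 5)
  r <- icc_2_1(rc$table)
  expect_equal(r$icc, 0.812125, tolerance = 1e-5)
  expect_equal(r$ci_low, 0.348743, tolerance = 1e-4)
  expect_equal(r$ci_high, 0.951548, tolerance = 1e-4)
})

test_that("ICC degenerate and offset cases behave as absolute agreement
           demands", {
  y <- cbind(c(10, 20, 30, 40), c(10, 20, 30, 40))
  r <- icc_2_1(y)
  expect_equal(r$icc, 1)
  expect_equal(r$ci_low, 1)
  # constant offset between sessions is penalized (ICC < 1)
  y2 <- cbind(c(10, 20, 30, 40), c(12, 22, 32, 42))
  r2 <- icc_2_1(y2)
  expect_lt(r2$icc, 1)
  expect_gt(r2$icc, 0.8)
  expect_error(icc_2_1(cbind(c(1, 1, 1), c(1, 1, 1))), "zero total variance")
  expect_error(icc_2_1(cbind(1:2, 3:4)), "at least 3")
  expect_error(icc_2_1(cbind(c(1, NA, 3), c(1, 2, 3))), "missing")
})

test_that("the ICC estimator is consistent and near-unbiased at high
           reliability", {
  sig_for <- function(rho) sqrt(rho / (1 - rho))
  est95 <- vapply(1:200, function(i) {
    icc_2_1(build_reliability_cohort(10, sig_for(0.95), 0, 1,
                                     seed = 400 + i)$table)$icc
  }, numeric(1))
  expect_equal(mean(est95), 0.95, tolerance = 0.05 / 0.95)
  # small-sample bias shrinks with n at moderate reliability
  bias_n <- vapply(c(10, 100), function(n) {
    e <- vapply(1:100, function(i) {
      icc_2_1(build_reliability_cohort(n, sig_for(0.8), 0, 1,
                                       seed = 700 + i)$table)$icc
    }, numeric(1))
    abs(mean(e) - 0.8)
  }, numeric(1))
  expect_lt(bias_n[2], bias_n[1])
  expect_lt(bias_n[2], 0.02)
  # estimates order with the truth
  means <- vapply(c(0.5, 0.8, 0.95), function(rho) {
    mean(vapply(1:100, function(i) {
      icc_2_1(build_reliability_cohort(10, sig_for(rho), 0, 1,
                                       seed = 900 + i)$table)$icc
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("mean absolute difference uses the chosen denominator and is
           symmetric for the pair mean", {
  expect_equal(mean_abs_diff_pct(c(10, 20), c(10, 20)), 0)
  expect_equal(mean_abs_diff_pct(10, 9), 100 / 9.5, tolerance = 1e-12)
  expect_equal(mean_abs_diff_pct(9, 10), mean_abs_diff_pct(10, 9))
  expect_equal(mean_abs_diff_pct(10, 9, denominator = "first"), 10)
  expect_error(mean_abs_diff_pct(1, -1), "zero denominator")
})

test_that("the unpaired t-test matches hand computation and handles
           degenerate groups", {
  r <- unpaired_t(c(1, 2, 3), c(4, 5, 6), var_equal = TRUE)
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-9)  # -3.674
  expect_equal(r$df, 4)
  same <- unpaired_t(c(5, 5), c(5, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(unpaired_t(1, c(1, 2)), "n >= 2")
})

test_that("paired tables validate their structure", {
  expect_error(paired_table(1:2, 1:2, 1:2), "at least 3")
  expect_error(paired_table(1:3, 1:3, 1:2), "equal length")
  expect_error(paired_table(1:3, c(1, NA, 3), 1:3), "missing")
})

test_that("cohort reports aggregate, cross-check, and compare sexes", {
  bc <- build_cohort(seed = 14)
  rep <- make_cohort_report(bc$cohort)
  expect_identical(nrow(rep$table), 4L)
  expect_equal(rep$cross_checks$relative_volume_sums_pct, rep(100, 20),
               tolerance = 1e-9)
  # ratio-of-means vs mean-of-ratios PCSA both reported, and distinct objects
  expect_length(rep$cross_checks$pcsa_from_means_cm2, 4)
  expect_length(rep$cross_checks$pcsa_mean_of_ratios_cm2, 4)
  expect_true(all(c("subscapularis", "infraspinatus_plus_teres_minor") %in%
                    names(rep$cross_checks$subscapularis_vs_infra_plus_teres_cm2)))
  # injected sex effect on volume is detected
  volp <- rep$sex_comparison[rep$sex_comparison$parameter == "volume_cm3", ]
  expect_true(all(volp$male_mean > volp$female_mean))
  expect_true(all(volp$p < 0.05))

  broken <- bc$cohort[-3, ]  # one subject loses a muscle
  expect_error(make_cohort_report(broken), "inconsistent muscle sets")
})

test_that("report CSV writing applies table-style rounding", {
  bc <- build_cohort(seed = 14)
  rep <- make_cohort_report(bc$cohort)
  path <- withr::local_tempfile(fileext = ".csv")
  fmt <- write_cohort_report(rep, path)
  expect_true(file.exists(path))
  expect_match(fmt$volume_cm3[1], "^\\d+ \\+/- \\d+ \\(\\d+\\)$")
})
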