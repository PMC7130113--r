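make_two_posture_summary <- function(pss_unc = 10, pss_cro = 10,
                                     pct_unc = 0.95, pct_cro = 0.95,
                                     jnd_cro = 67.5) {
  data.frame(subject_id = "s01", posture = c("uncrossed", "crossed"),
             slope = -0.01, intercept = 0.1, r_squared = 0.9,
             pss_ms = c(pss_unc, pss_cro), jnd_signed_ms = -67.5,
             jnd_mag_ms = c(67.5, jnd_cro),
             pct_correct_200 = c(pct_unc, pct_cro), stringsAsFactors = FALSE)
}

test_that("exclusion criteria are applied per the two rules", {
  # crossed PSS of 450 ms fails criterion 1 in that posture only
  out <- apply_exclusion(make_two_posture_summary(pss_cro = 450))
  expect_equal(out$included, c(TRUE, FALSE))
  expect_equal(out$criterion1_pass, c(TRUE, FALSE))
  # a PSS of -399 with good performance everywhere is included
  out <- apply_exclusion(make_two_posture_summary(pss_unc = -399))
  expect_true(all(out$included))
  # performance at/below 60% in one posture excludes both postures
  out <- apply_exclusion(make_two_posture_summary(pct_unc = 0.55))
  expect_false(any(out$included))
  expect_false(any(out$criterion2_pass))
  expect_true(all(out$criterion1_pass))
  # the boundary itself fails (performance must be strictly above 60%)
  out <- apply_exclusion(make_two_posture_summary(pct_cro = 0.60))
  expect_false(any(out$included))
  # |PSS| >= 400 is never included
  out <- apply_exclusion(make_two_posture_summary(pss_cro = -400))
  expect_false(out$included[out$posture == "crossed"])
})

test_that("the JND sensitivity flag marks magnitudes above 200 ms", {
  out <- apply_exclusion(make_two_posture_summary(jnd_cro = 933.01))
  expect_equal(out$sensitivity_pass, c(TRUE, FALSE))
  expect_equal(apply_exclusion(make_two_posture_summary(jnd_cro = 200))$
                 sensitivity_pass, c(TRUE, TRUE))
})

test_that("a missing posture fails the both-posture performance criterion", {
  solo <- make_two_posture_summary()[1, ]
  out <- apply_exclusion(solo)
  expect_false(out$included)
  expect_false(out$criterion2_pass)
})

test_that("analysis table keeps excluded rows flagged and covariates joined", {
  fx <- make_summary_fixture(n = 45, crossed_pss_violations = 1:10)
  tab <- build_analysis_table(fx$summaries, fx$meta)
  expect_equal(nrow(tab), 90L)
  expect_equal(sum(tab$posture == "crossed" & !tab$included), 10L)
  expect_equal(sum(tab$posture == "uncrossed" & !tab$included), 0L)
  expect_true(all(c("group", "temp_diff_c", "temp_imputed") %in% names(tab)))
  # the excluded rows are exactly the planted subjects
  planted <- sprintf("s%02d", 1:10)
  expect_setequal(tab$subject_id[tab$posture == "crossed" & !tab$included],
                  planted)
  expect_error(build_analysis_table(fx$summaries,
                                    fx$meta[-1, , drop = FALSE]),
               "absent")
})

test_that("imputed temperatures are carried into the analysis table", {
  fx <- make_summary_fixture(n = 6)
  fx$meta$temp_diff_c <- c(0.2, 0.6, NA, 0.1, 0.2, 0.4)
  tab <- build_analysis_table(fx$summaries, fx$meta)
  filled <- tab[tab$subject_id == "s03", ]
  expect_true(all(filled$temp_imputed))
  expect_true(all(!is.na(filled$temp_diff_c)))
})

test_that("exclusion proportions feed the chi-squared comparison", {
  fx <- make_summary_fixture(n = 45, crossed_pss_violations = 1:10)
  tab <- build_analysis_table(fx$summaries, fx$meta)
  res <- exclusion_chi_square(tab)
  expect_equal(res$statistic, 11.25, tolerance = 1e-12)
})

test_that("group-level PSS tests cover every included group x posture cell", {
  fx <- make_summary_fixture(n = 45)
  # give the PSS values some spread so the t-test is defined
  set.seed(61)
  fx$summaries$pss_ms <- rnorm(90, 0, 30)
  tab <- build_analysis_table(fx$summaries, fx$meta)
  tests <- group_pss_tests(tab)
  expect_equal(nrow(tests), 6L)
  expect_equal(sum(tests$n), 90L)
  expect_true(all(tests$df == tests$n - 1))
})

test_that("recovery is exact for noiseless symmetric observers and reproducible", {
  rec <- recovery_experiment(pss_grid = 0, sigma = 1e-6, n_sims = 5,
                             seed = 71)
  expect_equal(rec$pss_bias, 0, tolerance = 1e-6)
  expect_equal(rec$pss_rmse, 0, tolerance = 1e-6)
  # away from zero (and off the design SOAs) a noiseless observer is fully
  # deterministic: every replicate gives the same estimate, so RMSE
  # collapses onto |bias|
  rec32 <- recovery_experiment(pss_grid = 32, sigma = 1e-6, n_sims = 5,
                               seed = 72)
  expect_equal(rec32$pss_rmse, abs(rec32$pss_bias), tolerance = 1e-9)
  expect_identical(recovery_experiment(pss_grid = 10, n_sims = 5, seed = 3),
                   recovery_experiment(pss_grid = 10, n_sims = 5, seed = 3))
  rec2 <- recovery_experiment(pss_grid = c(-20, 0, 20), n_sims = 4, seed = 1)
  expect_equal(nrow(rec2), 3L)
  expect_true(all(rec2$pss_rmse >= abs(rec2$pss_bias) - 1e-12))
})
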