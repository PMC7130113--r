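test_that("aggregation maps trials into the affected frame correctly", {
  # affected = left, left stimulated first (soa -200), reported left first:
  # an affected-first report at u = -200
  one <- data.frame(subject_id = "s01", block = 1L, trial_index = 1L,
                    posture = "uncrossed", soa_ms = -200,
                    response = "left_first", stringsAsFactors = FALSE)
  tab <- aggregate_proportions(one, "left")
  expect_equal(tab$u, -200)
  expect_equal(tab$n_affected_first, 1L)
  expect_equal(tab$p, 1)
  # the same physical trial for a right-affected subject is unaffected-first
  # at u = +200
  tab_r <- aggregate_proportions(one, "right")
  expect_equal(tab_r$u, 200)
  expect_equal(tab_r$n_affected_first, 0L)

  twelve <- data.frame(posture = "uncrossed", soa_ms = 55,
                       response = rep(c("left_first", "right_first"), 6),
                       stringsAsFactors = FALSE)
  expect_equal(aggregate_proportions(twelve, "left")$p, 0.5)
})

test_that("a full simulated subject yields 10 rows of 12 trials per posture", {
  trials <- simulate_subject(observer(0, 100), tiny_schedule(), seed = 6)
  tab <- aggregate_proportions(trials, "left")
  expect_equal(nrow(tab), 20L)
  expect_equal(as.vector(table(tab$posture)), c(10L, 10L))
  expect_true(all(tab$n_trials == 12L))
  expect_error(aggregate_proportions(trials[0, ], "left"), "empty")
})

test_that("probit transform matches the inverse-normal oracle", {
  tab <- data.frame(posture = "uncrossed", u = c(-55, 0, 55),
                    n_trials = 12L, n_affected_first = c(12L, 6L, 0L),
                    p = c(1, 0.5, 0))
  out <- probit_transform(tab)
  expect_equal(out$z[2], 0)
  expect_equal(out$z[1], qnorm(23 / 24))
  expect_equal(out$z[1], 1.732, tolerance = 1e-3)
  expect_equal(out$z[3], qnorm(1 / 24))
  # interior proportions pass through untouched under the default rule
  tab2 <- data.frame(posture = "uncrossed", u = 100, n_trials = 12L,
                     n_affected_first = NA, p = pnorm(-1))
  expect_equal(probit_transform(tab2)$z, -1, tolerance = 1e-12)
  # no clipping refuses saturated rows
  expect_error(probit_transform(tab, clip = "none"), "infinite")
  # fixed-epsilon rule
  out3 <- probit_transform(tab, clip = 0.01)
  expect_equal(out3$z[1], qnorm(0.99))
})

test_that("probit line fit equals the normal-equations oracle", {
  expect_equal(
    unclass(fit_probit_line(data.frame(u = c(-100, 0, 100),
                                       z = c(1, 0, -1))))[c("slope", "intercept")],
    list(slope = -0.01, intercept = 0))
  pts <- data.frame(u = c(-50, -10, 30, 80), z = (50 - c(-50, -10, 30, 80)) / 100)
  fit <- fit_probit_line(pts)
  expect_equal(fit$slope, -0.01, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.5, tolerance = 1e-12)
  set.seed(23)
  for (i in 1:25) {
    u <- sample(soa_levels(), 6)
    z <- rnorm(6)
    fit <- fit_probit_line(data.frame(u = u, z = z))
    oracle <- ls_oracle(u, z)
    expect_equal(fit$slope, unname(oracle["slope"]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(oracle["intercept"]), tolerance = 1e-10)
  }
  expect_error(fit_probit_line(data.frame(u = c(10, 10), z = c(0, 1))),
               "distinct")
})

test_that("PSS and JND derive from the fitted line", {
  fit <- structure(list(slope = -0.01, intercept = 0.5, n_points = 10,
                        r_squared = 1), class = "toj_linefit")
  expect_equal(compute_pss(fit), 50)
  fit$intercept <- 0
  expect_equal(compute_pss(fit), 0)
  fit$slope <- -0.00675
  jnd <- compute_jnd(fit)
  expect_equal(jnd$jnd_signed, -100)
  expect_equal(jnd$jnd_magnitude, 100)
  fit$slope <- 0
  expect_warning(pss <- compute_pss(fit), "undefined")
  expect_true(is.na(pss))
})

test_that("0.675/slope agrees with the quartile-crossing JND formula", {
  set.seed(3)
  for (i in 1:20) {
    slope <- runif(1, -0.05, -0.002)
    fit <- structure(list(slope = slope, intercept = runif(1, -1, 1),
                          n_points = 10, r_squared = 1),
                     class = "toj_linefit")
    jnd <- compute_jnd(fit)$jnd_magnitude
    u25 <- (qnorm(0.25) - fit$intercept) / slope
    u75 <- (qnorm(0.75) - fit$intercept) / slope
    alt <- abs(u25 - u75) / 2
    expect_lt(abs(jnd - alt) / alt, 0.001)
  }
})

test_that("exact observer probabilities round-trip to the true parameters", {
  # the probit of a cumulative normal is exactly linear, so the pipeline is
  # an identity on lapse-free model probabilities
  set.seed(11)
  for (i in 1:10) {
    pss <- runif(1, -150, 150)
    sigma <- runif(1, 40, 250)
    obs <- observer(pss, sigma)
    u <- as.numeric(soa_levels())
    tab <- data.frame(posture = "uncrossed", u = u, n_trials = 12L,
                      n_affected_first = NA,
                      p = response_probability(obs, u, "uncrossed"))
    fit <- fit_probit_line(probit_transform(tab, clip = "none"))
    expect_equal(compute_pss(fit), pss, tolerance = 1e-9)
    expect_equal(compute_jnd(fit)$jnd_magnitude, 0.675 * sigma,
                 tolerance = 1e-9)
    expect_equal(compute_jnd(fit)$jnd_signed, -0.675 * sigma,
                 tolerance = 1e-9)
  }
})

test_that("percent correct scores anatomical truth at the largest SOA", {
  trials <- simulate_subject(observer(0, 1e-9), tiny_schedule(), seed = 2)
  expect_equal(percent_correct_at(trials, 200), 1)
  # noiseless observer with |pss| < 200 is still perfect at 200 ms
  trials2 <- simulate_subject(observer(150, 1e-9), tiny_schedule(), seed = 2)
  expect_equal(percent_correct_at(trials2, 200), 1)
  # sigma = 100, pss = 0: expected accuracy pnorm(2) at |SOA| = 200
  sched <- data.frame(block = 1L, trial_index = 1:2000,
                      posture = "uncrossed", soa_ms = rep(c(-200, 200), 1000))
  trials3 <- simulate_subject(observer(0, 100), sched, seed = 13)
  p <- pnorm(2)
  expect_lt(abs(percent_correct_at(trials3, 200) - p),
            3 * sqrt(p * (1 - p) / 2000))
  expect_error(percent_correct_at(trials, 123), "no trials")
})

test_that("subject summaries are invariant under left/right relabeling", {
  sched <- tiny_schedule()
  trials <- simulate_subject(observer(40, 120, crossed_sigma_factor = 2,
                                      affected_side = "left"), sched, seed = 21)
  mirrored <- trials
  mirrored$soa_ms <- -trials$soa_ms
  mirrored$response <- ifelse(trials$response == "left_first",
                              "right_first", "left_first")
  a <- fit_subject(trials, "left")
  b <- fit_subject(mirrored, "right")
  expect_equal(a$pss_ms, b$pss_ms)
  expect_equal(a$jnd_mag_ms, b$jnd_mag_ms)
  expect_equal(a$pct_correct_200, b$pct_correct_200)
  expect_equal(nrow(a), 2L)
  expect_equal(sort(a$posture), c("crossed", "uncrossed"))
})

test_that("PSS estimates are unbiased at a true PSS of zero", {
  rec <- recovery_experiment(pss_grid = 0, sigma = 100, n_sims = 200,
                             seed = 31)
  expect_lt(abs(rec$pss_bias), 3 * rec$pss_mc_se)
})
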