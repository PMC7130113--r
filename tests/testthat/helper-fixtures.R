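# Shared in-code fixtures: small observers, schedules and a crafted cohort
# summary table with planted exclusion violations.

tiny_schedule <- function(seed = 1) build_trial_schedule("uncrossed", seed)

# Per-subject summary + metadata for `n` subjects with planted violations:
#  - `crossed_pss_violations` subjects get |PSS| >= 400 in the crossed posture
#    (criterion 1),
#  - `crossed_pct_violations` further subjects get crossed percent correct
#    at 200 ms below 0.60 (criterion 2, which knocks out both postures).
# Everyone else is clean in both postures.
make_summary_fixture <- function(n = 45, crossed_pss_violations = integer(),
                                 crossed_pct_violations = integer()) {
  ids <- sprintf("s%02d", seq_len(n))
  groups <- rep(c("crps", "shoulder", "wrist"), length.out = n)
  one <- function(id, posture, pss, pct) {
    data.frame(subject_id = id, posture = posture, slope = -0.01,
               intercept = pss * 0.01, r_squared = 0.95, pss_ms = pss,
               jnd_signed_ms = -67.5, jnd_mag_ms = 67.5,
               pct_correct_200 = pct, stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(n), function(i) {
    pss_cro <- if (i %in% crossed_pss_violations) 450 else 10
    pct_cro <- if (i %in% crossed_pct_violations) 0.55 else 0.95
    rbind(one(ids[i], "uncrossed", 5, 0.95),
          one(ids[i], "crossed", pss_cro, pct_cro))
  })
  summaries <- do.call(rbind, rows)
  meta <- data.frame(
    subject_id = ids, group = groups,
    affected_side = rep(c("left", "right"), length.out = n),
    pain_duration_months = 12, pain_intensity = 4,
    temp_diff_c = 0.3, stringsAsFactors = FALSE)
  list(summaries = summaries, meta = meta)
}

# independent least-squares oracle: explicit normal equations
ls_oracle <- function(u, z) {
  n <- length(u)
  sxx <- sum(u^2) - sum(u)^2 / n
  sxy <- sum(u * z) - sum(u) * sum(z) / n
  slope <- sxy / sxx
  intercept <- mean(z) - slope * mean(u)
  c(intercept = intercept, slope = slope)
}

# independent 2x2 Pearson chi-square oracle, written from the textbook formula
chisq_oracle <- function(k1, n1, k2, n2) {
  a <- k1; b <- n1 - k1; c <- k2; d <- n2 - k2
  N <- n1 + n2
  N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}
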