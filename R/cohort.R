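#' Configuration for a synthetic patient cohort
#'
#' Defaults emulate the study design the package analyses: three unilateral
#' pain groups (CRPS, shoulder, wrist) of 14/15/16 subjects, each completing
#' 4 blocks x 60 trials with alternating posture. Subject-level PSS values are
#' generated from a linear model on the covariates,
#' `pss = intercept + beta_temp * temp_diff + beta_duration * pain_duration
#' (+ posture interactions) + subject noise`, with posture interactions adding
#' to the crossed-posture PSS only. The default covariate effects place the
#' temperature effect on the wrist group (+12.25 ms/degC), the posture x
#' temperature interaction on the shoulder group (-37.69 ms/degC) and a small
#' negative pain-duration effect on the wrist group (-0.74 ms/month); the
#' other coefficients are zero.
#'
#' @param group_sizes Named integer vector, subjects per group.
#' @param sigma Uncrossed psychometric spread in ms shared by all subjects.
#' @param crossed_sigma_factor Spread multiplier for the crossed posture.
#' @param lapse Lapse rate for all subjects.
#' @param pss_intercept Named numeric, per-group baseline PSS in ms.
#' @param beta_temp Named numeric, ms of PSS per degC of temperature
#'   difference (affected minus unaffected limb).
#' @param beta_temp_crossed Named numeric, additional temperature slope in the
#'   crossed posture (posture x temperature interaction).
#' @param beta_duration Named numeric, ms of PSS per month of pain duration.
#' @param beta_duration_crossed Named numeric, additional duration slope in
#'   the crossed posture.
#' @param subject_sd SD in ms of the subject-level random intercept added to
#'   both postures' true PSS.
#' @param duration_meanlog,duration_sdlog Named numerics, log-normal
#'   parameters of pain duration in months (defaults give group means of
#'   roughly 10, 24 and 24 months).
#' @param temp_mean,temp_sd Named numerics, normal parameters of the
#'   temperature difference in degC.
#' @param intensity_mean Named numeric, mean of the 0-10 pain-intensity score
#'   (drawn from a normal, rounded and clamped to 0-10).
#' @param n_missing_temp Named integer vector, how many subjects per group
#'   have a missing temperature difference (to exercise imputation).
#' @param seed Master seed; per-subject streams are derived as
#'   `seed + subject index` so subjects are independent but reproducible.
#' @return A list of class `toj_cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(crps = 14L, shoulder = 15L, wrist = 16L),
                          sigma = 100,
                          crossed_sigma_factor = 2.2,
                          lapse = 0.02,
                          pss_intercept = c(crps = 0, shoulder = 0, wrist = 0),
                          beta_temp = c(crps = 0, shoulder = 0, wrist = 12.25),
                          beta_temp_crossed = c(crps = 0, shoulder = -37.69, wrist = 0),
                          beta_duration = c(crps = 0, shoulder = 0, wrist = -0.74),
                          beta_duration_crossed = c(crps = 0, shoulder = 0, wrist = 0),
                          subject_sd = 50,
                          duration_meanlog = c(crps = 1.98, shoulder = 2.86, wrist = 2.86),
                          duration_sdlog = c(crps = 0.8, shoulder = 0.8, wrist = 0.8),
                          temp_mean = c(crps = 0.5, shoulder = 0.06, wrist = 0.5),
                          temp_sd = c(crps = 1.5, shoulder = 0.8, wrist = 1.2),
                          intensity_mean = c(crps = 5, shoulder = 4, wrist = 3),
                          n_missing_temp = c(crps = 2L, shoulder = 0L, wrist = 3L),
                          seed = 1L) {
  groups <- c("crps", "shoulder", "wrist")
  if (!all(groups %in% names(group_sizes)) || any(group_sizes < 1)) {
    stop("`group_sizes` must name crps, shoulder and wrist, all >= 1",
         call. = FALSE)
  }
  if (sigma <= 0 || subject_sd < 0 || any(temp_sd < 0) || any(duration_sdlog < 0)) {
    stop("variance parameters must be non-negative (sigma strictly positive)",
         call. = FALSE)
  }
  if (any(n_missing_temp[groups] > group_sizes[groups])) {
    stop("`n_missing_temp` cannot exceed the group size", call. = FALSE)
  }
  cfg <- list(group_sizes = group_sizes, sigma = sigma,
              crossed_sigma_factor = crossed_sigma_factor, lapse = lapse,
              pss_intercept = pss_intercept, beta_temp = beta_temp,
              beta_temp_crossed = beta_temp_crossed,
              beta_duration = beta_duration,
              beta_duration_crossed = beta_duration_crossed,
              subject_sd = subject_sd,
              duration_meanlog = duration_meanlog,
              duration_sdlog = duration_sdlog,
              temp_mean = temp_mean, temp_sd = temp_sd,
              intensity_mean = intensity_mean,
              n_missing_temp = n_missing_temp, seed = as.integer(seed))
  class(cfg) <- "toj_cohort_config"
  cfg
}

#' Simulate a full synthetic cohort
#'
#' Draws per-subject covariates from the configured distributions, computes
#' each subject's posture-specific true PSS from the covariate model, builds a
#' trial schedule per subject (start posture alternating by subject index for
#' counterbalancing) and simulates every trial.
#'
#' @param config A [cohort_config()].
#' @return A list with components:
#'   \describe{
#'     \item{meta}{data frame of subject metadata (`subject_id`, `group`,
#'       `affected_side`, `pain_duration_months`, `pain_intensity`,
#'       `temp_diff_c` with `NA` for missing, plus the generative
#'       `pss_true_uncrossed`, `pss_true_crossed`, `start_posture`).}
#'     \item{trials}{data frame of all trial records, one row per trial.}
#'   }
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(seed = 7))
#' nrow(coh$meta)    # 45 subjects
#' nrow(coh$trials)  # 45 * 240 trials
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "toj_cohort_config"))
  groups <- rep(c("crps", "shoulder", "wrist"),
                times = config$group_sizes[c("crps", "shoulder", "wrist")])
  n <- length(groups)
  ids <- sprintf("s%02d", seq_len(n))

  covs <- with_local_seed(config$seed, {
    side <- sample(c("left", "right"), n, replace = TRUE)
    dur <- stats::rlnorm(n, config$duration_meanlog[groups],
                         config$duration_sdlog[groups])
    temp <- stats::rnorm(n, config$temp_mean[groups], config$temp_sd[groups])
    pain <- pmin(10, pmax(0, round(stats::rnorm(n, config$intensity_mean[groups], 2))))
    noise <- stats::rnorm(n, 0, config$subject_sd)
    miss <- unlist(lapply(c("crps", "shoulder", "wrist"), function(g) {
      in_g <- which(groups == g)
      sample(in_g, config$n_missing_temp[[g]])
    }))
    list(side = side, dur = dur, temp = temp, pain = pain,
         noise = noise, miss = miss)
  })

  pss_unc <- config$pss_intercept[groups] +
    config$beta_temp[groups] * covs$temp +
    config$beta_duration[groups] * covs$dur +
    covs$noise
  pss_cro <- pss_unc +
    config$beta_temp_crossed[groups] * covs$temp +
    config$beta_duration_crossed[groups] * covs$dur

  start <- ifelse(seq_len(n) %% 2L == 1L, "uncrossed", "crossed")
  temp_obs <- covs$temp
  temp_obs[covs$miss] <- NA_real_

  meta <- data.frame(
    subject_id = ids, group = groups, affected_side = covs$side,
    pain_duration_months = covs$dur, pain_intensity = covs$pain,
    temp_diff_c = temp_obs,
    pss_true_uncrossed = unname(pss_unc),
    pss_true_crossed = unname(pss_cro),
    start_posture = start,
    stringsAsFactors = FALSE
  )

  trials <- vector("list", n)
  for (i in seq_len(n)) {
    sub_seed <- config$seed + i
    sched <- build_trial_schedule(start[i], seed = sub_seed)
    # posture-specific PSS: simulate with a posture-varying observer by
    # splitting the schedule, keeping one RNG stream per subject
    obs_u <- observer(pss_unc[i], config$sigma, config$crossed_sigma_factor,
                      config$lapse, covs$side[i])
    obs_c <- observer(pss_cro[i], config$sigma, config$crossed_sigma_factor,
                      config$lapse, covs$side[i])
    u <- soa_to_u(sched$soa_ms, covs$side[i])
    crossed <- sched$posture == "crossed"
    p_aff <- numeric(nrow(sched))
    p_aff[!crossed] <- response_probability(obs_u, u[!crossed], "uncrossed")
    p_aff[crossed] <- response_probability(obs_c, u[crossed], "crossed")
    aff_first <- with_local_seed(sub_seed, stats::runif(nrow(sched)) < p_aff)
    aff_label <- if (covs$side[i] == "left") "left_first" else "right_first"
    una_label <- if (covs$side[i] == "left") "right_first" else "left_first"
    trials[[i]] <- data.frame(
      subject_id = ids[i], block = sched$block,
      trial_index = sched$trial_index, posture = sched$posture,
      soa_ms = sched$soa_ms,
      response = ifelse(aff_first, aff_label, una_label),
      stringsAsFactors = FALSE
    )
  }
  list(meta = meta, trials = do.call(rbind, trials))
}

#' Impute missing temperature differences by the group median
#'
#' Replaces each missing `temp_diff_c` with the median of the non-missing
#' values of the subject's own group, and records which rows were imputed.
#'
#' @param meta Subject metadata data frame with columns `group` and
#'   `temp_diff_c`.
#' @return `meta` with missing `temp_diff_c` filled in and a logical
#'   `temp_imputed` column added.
#' @export
impute_temperature <- function(meta) {
  stopifnot(all(c("group", "temp_diff_c") %in% names(meta)))
  miss <- is.na(meta$temp_diff_c)
  for (g in unique(meta$group[miss])) {
    in_g <- meta$group == g
    donors <- meta$temp_diff_c[in_g & !miss]
    if (length(donors) == 0L) {
      stop(sprintf("group '%s' has no observed temperature difference to impute from", g),
           call. = FALSE)
    }
    meta$temp_diff_c[in_g & miss] <- stats::median(donors)
  }
  meta$temp_imputed <- miss
  meta
}
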