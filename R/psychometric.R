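#' Tabulate affected-hand-first proportions per SOA and posture
#'
#' Re-expresses every trial in the affected frame (`u` = lead time of the
#' unaffected hand, so `u > 0` means the unaffected hand was stimulated
#' first), then counts, for each distinct `u` within each posture, how often
#' the response named the affected hand as first.
#'
#' @param trials Trial records for a single subject: columns `posture`,
#'   `soa_ms` (signed, negative = left first) and `response`
#'   (`"left_first"`/`"right_first"`).
#' @param affected_side `"left"` or `"right"`.
#' @return Data frame with columns `posture`, `u` (ms), `n_trials`,
#'   `n_affected_first` and `p`.
#' @export
aggregate_proportions <- function(trials, affected_side = c("left", "right")) {
  affected_side <- match.arg(affected_side)
  if (nrow(trials) == 0L) stop("`trials` is empty", call. = FALSE)
  if ("subject_id" %in% names(trials) &&
      length(unique(trials$subject_id)) > 1L) {
    stop("`trials` must belong to a single subject", call. = FALSE)
  }
  u <- soa_to_u(trials$soa_ms, affected_side)
  aff_label <- if (affected_side == "left") "left_first" else "right_first"
  aff_first <- trials$response == aff_label
  agg <- stats::aggregate(
    cbind(n_trials = rep(1L, length(u)), n_affected_first = as.integer(aff_first)),
    by = list(posture = trials$posture, u = u), FUN = sum)
  agg <- agg[order(agg$posture, agg$u), , drop = FALSE]
  agg$p <- agg$n_affected_first / agg$n_trials
  rownames(agg) <- NULL
  agg
}

#' Probit-transform response proportions
#'
#' Converts each proportion into a z-score through the inverse standard
#' normal CDF. Observed proportions of exactly 0 or 1 have infinite probits,
#' so the default rule clamps proportions into `[1/(2n), 1 - 1/(2n)]` (with
#' `n` the row's trial count) before transforming; for count data this only
#' ever alters rows with 0 or n affected-first responses. Use `clip = "none"`
#' when feeding exact model probabilities, which never need correction.
#'
#' @param tab A proportion table from [aggregate_proportions()].
#' @param clip `"half_count"` (default), `"none"`, or a single numeric
#'   epsilon to clamp into `[eps, 1 - eps]`.
#' @return `tab` with columns `p_clipped` and `z` appended.
#' @export
probit_transform <- function(tab, clip = "half_count") {
  p <- tab$p
  if (identical(clip, "half_count")) {
    lo <- 1 / (2 * tab$n_trials)
    p <- pmin(pmax(p, lo), 1 - lo)
  } else if (is.numeric(clip)) {
    stopifnot_scalar_prob(clip, "clip")
    p <- pmin(pmax(p, clip), 1 - clip)
  } else if (!identical(clip, "none")) {
    stop('`clip` must be "half_count", "none", or a numeric epsilon',
         call. = FALSE)
  }
  if (any(p <= 0 | p >= 1)) {
    stop("proportions of 0 or 1 have infinite probits; choose a clip rule",
         call. = FALSE)
  }
  tab$p_clipped <- p
  tab$z <- stats::qnorm(p)
  tab
}

#' Fit the best-fitting straight line to probit scores
#'
#' Ordinary (unweighted) least squares of `z` on `u`. The slope and intercept
#' of this line carry the psychometric parameters: the PSS is where the line
#' crosses z = 0 and the JND is `0.675 / slope`.
#'
#' @param points Data frame with columns `u` and `z` (one posture's rows of a
#'   probit-transformed proportion table).
#' @return A list of class `toj_linefit` with `slope` (per ms), `intercept`
#'   (probit units), `n_points` and `r_squared`.
#' @export
fit_probit_line <- function(points) {
  if (length(unique(points$u)) < 2L) {
    stop("need at least two distinct u values to fit a line", call. = FALSE)
  }
  fit <- stats::lm(z ~ u, data = points)
  cf <- stats::coef(fit)
  ss_tot <- sum((points$z - mean(points$z))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  structure(
    list(slope = unname(cf[["u"]]), intercept = unname(cf[["(Intercept)"]]),
         n_points = nrow(points), r_squared = r2),
    class = "toj_linefit"
  )
}

#' Point of subjective simultaneity from a probit line
#'
#' `PSS = -intercept / slope`, the SOA at which the fitted line predicts a
#' 0.5 proportion of affected-hand-first reports. Because fitting happens in
#' the affected frame, a positive PSS always means the affected limb's
#' stimuli are prioritised, for either affected side.
#'
#' @param fit A [fit_probit_line()] result.
#' @return PSS in ms, or `NA` with a warning when the slope is zero.
#' @export
compute_pss <- function(fit) {
  stopifnot(inherits(fit, "toj_linefit"))
  if (fit$slope == 0) {
    warning("slope is zero; PSS undefined")
    return(NA_real_)
  }
  -fit$intercept / fit$slope
}

#' Just noticeable difference from a probit line
#'
#' `JND = 0.675 / slope`. The signed value is negative under the affected
#' frame (the line falls with increasing unaffected-hand lead); its magnitude
#' equals half the distance between the SOAs at which the line crosses the
#' 0.25 and 0.75 proportion points, up to the rounding of 0.675 for
#' `qnorm(0.75)`.
#'
#' @param fit A [fit_probit_line()] result.
#' @return List with `jnd_signed` and `jnd_magnitude`, both in ms (`NA` when
#'   the slope is zero).
#' @export
compute_jnd <- function(fit) {
  stopifnot(inherits(fit, "toj_linefit"))
  if (fit$slope == 0) {
    warning("slope is zero; JND undefined")
    return(list(jnd_signed = NA_real_, jnd_magnitude = NA_real_))
  }
  signed <- 0.675 / fit$slope
  list(jnd_signed = signed, jnd_magnitude = abs(signed))
}

#' Proportion of correct order reports at a given absolute SOA
#'
#' A response is correct when it names the hand that was truly stimulated
#' first (anatomical truth, independent of posture).
#'
#' @param trials Trial records (columns `soa_ms`, `response`).
#' @param abs_soa Absolute SOA in ms to evaluate at (default 200, the
#'   largest in the design).
#' @return Proportion correct among the matching trials.
#' @export
percent_correct_at <- function(trials, abs_soa = 200) {
  sel <- abs(trials$soa_ms) == abs_soa
  if (!any(sel)) {
    stop(sprintf("no trials with |SOA| = %s ms", abs_soa), call. = FALSE)
  }
  truth <- ifelse(trials$soa_ms[sel] < 0, "left_first", "right_first")
  mean(trials$response[sel] == truth)
}

#' Fit one subject's psychometric summary, per posture
#'
#' Runs the full per-subject pipeline: affected-frame aggregation, probit
#' transform, straight-line fit, then PSS, JND and percent correct at the
#' largest SOA, separately for each posture.
#'
#' @param trials One subject's trial records.
#' @param affected_side `"left"` or `"right"`.
#' @param clip Clip rule passed to [probit_transform()].
#' @param abs_soa_check Absolute SOA for the performance check (default 200).
#' @return Data frame with one row per posture: `subject_id` (if present in
#'   `trials`), `posture`, `slope`, `intercept`, `r_squared`, `pss_ms`,
#'   `jnd_signed_ms`, `jnd_mag_ms`, `pct_correct_200`.
#' @export
#' @examples
#' sched <- build_trial_schedule("uncrossed", seed = 1)
#' trials <- simulate_subject(observer(pss_true = 20, sigma = 100), sched, seed = 3)
#' fit_subject(trials, "left")
fit_subject <- function(trials, affected_side = c("left", "right"),
                        clip = "half_count", abs_soa_check = 200) {
  affected_side <- match.arg(affected_side)
  tab <- aggregate_proportions(trials, affected_side)
  tab <- probit_transform(tab, clip)
  postures <- sort(unique(tab$posture))
  rows <- lapply(postures, function(post) {
    pts <- tab[tab$posture == post, , drop = FALSE]
    fit <- fit_probit_line(pts)
    jnd <- compute_jnd(fit)
    data.frame(
      posture = post, slope = fit$slope, intercept = fit$intercept,
      r_squared = fit$r_squared,
      pss_ms = compute_pss(fit),
      jnd_signed_ms = jnd$jnd_signed, jnd_mag_ms = jnd$jnd_magnitude,
      pct_correct_200 = percent_correct_at(
        trials[trials$posture == post, , drop = FALSE], abs_soa_check),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if ("subject_id" %in% names(trials)) {
    out <- cbind(subject_id = trials$subject_id[1L], out,
                 stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Fit psychometric summaries for every subject of a cohort
#'
#' @param trials Trial records for several subjects (column `subject_id`).
#' @param meta Metadata with `subject_id` and `affected_side`.
#' @param clip Clip rule passed to [probit_transform()].
#' @return Row-bound [fit_subject()] results, one row per subject x posture.
#' @export
fit_cohort <- function(trials, meta, clip = "half_count") {
  stopifnot(all(c("subject_id", "affected_side") %in% names(meta)))
  split_trials <- split(trials, trials$subject_id)
  side <- stats::setNames(meta$affected_side, meta$subject_id)
  missing_ids <- setdiff(names(split_trials), names(side))
  if (length(missing_ids) > 0L) {
    stop("trials contain subject ids absent from `meta`: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(names(split_trials), function(id) {
    fit_subject(split_trials[[id]], side[[id]], clip)
  }))
  rownames(out) <- NULL
  out
}
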