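#' Construct a synthetic TOJ observer
#'
#' An observer is the generative counterpart of the fitted psychometric
#' function: a cumulative-normal decision model with a subject-level point of
#' subjective simultaneity (PSS), a spread parameter, an optional crossed-arms
#' degradation of the spread, and a lapse rate.
#'
#' All temporal quantities live in the *affected frame*: `u` denotes the lead
#' time of the unaffected hand in ms, so `u > 0` means the unaffected hand was
#' stimulated first. A positive `pss_true` means the unaffected stimulus must
#' lead by that much to be perceived as simultaneous with the affected one,
#' i.e. stimuli on the affected limb are prioritised.
#'
#' @param pss_true True PSS in ms (positive = affected-limb advantage).
#' @param sigma Psychometric spread in ms for the uncrossed posture; must be
#'   positive. The generative JND magnitude is `0.675 * sigma`.
#' @param crossed_sigma_factor Multiplier (>= 1) applied to `sigma` when the
#'   arms are crossed; models the crossed-hands deficit.
#' @param lapse Probability in [0, 0.5) of a stimulus-independent random
#'   response (split evenly between the two labels).
#' @param affected_side `"left"` or `"right"`: which hand is the painful one.
#' @return A list of class `toj_observer`.
#' @export
#' @examples
#' obs <- observer(pss_true = 30, sigma = 100)
#' response_probability(obs, u = 30, "uncrossed")  # 0.5 at the PSS
observer <- function(pss_true = 0, sigma = 100, crossed_sigma_factor = 1,
                     lapse = 0, affected_side = c("left", "right")) {
  affected_side <- match.arg(affected_side)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    stop("`sigma` must be a single positive number (ms)", call. = FALSE)
  }
  if (crossed_sigma_factor < 1) {
    stop("`crossed_sigma_factor` must be >= 1", call. = FALSE)
  }
  if (lapse < 0 || lapse >= 0.5) {
    stop("`lapse` must lie in [0, 0.5)", call. = FALSE)
  }
  structure(
    list(pss_true = pss_true, sigma = sigma,
         crossed_sigma_factor = crossed_sigma_factor,
         lapse = lapse, affected_side = affected_side),
    class = "toj_observer"
  )
}

#' @export
print.toj_observer <- function(x, ...) {
  cat(sprintf(
    "TOJ observer: PSS %.1f ms, sigma %.1f ms (x%.2f crossed), lapse %.3f, affected side %s\n",
    x$pss_true, x$sigma, x$crossed_sigma_factor, x$lapse, x$affected_side))
  invisible(x)
}

#' Probability of reporting the affected hand first
#'
#' The generative response model underlying the probit analysis:
#' `P(affected first) = lapse/2 + (1 - lapse) * pnorm((pss_true - u) / sigma_p)`
#' where `sigma_p` is `sigma`, inflated by `crossed_sigma_factor` in the
#' crossed posture, and `u` is the unaffected hand's lead time in ms.
#'
#' @param obs A [observer()].
#' @param u Numeric vector of unaffected-hand lead times in ms (`u > 0` means
#'   the unaffected hand was stimulated first).
#' @param posture `"uncrossed"` or `"crossed"`.
#' @return Vector of probabilities of an affected-hand-first report.
#' @export
response_probability <- function(obs, u, posture = c("uncrossed", "crossed")) {
  stopifnot(inherits(obs, "toj_observer"))
  posture <- match.arg(posture)
  sigma_p <- obs$sigma * if (posture == "crossed") obs$crossed_sigma_factor else 1
  obs$lapse / 2 + (1 - obs$lapse) * stats::pnorm((obs$pss_true - u) / sigma_p)
}

# left/right frame -> affected frame: lead time of the unaffected hand.
# soa_ms < 0 means left first. If the left hand is affected, a left-first
# trial is affected-first, so u = soa_ms; with the right hand affected the
# axis flips.
soa_to_u <- function(soa_ms, affected_side) {
  if (affected_side == "left") soa_ms else -soa_ms
}

#' Simulate one subject's responses over a trial schedule
#'
#' Converts every scheduled left/right-frame SOA into the observer's affected
#' frame, draws a Bernoulli response from [response_probability()], and maps
#' the outcome back to a left/right-frame response label.
#'
#' @param obs A [observer()].
#' @param schedule A [build_trial_schedule()] data frame (columns `block`,
#'   `trial_index`, `posture`, `soa_ms`).
#' @param seed Single non-negative integer; same seed, same responses.
#' @param subject_id Identifier stored in the output rows.
#' @return Data frame of trial records: `subject_id`, `block`, `trial_index`,
#'   `posture`, `soa_ms`, `response` (`"left_first"`/`"right_first"`).
#' @export
#' @examples
#' sched <- build_trial_schedule("uncrossed", seed = 1)
#' trials <- simulate_subject(observer(pss_true = 20, sigma = 80), sched, seed = 2)
#' head(trials)
simulate_subject <- function(obs, schedule, seed, subject_id = "s01") {
  stopifnot(inherits(obs, "toj_observer"))
  if (!all(c("block", "trial_index", "posture", "soa_ms") %in% names(schedule))) {
    stop("`schedule` must have columns block, trial_index, posture, soa_ms",
         call. = FALSE)
  }
  if (any(schedule$soa_ms == 0)) stop("SOA of 0 ms is not a valid trial")
  u <- soa_to_u(schedule$soa_ms, obs$affected_side)
  p_aff <- numeric(nrow(schedule))
  for (post in unique(schedule$posture)) {
    idx <- schedule$posture == post
    p_aff[idx] <- response_probability(obs, u[idx], post)
  }
  aff_first <- with_local_seed(seed, stats::runif(nrow(schedule)) < p_aff)
  aff_label <- if (obs$affected_side == "left") "left_first" else "right_first"
  una_label <- if (obs$affected_side == "left") "right_first" else "left_first"
  data.frame(
    subject_id = subject_id,
    block = schedule$block,
    trial_index = schedule$trial_index,
    posture = schedule$posture,
    soa_ms = schedule$soa_ms,
    response = ifelse(aff_first, aff_label, una_label),
    stringsAsFactors = FALSE
  )
}
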