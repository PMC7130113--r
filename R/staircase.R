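#' Configuration of the double random staircase
#'
#' Intensity matching runs two interleaved staircases, one starting high and
#' one low, for 16 trials per part. After each rating the active staircase
#' moves one fixed step towards the target rating of 3 ("moderate" /
#' "equally strong"): down after a rating above 3, up after a rating below 3,
#' unchanged at exactly 3. Levels are clamped to `(0, max_power]`.
#'
#' @param max_power Reference (maximum) intensity in Watt.
#' @param n_trials Trials per part (split evenly over the two staircases).
#' @param step_fraction Step size as a fraction of `max_power`.
#' @param start_levels Length-2 numeric, the high and low starting levels.
#' @return List of class `toj_staircase_config`.
#' @export
staircase_config <- function(max_power = 0.21, n_trials = 16L,
                             step_fraction = 0.1,
                             start_levels = c(0.20, 0.02)) {
  if (step_fraction <= 0 || step_fraction >= 1) {
    stop("`step_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (any(start_levels <= 0) || any(start_levels > max_power)) {
    stop("`start_levels` must lie in (0, max_power]", call. = FALSE)
  }
  structure(
    list(max_power = max_power, n_trials = as.integer(n_trials),
         step_fraction = step_fraction,
         start_levels = sort(start_levels, decreasing = TRUE)),
    class = "toj_staircase_config"
  )
}

#' A rating model mapping delivered intensity to a 1-5 rating
#'
#' Models the participant's Likert judgment: the expected rating is 3 at the
#' anchor intensity and rises linearly with intensity at `3 + (I - anchor) /
#' width` rating points, optionally perturbed by Gaussian noise, then rounded
#' and clamped to 1-5. The anchor can be given either absolutely (`anchor`,
#' Watt) or relative to a reference intensity supplied at run time
#' (`anchor_ratio`), which is how the second staircase part compares the
#' right hand against the selected left-hand intensity.
#'
#' @param anchor Intensity in Watt at which the expected rating is 3.
#' @param anchor_ratio Alternative to `anchor`: anchor = ratio x reference.
#' @param width Watt per rating point (sensitivity of the scale).
#' @param noise_sd SD of rating noise before rounding (0 = deterministic).
#' @return List of class `toj_rating_model`.
#' @export
rating_model <- function(anchor = NULL, anchor_ratio = NULL, width = 0.02,
                         noise_sd = 0) {
  if (is.null(anchor) && is.null(anchor_ratio)) {
    stop("give either `anchor` or `anchor_ratio`", call. = FALSE)
  }
  if (width <= 0) stop("`width` must be positive", call. = FALSE)
  structure(
    list(anchor = anchor, anchor_ratio = anchor_ratio, width = width,
         noise_sd = noise_sd),
    class = "toj_rating_model"
  )
}

#' Run one part of the double random staircase
#'
#' Interleaves the high- and low-start staircases in seeded random order
#' (half the trials each), applies the one-step update rule after every
#' rating, and selects the final intensity with [select_intensity()].
#'
#' @param model A [rating_model()] for this part.
#' @param config A [staircase_config()].
#' @param seed Single non-negative integer.
#' @param reference Reference intensity in Watt, needed when `model` is
#'   relative (`anchor_ratio`).
#' @return List with `selected` (Watt) and `log`, a data frame of columns
#'   `trial`, `staircase_id` (1 = high start, 2 = low start),
#'   `intensity_watt`, `rating`.
#' @export
run_double_staircase <- function(model, config = staircase_config(), seed,
                                 reference = NULL) {
  stopifnot(inherits(model, "toj_rating_model"),
            inherits(config, "toj_staircase_config"))
  step <- config$step_fraction * config$max_power
  n <- config$n_trials
  order_ids <- with_local_seed(seed, {
    ids <- sample(rep(c(1L, 2L), length.out = n))
    noise <- if (model$noise_sd > 0) stats::rnorm(n) else numeric(n)
    list(ids = ids, noise = noise)
  })
  levels <- config$start_levels
  log <- data.frame(trial = seq_len(n), staircase_id = order_ids$ids,
                    intensity_watt = NA_real_, rating = NA_integer_)
  for (t in seq_len(n)) {
    id <- order_ids$ids[t]
    intensity <- levels[id]
    anchor <- model$anchor
    if (is.null(anchor)) {
      if (is.null(reference)) {
        stop("rating model is relative but no reference intensity was given",
             call. = FALSE)
      }
      anchor <- model$anchor_ratio * reference
    }
    r <- 3 + (intensity - anchor) / model$width + order_ids$noise[t] * model$noise_sd
    rating <- min(5L, max(1L, as.integer(round(r))))
    log$intensity_watt[t] <- intensity
    log$rating[t] <- rating
    # one fixed step towards the target rating; a move that would leave
    # (0, max_power] is not taken
    if (rating > 3L) {
      if (levels[id] - step > 0) levels[id] <- levels[id] - step
    } else if (rating < 3L) {
      levels[id] <- min(config$max_power, levels[id] + step)
    }
  }
  list(selected = select_intensity(log), log = log)
}

#' Select the intensity whose average rating is three
#'
#' Groups the staircase log by intensity level and averages the ratings per
#' level. A level whose mean rating is exactly 3 is returned directly (the
#' lowest such level on ties). Otherwise the two adjacent levels bracketing a
#' mean rating of 3 are linearly interpolated; if no pair brackets 3, the
#' level with the mean rating closest to 3 is returned (again lowest first).
#'
#' @param log Data frame with columns `intensity_watt` and `rating`.
#' @return Selected intensity in Watt.
#' @export
select_intensity <- function(log) {
  if (nrow(log) == 0L) stop("staircase log is empty", call. = FALSE)
  means <- stats::aggregate(rating ~ intensity_watt, data = log, FUN = mean)
  means <- means[order(means$intensity_watt), , drop = FALSE]
  hit <- which(abs(means$rating - 3) < 1e-12)
  if (length(hit) > 0L) return(means$intensity_watt[hit[1L]])
  if (nrow(means) > 1L) {
    d <- means$rating - 3
    cross <- which(d[-nrow(means)] * d[-1L] < 0)
    if (length(cross) > 0L) {
      i <- cross[1L]
      x1 <- means$intensity_watt[i]; x2 <- means$intensity_watt[i + 1L]
      y1 <- means$rating[i]; y2 <- means$rating[i + 1L]
      return(x1 + (3 - y1) * (x2 - x1) / (y2 - y1))
    }
  }
  means$intensity_watt[which.min(abs(means$rating - 3))]
}

#' Match vibrotactile intensities between hands
#'
#' Part 1 calibrates the left hand against the maximum-power reference
#' stimulus on the 1-5 sensation scale; the selected left intensity then
#' serves as the reference for part 2, where the right hand is compared on
#' the 1-5 "equally strong" scale with the same staircase mechanics.
#'
#' @param model_left,model_right [rating_model()]s for the two parts.
#'   `model_right` is typically relative (`anchor_ratio`).
#' @param config A [staircase_config()] shared by both parts.
#' @param seed Single non-negative integer (part 2 uses `seed + 1`).
#' @return List with `intensity_left`, `intensity_right` (Watt) and `log`,
#'   the combined trial log with a `part` column.
#' @export
#' @examples
#' left <- rating_model(anchor = 0.094)
#' right <- rating_model(anchor_ratio = 1)
#' match_hands(left, right, seed = 1)[c("intensity_left", "intensity_right")]
match_hands <- function(model_left, model_right, config = staircase_config(),
                        seed = 1L) {
  part1 <- run_double_staircase(model_left, config, seed)
  part2 <- run_double_staircase(model_right, config, seed + 1L,
                                reference = part1$selected)
  log <- rbind(cbind(part = 1L, part1$log), cbind(part = 2L, part2$log))
  list(intensity_left = part1$selected, intensity_right = part2$selected,
       log = log)
}
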