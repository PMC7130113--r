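#' Stimulus onset asynchronies used in the main blocks
#'
#' Signed SOAs in milliseconds; negative values mean the left hand was
#' stimulated first, positive values the right hand.
#'
#' @return Integer vector of the ten trial types.
#' @export
#' @examples
#' soa_levels()
soa_levels <- function() {
  as.integer(c(-200, -90, -55, -30, -10, 10, 30, 55, 90, 200))
}

#' Build the main temporal-order-judgment trial schedule
#'
#' Constructs the four-block schedule of the TOJ experiment: 4 blocks of 60
#' trials, each block containing every one of the ten SOA types
#' (+/-10, +/-30, +/-55, +/-90, +/-200 ms) exactly six times in seeded random
#' order. Arm posture alternates between consecutive blocks starting from
#' `start_posture`, giving two blocks per posture.
#'
#' @param start_posture `"uncrossed"` or `"crossed"`; posture of block 1.
#' @param seed Single non-negative integer. The same seed always yields the
#'   identical schedule.
#' @return A data frame of class `toj_schedule` with columns `block`,
#'   `trial_index` (1--60 within block), `posture` and `soa_ms`, plus
#'   attributes `start_posture` and `seed`.
#' @export
#' @examples
#' sched <- build_trial_schedule("uncrossed", seed = 1)
#' nrow(sched)                      # 240
#' table(sched$block, sched$posture)
build_trial_schedule <- function(start_posture = c("uncrossed", "crossed"),
                                 seed) {
  start_posture <- match.arg(start_posture)
  other <- if (start_posture == "uncrossed") "crossed" else "uncrossed"
  postures <- rep(c(start_posture, other), 2L)
  soas <- rep(soa_levels(), each = 6L)   # 60 trials per block

  blocks <- with_local_seed(seed, {
    lapply(seq_len(4L), function(b) {
      data.frame(
        block = b,
        trial_index = seq_len(60L),
        posture = postures[b],
        soa_ms = sample(soas),
        stringsAsFactors = FALSE
      )
    })
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  attr(out, "start_posture") <- start_posture
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("toj_schedule", "data.frame")
  out
}

#' Build the three practice blocks
#'
#' Practice precedes the main blocks and increases in difficulty:
#' \itemize{
#'   \item Block 1: 8 single-stimulus localisation trials (4 left, 4 right,
#'     random order), to practise the response mapping.
#'   \item Block 2: 12 paired trials, arms uncrossed, drawn from the three
#'     largest SOAs (+/-55, +/-90, +/-200 ms), two of each type.
#'   \item Block 3: 18 such paired trials with arms crossed, three of each
#'     type.
#' }
#'
#' @param seed Single non-negative integer.
#' @return A list of three data frames. Block 1 has columns `trial_index` and
#'   `side`; blocks 2--3 have `trial_index`, `posture` and `soa_ms`.
#' @export
build_practice_blocks <- function(seed) {
  large <- as.integer(c(-200, -90, -55, 55, 90, 200))
  with_local_seed(seed, {
    b1 <- data.frame(
      trial_index = seq_len(8L),
      side = sample(rep(c("left", "right"), each = 4L)),
      stringsAsFactors = FALSE
    )
    b2 <- data.frame(
      trial_index = seq_len(12L),
      posture = "uncrossed",
      soa_ms = sample(rep(large, each = 2L)),
      stringsAsFactors = FALSE
    )
    b3 <- data.frame(
      trial_index = seq_len(18L),
      posture = "crossed",
      soa_ms = sample(rep(large, each = 3L)),
      stringsAsFactors = FALSE
    )
    list(localisation = b1, uncrossed = b2, crossed = b3)
  })
}
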