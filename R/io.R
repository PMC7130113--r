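#' Read and write trial records
#'
#' CSV with header is the single interchange dialect: UTF-8, `.` decimal
#' separator, missing values as empty fields. `read_trials()` validates the
#' records and reports malformed rows with their line numbers.
#'
#' Validation: required columns present; `soa_ms` nonzero; `response` one of
#' `left_first`/`right_first`; `posture` one of `uncrossed`/`crossed`; no
#' duplicate subject x block x trial keys. An SOA outside the standard set
#' (+/-10/30/55/90/200 ms) is retained with a warning, since custom designs
#' are legitimate.
#'
#' @param path File path.
#' @param trials Trial-record data frame (see [simulate_subject()]).
#' @return `read_trials()`: the validated data frame. `write_trials()`: the
#'   path, invisibly.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "block", "trial_index", "posture", "soa_ms",
            "response")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- function(sel, what) {
    if (any(sel)) {
      stop(sprintf("%s (lines %s)", what,
                   paste(utils::head(line[sel], 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad(is.na(df$soa_ms) | df$soa_ms == 0, "SOA must be nonzero")
  bad(!df$response %in% c("left_first", "right_first"),
      "response must be left_first or right_first")
  bad(!df$posture %in% c("uncrossed", "crossed"),
      "posture must be uncrossed or crossed")
  key <- paste(df$subject_id, df$block, df$trial_index)
  bad(duplicated(key), "duplicate subject x block x trial key")
  odd <- !abs(df$soa_ms) %in% abs(soa_levels())
  if (any(odd)) {
    warning(sprintf("%d trials use SOAs outside the standard set; retained",
                    sum(odd)))
  }
  df
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and write subject metadata
#'
#' Metadata columns: `subject_id`, `group` (`crps`/`shoulder`/`wrist`),
#' `affected_side` (`left`/`right`), `pain_duration_months`,
#' `pain_intensity` (0-10), `temp_diff_c` (affected minus unaffected limb,
#' degC; empty = missing).
#'
#' @param path File path.
#' @param meta Metadata data frame.
#' @return `read_meta()`: the validated data frame. `write_meta()`: the
#'   path, invisibly.
#' @export
read_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "affected_side", "pain_duration_months",
            "pain_intensity", "temp_diff_c")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!df$group %in% c("crps", "shoulder", "wrist"))) {
    stop("group must be crps, shoulder or wrist", call. = FALSE)
  }
  if (any(!df$affected_side %in% c("left", "right"))) {
    stop("affected_side must be left or right", call. = FALSE)
  }
  if (any(df$pain_intensity < 0 | df$pain_intensity > 10, na.rm = TRUE)) {
    stop("pain_intensity must lie in [0, 10]", call. = FALSE)
  }
  if (any(duplicated(df$subject_id))) {
    stop("duplicate subject_id in metadata", call. = FALSE)
  }
  df
}

#' @rdname read_meta
#' @export
write_meta <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
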