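#' Apply the PSS exclusion criteria
#'
#' Two criteria decide whether a posture's PSS (and JND) enter the analysis:
#' \enumerate{
#'   \item `|PSS| < 400` ms (twice the largest SOA) for that posture;
#'   \item percent correct at the largest SOA above 60\% in \emph{both}
#'     postures — a subject-level condition, so failing it in one posture
#'     excludes the subject's PSS in both.
#' }
#' A separate sensitivity flag marks postures with `|JND| <= 200` ms, used
#' for the JND-based sensitivity re-analysis, not for a priori exclusion.
#'
#' @param summary A per-subject summary from [fit_subject()] (both postures).
#' @param pss_limit,pct_correct_min,jnd_limit The thresholds; defaults 400
#'   ms, 0.60 and 200 ms.
#' @return `summary` with logical columns `criterion1_pass`,
#'   `criterion2_pass`, `included` and `sensitivity_pass` appended.
#' @export
apply_exclusion <- function(summary, pss_limit = 400, pct_correct_min = 0.60,
                            jnd_limit = 200) {
  need <- c("posture", "pss_ms", "jnd_mag_ms", "pct_correct_200")
  stopifnot(all(need %in% names(summary)))
  c1 <- !is.na(summary$pss_ms) & abs(summary$pss_ms) < pss_limit
  # criterion 2 demands > 60% correct at the largest SOA in both postures;
  # a missing posture cannot satisfy "both"
  c2 <- length(unique(summary$posture)) >= 2L &&
    all(summary$pct_correct_200 > pct_correct_min)
  summary$criterion1_pass <- c1
  summary$criterion2_pass <- rep(c2, nrow(summary))
  summary$included <- c1 & c2
  summary$sensitivity_pass <- !is.na(summary$jnd_mag_ms) &
    summary$jnd_mag_ms <= jnd_limit
  summary
}

#' Build the tidy per-subject, per-posture analysis table
#'
#' Joins the psychometric summaries with the subject metadata (imputing
#' missing temperature differences first), applies the exclusion criteria per
#' subject, and returns one row per subject x posture. Excluded rows are
#' flagged, never dropped, so the missing-value comparison between postures
#' stays reproducible.
#'
#' @param summaries Row-bound [fit_subject()] results (column `subject_id`).
#' @param meta Subject metadata (`subject_id`, `group`, `affected_side`,
#'   `pain_duration_months`, `pain_intensity`, `temp_diff_c`).
#' @param ... Passed to [apply_exclusion()].
#' @return Data frame, one row per subject x posture, with psychometric
#'   estimates, inclusion flags, covariates and a `temp_imputed` flag. Ready
#'   for downstream mixed-model tools.
#' @export
build_analysis_table <- function(summaries, meta, ...) {
  stopifnot("subject_id" %in% names(summaries),
            "subject_id" %in% names(meta))
  extra <- setdiff(summaries$subject_id, meta$subject_id)
  if (length(extra) > 0L) {
    stop("summaries contain subject ids absent from `meta`: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (anyNA(meta$temp_diff_c)) meta <- impute_temperature(meta)
  if (!"temp_imputed" %in% names(meta)) meta$temp_imputed <- FALSE

  flagged <- do.call(rbind, lapply(split(summaries, summaries$subject_id),
                                   apply_exclusion, ...))
  keep <- c("subject_id", "group", "affected_side", "pain_duration_months",
            "pain_intensity", "temp_diff_c", "temp_imputed")
  keep <- intersect(keep, names(meta))
  out <- merge(flagged, meta[, keep, drop = FALSE],
               by = "subject_id", sort = TRUE)
  out <- out[order(out$subject_id, out$posture), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare exclusion proportions between postures
#'
#' Convenience wrapper: counts excluded rows per posture in an analysis
#' table and runs [chi_square_equal_prop()] on the two proportions.
#'
#' @param analysis_table A [build_analysis_table()] result.
#' @return A `toj_test` result (see [chi_square_equal_prop()]).
#' @export
exclusion_chi_square <- function(analysis_table) {
  stopifnot(all(c("posture", "included") %in% names(analysis_table)))
  tab <- analysis_table
  n_cro <- sum(tab$posture == "crossed")
  n_unc <- sum(tab$posture == "uncrossed")
  k_cro <- sum(tab$posture == "crossed" & !tab$included)
  k_unc <- sum(tab$posture == "uncrossed" & !tab$included)
  chi_square_equal_prop(k_cro, n_cro, k_unc, n_unc)
}
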