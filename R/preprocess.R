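#' Mark physiologically invalid samples
#'
#' Flags samples where the oximeter reported no reading. A raw value of 0 is
#' the device's invalid code; by default readings outside the physiological
#' range 50--100% are also flagged (an extension that can be switched off with
#' `strict_zero_only = TRUE`). Sample values are never modified.
#'
#' @param record An [spo2_record()].
#' @param strict_zero_only If `TRUE`, flag only exact zeros.
#' @return The record with its validity mask updated.
#' @export
mark_invalid <- function(record, strict_zero_only = FALSE) {
  assert_record(record)
  bad <- record$samples == 0
  if (!strict_zero_only)
    bad <- bad | record$samples < 50 | record$samples > 100
  record$valid_mask <- record$valid_mask & !bad
  record
}

#' Trim recording edges
#'
#' Removes the first and last `trim_min` minutes of the recording, where
#' device setup and removal contaminate the trace. The record's `t0_offset`
#' is advanced by the trimmed duration.
#'
#' @param record An [spo2_record()].
#' @param trim_min Minutes to remove from each end (default 15).
#' @return The trimmed record.
#' @export
trim_edges <- function(record, trim_min = 15) {
  assert_record(record)
  if (trim_min < 0) stop("trim_min must be non-negative")
  n_trim <- as.integer(round(trim_min * 60 * record$fs))
  if (n_trim == 0L) return(record)
  n <- length(record$samples)
  if (n <= 2L * n_trim)
    stop(sprintf(
      "record too short to trim: %.1f min total, %g min removed per edge",
      n / record$fs / 60, trim_min))
  keep <- (n_trim + 1L):(n - n_trim)
  record$samples <- record$samples[keep]
  record$valid_mask <- record$valid_mask[keep]
  record$t0_offset <- record$t0_offset + n_trim / record$fs
  record
}

#' Median-filter an SpO2 trace
#'
#' Replaces each valid sample by the median of the valid samples in a
#' centered window of `window_s` seconds (30 samples at 3 Hz), truncated at
#' the record edges. Invalid samples are excluded from every window and pass
#' through unchanged; a window containing no valid neighbours leaves the
#' sample as is. For an even window length the extra sample is taken from the
#' past (left) side.
#'
#' @param record An [spo2_record()].
#' @param window_s Window length in seconds (default 10).
#' @return The filtered record.
#' @export
median_filter_spo2 <- function(record, window_s = 10) {
  assert_record(record)
  w <- as.integer(round(window_s * record$fs))
  if (w < 1L) stop("window_s * fs must be at least 1 sample")
  left <- as.integer(floor(w / 2))
  right <- w - 1L - left
  record$samples <- median_filter_masked(record$samples, record$valid_mask,
                                         left, right)
  record
}

#' Check record eligibility
#'
#' A trimmed, invalid-marked record is eligible for feature extraction when
#' it retains at least one hour of signal and no more than half of its
#' samples are invalid.
#'
#' @param record A trimmed, invalid-marked [spo2_record()].
#' @param min_duration_s Minimum retained duration in seconds (default 3600).
#' @param max_invalid_frac Maximum tolerated invalid fraction (default 0.5).
#' @return A `preprocess_report` list with fields `eligible`, `reason`,
#'   `n_trimmed_start`, `n_trimmed_end`, `frac_invalid`, `duration_s`.
#' @export
check_eligibility <- function(record, min_duration_s = 3600,
                              max_invalid_frac = 0.5) {
  assert_record(record)
  duration_s <- record_duration(record)
  frac_invalid <- mean(!record$valid_mask)
  eligible <- TRUE
  reason <- "eligible"
  if (duration_s < min_duration_s) {
    eligible <- FALSE
    reason <- "duration < 1 h"
  } else if (frac_invalid > max_invalid_frac) {
    eligible <- FALSE
    reason <- "invalid > 50%"
  }
  n_trim <- as.integer(round(record$t0_offset * record$fs))
  structure(
    list(eligible = eligible, reason = reason,
         n_trimmed_start = n_trim, n_trimmed_end = n_trim,
         frac_invalid = frac_invalid, duration_s = duration_s),
    class = "preprocess_report"
  )
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("<preprocess_report> %s (%s); %.1f min retained, %.1f%% invalid\n",
              if (x$eligible) "eligible" else "ineligible", x$reason,
              x$duration_s / 60, 100 * x$frac_invalid))
  invisible(x)
}

#' Run the full preprocessing pipeline
#'
#' Applies the fixed order: invalid-sample marking, edge trimming, median
#' filtering, eligibility check. Re-running on the output is idempotent when
#' `trim_min = 0` (the signal has already been trimmed once).
#'
#' @param record A raw [spo2_record()].
#' @param trim_min Minutes trimmed per edge (default 15).
#' @param median_window_s Median-filter window in seconds (default 10).
#' @param strict_invalid_zero_only Passed to [mark_invalid()].
#' @param min_duration_s,max_invalid_frac Passed to [check_eligibility()].
#' @return A list with elements `record` (preprocessed) and `report`
#'   (the [check_eligibility()] output).
#' @export
preprocess_spo2 <- function(record, trim_min = 15, median_window_s = 10,
                            strict_invalid_zero_only = FALSE,
                            min_duration_s = 3600, max_invalid_frac = 0.5) {
  record <- mark_invalid(record, strict_zero_only = strict_invalid_zero_only)
  record <- trim_edges(record, trim_min = trim_min)
  record <- median_filter_spo2(record, window_s = median_window_s)
  report <- check_eligibility(record, min_duration_s = min_duration_s,
                              max_invalid_frac = max_invalid_frac)
  list(record = record, report = report)
}
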