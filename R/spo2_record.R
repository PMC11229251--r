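#' Construct an SpO2 record
#'
#' An `spo2_record` holds one overnight pulse-oximetry trace: a vector of
#' saturation values in percent (integer-quantized at the source, typically at
#' 1% resolution), a per-sample validity mask, the sampling rate, and the
#' number of seconds trimmed from the original recording start.
#'
#' @param samples Numeric vector of SpO2 values in percent.
#' @param fs Sampling rate in Hz (default 3, the usual rate of home sleep
#'   apnea test oximeters).
#' @param subject_id Opaque subject identifier.
#' @param phase Either `"preop"` or `"postop"`.
#' @param valid_mask Logical vector, one entry per sample; `TRUE` marks a
#'   usable sample. Defaults to all-`TRUE` (validity is assigned by
#'   [mark_invalid()]).
#' @param t0_offset Seconds removed from the original recording start by
#'   trimming.
#'
#' @return An object of class `spo2_record`.
#' @seealso [mark_invalid()], [trim_edges()], [median_filter_spo2()]
#' @export
spo2_record <- function(samples, fs = 3, subject_id = "anonymous",
                        phase = c("preop", "postop"),
                        valid_mask = NULL, t0_offset = 0) {
  phase <- match.arg(phase)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("an spo2_record must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, length(samples))
  valid_mask <- as.logical(valid_mask)
  if (length(valid_mask) != length(samples))
    stop("valid_mask must have one entry per sample")
  structure(
    list(subject_id = as.character(subject_id), phase = phase, fs = fs,
         samples = samples, valid_mask = valid_mask,
         t0_offset = as.numeric(t0_offset)),
    class = "spo2_record"
  )
}

#' @export
print.spo2_record <- function(x, ...) {
  n <- length(x$samples)
  dur <- n / x$fs
  cat(sprintf("<spo2_record> subject '%s' (%s)\n", x$subject_id, x$phase))
  cat(sprintf("  %d samples at %g Hz (%.1f min), %.1f%% valid, t0 offset %g s\n",
              n, x$fs, dur / 60, 100 * mean(x$valid_mask), x$t0_offset))
  v <- x$samples[x$valid_mask]
  if (length(v))
    cat(sprintf("  valid SpO2 range [%g, %g]%%\n", min(v), max(v)))
  invisible(x)
}

#' Duration of a record in seconds
#'
#' @param record An [spo2_record()].
#' @param valid_only If `TRUE`, count only valid samples (analyzed time);
#'   otherwise the full retained record length.
#' @return Duration in seconds.
#' @export
record_duration <- function(record, valid_only = FALSE) {
  stopifnot(inherits(record, "spo2_record"))
  n <- if (valid_only) sum(record$valid_mask) else length(record$samples)
  n / record$fs
}

is_spo2_record <- function(x) inherits(x, "spo2_record")

assert_record <- function(record) {
  if (!is_spo2_record(record))
    stop("expected an spo2_record; see spo2_record()")
  invisible(record)
}
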