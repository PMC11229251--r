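#' Shannon entropy of the overnight SpO2 signal
#'
#' Entropy of the empirical distribution of valid SpO2 values over the
#' signal's native 1% alphabet (values are rounded to integer percent before
#' tabulation; median filtering with an even window can introduce half-percent
#' values). Natural log by default, so the result is in nats.
#'
#' @param record A preprocessed [spo2_record()].
#' @param base Logarithm base (`exp(1)` for nats, `2` for bits).
#' @return Entropy (nats by default).
#' @export
spo2_entropy <- function(record, base = exp(1)) {
  assert_record(record)
  v <- record$samples[record$valid_mask]
  if (length(v) == 0L) stop("no valid samples")
  entropy_from_counts(table(round(v)), base = base)
}

#' Standard deviation of the overnight SpO2 signal
#'
#' Population standard deviation of the valid samples, in percent.
#'
#' @param record A preprocessed [spo2_record()].
#' @return Standard deviation in percent.
#' @export
spo2_std <- function(record) {
  assert_record(record)
  v <- record$samples[record$valid_mask]
  if (length(v) < 2L) stop("need at least 2 valid samples")
  pop_sd(v)
}

#' Below-average burden (BAB)
#'
#' Area of the SpO2 trace below its own overnight mean, divided by the
#' analyzed (valid) time in seconds: with m the mean of valid samples,
#' BAB = sum(max(0, m - SpO2_i)) / fs / T_valid, in percent. Shifting the
#' whole signal by a constant leaves BAB unchanged.
#'
#' @param record A preprocessed [spo2_record()].
#' @return BAB in percent.
#' @export
below_average_burden <- function(record) {
  assert_record(record)
  v <- record$samples[record$valid_mask]
  if (length(v) == 0L) stop("no valid samples")
  m <- mean(v)
  duration <- length(v) / record$fs
  sum(pmax(0, m - v)) / record$fs / duration
}

#' Summary statistics of normalized episode burdens (ODB AVG/STD/ENT)
#'
#' Mean, population standard deviation, and Shannon entropy of the normalized
#' desaturation burdens of the night's episodes. The entropy uses a histogram
#' with fixed bin width `ent_bin` starting at 0. With no episodes all three
#' are 0.
#'
#' @param episodes A [detect_episodes()] table.
#' @param ent_bin Histogram bin width in normalized-burden units (default 0.1).
#' @param base Logarithm base for the entropy.
#' @return A list with elements `odb_avg`, `odb_std`, `odb_ent`.
#' @export
odb_statistics <- function(episodes, ent_bin = 0.1, base = exp(1)) {
  nb <- episodes$normalized_burden
  if (length(nb) == 0L)
    return(list(odb_avg = 0, odb_std = 0, odb_ent = 0))
  counts <- table(floor(nb / ent_bin))
  list(odb_avg = mean(nb), odb_std = pop_sd(nb),
       odb_ent = entropy_from_counts(counts, base = base))
}

#' Nocturnal desaturation burden (NDB)
#'
#' Cumulative burden of all desaturation episodes divided by the analyzed
#' (valid) recording time in seconds, in percent.
#'
#' @param episodes A [detect_episodes()] table.
#' @param record The record the episodes were detected on.
#' @return NDB in percent.
#' @export
nocturnal_desaturation_burden <- function(episodes, record) {
  assert_record(record)
  duration <- record_duration(record, valid_only = TRUE)
  if (duration <= 0 || nrow(episodes) == 0L) return(0)
  sum(episodes$burden) / duration
}

#' Extract the seven overnight SpO2 measures
#'
#' Runs episode detection and computes all seven measures on a preprocessed
#' record: `spo2_ent`, `spo2_std`, `bab`, `odb_avg`, `odb_std`, `odb_ent`,
#' `ndb`, plus the episode count and analyzed duration. Deterministic for a
#' fixed input and configuration.
#'
#' @param record A preprocessed, eligible [spo2_record()].
#' @param min_drop Minimum episode drop in percent (default 3).
#' @param ent_base Logarithm base for both entropies.
#' @param odb_ent_bin Histogram bin width for the burden entropy.
#' @param ... Further arguments passed to [detect_episodes()].
#' @return A one-row data.frame of class `spo2_features`.
#' @export
extract_features <- function(record, min_drop = 3, ent_base = exp(1),
                             odb_ent_bin = 0.1, ...) {
  assert_record(record)
  episodes <- detect_episodes(record, min_drop = min_drop, ...)
  odb <- odb_statistics(episodes, ent_bin = odb_ent_bin, base = ent_base)
  out <- data.frame(
    spo2_ent = spo2_entropy(record, base = ent_base),
    spo2_std = spo2_std(record),
    bab = below_average_burden(record),
    odb_avg = odb$odb_avg,
    odb_std = odb$odb_std,
    odb_ent = odb$odb_ent,
    ndb = nocturnal_desaturation_burden(episodes, record),
    n_episodes = nrow(episodes),
    analysis_duration_s = record_duration(record, valid_only = TRUE)
  )
  class(out) <- c("spo2_features", "data.frame")
  out
}

#' Names of the seven overnight SpO2 measures
#' @return Character vector of feature column names.
#' @export
spo2_feature_names <- function() {
  c("spo2_ent", "spo2_std", "bab", "odb_avg", "odb_std", "odb_ent", "ndb")
}

#' Detect postoperative respiratory depression
#'
#' Labels a postoperative record positive when it contains at least one
#' hypoxemia episode with SpO2 strictly below 85% lasting more than 3 minutes.
#' Episodes are maximal runs of valid sub-threshold samples; invalid samples
#' break a run.
#'
#' @param record A preprocessed postoperative [spo2_record()].
#' @param threshold SpO2 threshold in percent (default 85; strict `<`).
#' @param min_duration_s Minimum episode duration in seconds (default 180;
#'   strict `>`).
#' @return A list of class `rd_outcome` with fields `label` (logical),
#'   `episodes` (data.frame of `start_s`, `end_s`, `duration_s`), and
#'   `longest_s`.
#' @export
detect_respiratory_depression <- function(record, threshold = 85,
                                          min_duration_s = 180) {
  assert_record(record)
  fs <- record$fs
  below <- record$valid_mask & record$samples < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  eps <- data.frame(
    start_s = (starts[keep] - 1L) / fs,
    end_s = ends[keep] / fs,
    duration_s = r$lengths[keep] / fs
  )
  longest <- if (nrow(eps)) max(eps$duration_s) else 0
  structure(
    list(label = any(eps$duration_s > min_duration_s),
         episodes = eps, longest_s = longest),
    class = "rd_outcome"
  )
}

#' @export
print.rd_outcome <- function(x, ...) {
  cat(sprintf("<rd_outcome> %s: %d sub-threshold run(s), longest %.0f s\n",
              if (x$label) "respiratory depression" else "no respiratory depression",
              nrow(x$episodes), x$longest_s))
  invisible(x)
}
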