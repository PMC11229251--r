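#' Detect SpO2 desaturation episodes
#'
#' Segments a preprocessed SpO2 trace into desaturation episodes with drops of
#' at least `min_drop` percent, using drop/recovery phase logic on the signal's
#' first differences. Because the filtered signal is piecewise-constant (1%
#' source quantization), a drop phase is a maximal non-increasing run that
#' loses at least `min_drop` from its starting level to its minimum; plateaus
#' (zero difference) extend the current phase. The episode onset is the last
#' sample at the run's starting level before the first strict decrease, and
#' the nadir is the run's final (minimum) sample.
#'
#' The recovery phase ends at the first sample that returns to the onset
#' level, searched up to `recovery_window_s` seconds past the nadir. If the
#' signal does not recover in that window, the episode ends at the (earliest)
#' maximum SpO2 within the window. If a new qualifying decline begins before
#' recovery completes, the current episode is closed at the local maximum
#' preceding the new decline, so episodes never overlap. Episodes never span
#' invalid gaps longer than `gap_tolerance_s`; a longer gap terminates the
#' episode at the last valid sample before it.
#'
#' @param record A preprocessed [spo2_record()] (invalid-marked, trimmed,
#'   median-filtered).
#' @param min_drop Minimum onset-to-nadir drop in percent (default 3).
#' @param recovery_window_s Recovery search window after the nadir, seconds
#'   (default 120).
#' @param baseline_window_s Look-back window for the episode baseline, seconds
#'   (default 100).
#' @param gap_tolerance_s Longest invalid gap an episode may span, seconds
#'   (default 10).
#' @return A data.frame of class `desat_episodes`, one row per episode,
#'   ordered and non-overlapping, with 1-based sample indices
#'   (`drop_onset_idx`, `nadir_idx`, `recovery_end_idx`), times in seconds
#'   from the record start, levels in percent, and burden columns (see
#'   [compute_burden()]).
#' @export
detect_episodes <- function(record, min_drop = 3, recovery_window_s = 120,
                            baseline_window_s = 100, gap_tolerance_s = 10) {
  assert_record(record)
  check_preprocessed(record)
  fs <- record$fs
  eps <- 1e-9

  empty <- empty_episodes()
  vidx_all <- which(record$valid_mask)
  if (length(vidx_all) < 2L) return(empty)
  vals_all <- record$samples[vidx_all]

  gap_tol_n <- round(gap_tolerance_s * fs)
  gaps <- diff(vidx_all) - 1L
  brk <- which(gaps > gap_tol_n)
  seg_start <- c(1L, brk + 1L)
  seg_end <- c(brk, length(vidx_all))

  out <- vector("list", length(seg_start))
  for (s in seq_along(seg_start)) {
    pos <- seg_start[s]:seg_end[s]
    if (length(pos) < 2L) next
    v <- vals_all[pos]
    vi <- vidx_all[pos]

    inc <- diff(v) > eps
    run_first <- which(c(TRUE, inc))
    run_last <- c(run_first[-1L] - 1L, length(v))
    qual <- which(v[run_first] - v[run_last] >= min_drop - eps)
    if (length(qual) == 0L) next

    # last sample of the plateau containing each position (skips the leading
    # plateau of a run when locating the true onset of decline)
    r <- rle(v)
    plat_end <- cumsum(r$lengths)
    plat_id <- rep(seq_along(r$lengths), r$lengths)

    onset_pos <- pmin(plat_end[plat_id[run_first[qual]]], run_last[qual])
    nadir_pos <- run_last[qual]

    rows <- vector("list", length(qual))
    for (k in seq_along(qual)) {
      o <- onset_pos[k]
      b <- nadir_pos[k]
      L <- v[run_first[qual[k]]]
      o_next <- if (k < length(qual)) onset_pos[k + 1L] else length(v)
      hi <- min(findInterval(vi[b] + round(recovery_window_s * fs), vi), o_next)
      if (hi <= b) {
        rec <- b
        recovered <- FALSE
      } else {
        w <- (b + 1L):hi
        full <- w[v[w] >= L - eps]
        if (length(full)) {
          rec <- full[1L]
          recovered <- TRUE
        } else {
          rec <- w[which.max(v[w])]
          recovered <- FALSE
        }
      }
      rows[[k]] <- data.frame(
        drop_onset_idx = vi[o], nadir_idx = vi[b], recovery_end_idx = vi[rec],
        onset_level = L, nadir_level = v[b], drop_magnitude = L - v[b],
        recovered_fully = recovered
      )
    }
    out[[s]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty)
  ep <- do.call(rbind, out)

  ep$onset_s <- (ep$drop_onset_idx - 1L) / fs
  ep$nadir_s <- (ep$nadir_idx - 1L) / fs
  ep$end_s <- (ep$recovery_end_idx - 1L) / fs
  ep$duration_s <- ep$end_s - ep$onset_s

  ep$baseline_level <- vapply(seq_len(nrow(ep)), function(i)
    baseline_for(vidx_all, vals_all, ep$nadir_idx[i], ep$onset_level[i],
                 baseline_window_s, fs), numeric(1))
  bn <- vapply(seq_len(nrow(ep)), function(i)
    burden_for(vidx_all, vals_all, ep$drop_onset_idx[i], ep$recovery_end_idx[i],
               ep$baseline_level[i], fs), numeric(1))
  ep$burden <- bn
  ep$normalized_burden <- ep$burden / ep$duration_s

  ep <- ep[, c("drop_onset_idx", "nadir_idx", "recovery_end_idx",
               "onset_s", "nadir_s", "end_s",
               "onset_level", "nadir_level", "drop_magnitude",
               "baseline_level", "duration_s", "burden",
               "normalized_burden", "recovered_fully")]
  rownames(ep) <- NULL
  class(ep) <- c("desat_episodes", "data.frame")
  ep
}

empty_episodes <- function() {
  ep <- data.frame(
    drop_onset_idx = integer(), nadir_idx = integer(),
    recovery_end_idx = integer(), onset_s = numeric(), nadir_s = numeric(),
    end_s = numeric(), onset_level = numeric(), nadir_level = numeric(),
    drop_magnitude = numeric(), baseline_level = numeric(),
    duration_s = numeric(), burden = numeric(), normalized_burden = numeric(),
    recovered_fully = logical()
  )
  class(ep) <- c("desat_episodes", "data.frame")
  ep
}

check_preprocessed <- function(record) {
  bad <- record$valid_mask &
    (record$samples == 0 | record$samples < 50 | record$samples > 100)
  if (any(bad))
    stop("record does not appear preprocessed: out-of-range samples are ",
         "still marked valid; run preprocess_spo2() or mark_invalid() first")
  invisible(record)
}

baseline_for <- function(vidx, vals, nadir_idx, onset_level,
                         baseline_window_s, fs) {
  win_n <- round(baseline_window_s * fs)
  p1 <- findInterval(nadir_idx - win_n - 1L, vidx) + 1L
  p2 <- findInterval(nadir_idx - 1L, vidx)
  if (p1 > p2) return(onset_level)
  max(vals[p1:p2])
}

burden_for <- function(vidx, vals, onset_idx, end_idx, baseline, fs) {
  p1 <- findInterval(onset_idx - 1L, vidx) + 1L
  p2 <- findInterval(end_idx, vidx)
  if (p1 > p2) return(0)
  sum(pmax(0, baseline - vals[p1:p2])) / fs
}

#' Episode baseline level
#'
#' The baseline of a desaturation episode is the maximum valid SpO2 in the
#' `baseline_window_s` seconds before the recovery onset (the nadir), with the
#' window truncated at the record start. If the window holds no valid sample,
#' the episode's onset level is used.
#'
#' @param record The [spo2_record()] the episode was detected on.
#' @param episode One row of a [detect_episodes()] table.
#' @param baseline_window_s Look-back window in seconds (default 100).
#' @return Baseline SpO2 level in percent.
#' @export
compute_baseline <- function(record, episode, baseline_window_s = 100) {
  assert_record(record)
  vidx <- which(record$valid_mask)
  baseline_for(vidx, record$samples[vidx], episode$nadir_idx,
               episode$onset_level, baseline_window_s, record$fs)
}

#' Episode desaturation burden
#'
#' The burden of an episode is the rectangle-rule area between its baseline
#' and the SpO2 trace, summed over the episode's valid samples:
#' sum of max(0, baseline - SpO2_i) / fs, in percent-seconds. Invalid samples
#' contribute zero. The normalized burden divides by the episode duration in
#' seconds, giving a mean depth in percent.
#'
#' @param record The [spo2_record()] the episode was detected on.
#' @param episode One row of a [detect_episodes()] table (must carry
#'   `baseline_level`, `drop_onset_idx`, `recovery_end_idx`, `duration_s`).
#' @return A list with elements `burden` (%·s) and `normalized_burden` (%).
#' @export
compute_burden <- function(record, episode) {
  assert_record(record)
  if (episode$duration_s <= 0) stop("zero-duration episode")
  vidx <- which(record$valid_mask)
  b <- burden_for(vidx, record$samples[vidx], episode$drop_onset_idx,
                  episode$recovery_end_idx, episode$baseline_level, record$fs)
  list(burden = b, normalized_burden = b / episode$duration_s)
}

#' Oxygen desaturation index (convenience)
#'
#' Count of detected episodes with a drop of at least `min_drop` percent
#' (default 4, the conventional ODI definition) per hour of analyzed (valid)
#' time. Provided for comparison with the burden measures only.
#'
#' @param episodes A [detect_episodes()] table.
#' @param record The record the episodes came from.
#' @param min_drop Minimum drop in percent (default 4).
#' @return Events per hour.
#' @export
odi <- function(episodes, record, min_drop = 4) {
  hours <- record_duration(record, valid_only = TRUE) / 3600
  if (hours <= 0) return(0)
  sum(episodes$drop_magnitude >= min_drop - 1e-9) / hours
}
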