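# Independent brute-force oracles. These re-implement the stated rules with
# explicit sample-by-sample walks, deliberately sharing no code with the
# package's vectorized implementations.

oracle_median_filter <- function(samples, valid, w) {
  n <- length(samples)
  left <- floor(w / 2)
  right <- w - 1 - left
  out <- samples
  for (i in seq_len(n)) {
    if (!valid[i]) next
    win <- max(1, i - left):min(n, i + right)
    win <- win[valid[win]]
    if (length(win)) out[i] <- stats::median(samples[win])
  }
  out
}

oracle_entropy <- function(values, base = exp(1)) {
  tab <- table(values)
  p <- as.numeric(tab) / sum(tab)
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

# Exhaustive episode scanner: enumerates maximal non-increasing runs by
# explicit walking, then applies the drop/recovery/baseline/burden rules.
oracle_detect <- function(record, min_drop = 3, recovery_window_s = 120,
                          baseline_window_s = 100, gap_tolerance_s = 10) {
  fs <- record$fs
  eps <- 1e-9
  vidx <- which(record$valid_mask)
  vals <- record$samples[vidx]
  episodes <- list()
  if (length(vidx) >= 2) {
    tol <- round(gap_tolerance_s * fs)
    seg_id <- integer(length(vidx))
    cur <- 1L
    seg_id[1] <- 1L
    for (p in 2:length(vidx)) {
      if (vidx[p] - vidx[p - 1] - 1L > tol) cur <- cur + 1L
      seg_id[p] <- cur
    }
    for (s in unique(seg_id)) {
      pos <- which(seg_id == s)       # global positions of this segment
      v <- vals[pos]
      vi <- vidx[pos]
      m <- length(v)
      if (m < 2) next
      runs <- list()
      i <- 1L
      while (i <= m) {
        j <- i
        while (j < m && v[j + 1] <= v[j] + eps) j <- j + 1L
        runs[[length(runs) + 1L]] <- c(i, j)
        i <- j + 1L
      }
      qual <- Filter(function(r) v[r[1]] - v[r[2]] >= min_drop - eps, runs)
      if (!length(qual)) next
      onsets <- vapply(qual, function(r) {
        a <- r[1]
        while (a < r[2] && abs(v[a + 1] - v[a]) <= eps) a <- a + 1L
        a
      }, numeric(1))
      for (k in seq_along(qual)) {
        b <- qual[[k]][2]
        o <- onsets[k]
        L <- v[qual[[k]][1]]
        cap <- if (k < length(qual)) onsets[k + 1] else m
        bound <- vi[b] + round(recovery_window_s * fs)
        p <- b
        while (p < cap && vi[p + 1] <= bound) p <- p + 1L
        cap <- p
        rec_end <- b
        recovered <- FALSE
        if (cap > b) {
          found <- 0L
          for (j in (b + 1):cap) if (v[j] >= L - eps) { found <- j; break }
          if (found > 0L) {
            rec_end <- found
            recovered <- TRUE
          } else {
            best <- b + 1L
            for (j in (b + 1):cap) if (v[j] > v[best] + eps) best <- j
            rec_end <- best
          }
        }
        # baseline: walk backwards over valid samples within the time window
        gb <- pos[b]
        base <- -Inf
        q <- gb - 1L
        while (q >= 1 && vidx[q] >= vi[b] - round(baseline_window_s * fs)) {
          if (vals[q] > base) base <- vals[q]
          q <- q - 1L
        }
        if (!is.finite(base)) base <- L
        burden <- 0
        for (j in o:rec_end) burden <- burden + max(0, base - v[j])
        burden <- burden / fs
        dur <- (vi[rec_end] - vi[o]) / fs
        episodes[[length(episodes) + 1L]] <- data.frame(
          drop_onset_idx = vi[o], nadir_idx = vi[b],
          recovery_end_idx = vi[rec_end],
          onset_level = L, nadir_level = v[b], drop_magnitude = L - v[b],
          baseline_level = base, duration_s = dur, burden = burden,
          normalized_burden = burden / dur, recovered_fully = recovered)
      }
    }
  }
  if (!length(episodes))
    return(data.frame(drop_onset_idx = integer(), nadir_idx = integer(),
                      recovery_end_idx = integer(), onset_level = numeric(),
                      nadir_level = numeric(), drop_magnitude = numeric(),
                      baseline_level = numeric(), duration_s = numeric(),
                      burden = numeric(), normalized_burden = numeric(),
                      recovered_fully = logical()))
  do.call(rbind, episodes)
}

# episode-for-episode comparison of detector output against the oracle
expect_episodes_match <- function(detected, oracle, label = "") {
  expect_equal(nrow(detected), nrow(oracle), info = label)
  if (nrow(oracle) == 0) return(invisible(TRUE))
  for (col in c("drop_onset_idx", "nadir_idx", "recovery_end_idx",
                "onset_level", "nadir_level", "drop_magnitude",
                "baseline_level", "duration_s", "burden",
                "normalized_burden", "recovered_fully")) {
    expect_equal(unname(detected[[col]]), unname(oracle[[col]]),
                 tolerance = 1e-9, info = paste(label, col))
  }
  invisible(TRUE)
}
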