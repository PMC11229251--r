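# Programmatic fixture builders used across the test files.

flat_record <- function(level = 97, n = 600, fs = 3, ...) {
  spo2_record(rep(level, n), fs = fs, ...)
}

# piecewise-linear V dip: flat, linear down over down_s, linear up over up_s,
# flat again; optionally quantized to integer percent
dip_record <- function(top = 97, bottom = 92, down_s = 30, up_s = 30,
                       flank_s = 100, fs = 3, quantize = FALSE, tail_s = flank_s) {
  nd <- round(down_s * fs); nu <- round(up_s * fs)
  sig <- c(rep(top, round(flank_s * fs)),
           top - (top - bottom) * seq_len(nd) / nd,
           bottom + (top - bottom) * seq_len(nu) / nu,
           rep(top, round(tail_s * fs)))
  if (quantize) sig <- round(sig)
  spo2_record(sig, fs = fs)
}

# random quantized night of a given duration, preprocessed without trimming
random_preprocessed_night <- function(seed, duration_h = 1 / 6,
                                      rate = NULL, noise = NULL,
                                      invalid_frac = NULL) {
  draws <- withr::with_seed((seed * 17 + 5) %% 2147483629,
                            stats::runif(3))
  r <- if (is.null(rate)) 60 * draws[1] else rate
  nz <- if (is.null(noise)) 0.6 * draws[2] else noise
  iv <- if (is.null(invalid_frac)) 0.1 * draws[3] else invalid_frac
  cfg <- night_sim_config(duration_h = duration_h, event_rate_per_h = r,
                          noise_sd = nz, invalid_frac = iv, seed = seed)
  rec <- simulate_night(cfg)$record
  rec <- mark_invalid(rec)
  median_filter_spo2(rec)
}
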