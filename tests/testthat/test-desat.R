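test_that("constant and shallow signals yield no episodes", {
  expect_equal(nrow(detect_episodes(flat_record())), 0)
  shallow <- dip_record(top = 97, bottom = 95)        # 2% dip, below threshold
  expect_equal(nrow(detect_episodes(shallow)), 0)
})

test_that("a V-shaped dip is one fully recovered episode", {
  rec <- dip_record(top = 97, bottom = 92, down_s = 30, up_s = 30)
  ep <- detect_episodes(rec)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$drop_magnitude, 5)
  expect_true(ep$recovered_fully)
  expect_lt(abs(ep$onset_s - 100), 2)                 # decline starts at 100 s
  expect_episodes_match(ep, oracle_detect(rec))
})

test_that("non-recovering episodes end at the 2-minute fallback maximum", {
  fs <- 3
  sig <- c(rep(97, 300),
           97 - 7 * seq_len(60) / 60,                 # drop to 90 over 20 s
           90 + 3 * seq_len(30) / 30,                 # rise to 93 over 10 s
           rep(93, 900),                              # 5-min plateau at 93
           rep(97, 300))
  rec <- spo2_record(sig, fs = fs)
  ep <- detect_episodes(rec)
  expect_equal(nrow(ep), 1)
  expect_false(ep$recovered_fully)
  # ends at the first sample attaining the window maximum (93)
  expect_equal(rec$samples[ep$recovery_end_idx], 93)
  expect_lte(ep$end_s - ep$nadir_s, 120)
  expect_equal(ep$recovery_end_idx, 300 + 60 + 30)
})

test_that("a new qualifying decline closes the running episode", {
  fs <- 3
  ramp <- function(a, b, s) a + (b - a) * seq_len(round(s * fs)) / round(s * fs)
  sig <- c(rep(97, 150), ramp(97, 91, 30), ramp(91, 95, 20),
           ramp(95, 90, 25), ramp(90, 97, 40), rep(97, 150))
  rec <- spo2_record(sig, fs = fs)
  ep <- detect_episodes(rec)
  expect_equal(nrow(ep), 2)
  expect_false(ep$recovered_fully[1])
  expect_equal(rec$samples[ep$recovery_end_idx[1]], 95)
  expect_true(ep$recovered_fully[2])
  # the first episode ends where the second begins: no interior overlap
  expect_equal(ep$recovery_end_idx[1], ep$drop_onset_idx[2])
  expect_episodes_match(ep, oracle_detect(rec))
})

test_that("episodes do not span long invalid gaps", {
  fs <- 3
  ramp <- function(a, b, s) a + (b - a) * seq_len(round(s * fs)) / round(s * fs)
  sig <- c(rep(97, 150), ramp(97, 91, 30), rep(0, round(20 * fs)),
           ramp(91, 97, 30), rep(97, 150))
  rec <- mark_invalid(spo2_record(sig, fs = fs))
  ep <- detect_episodes(rec, gap_tolerance_s = 10)
  gap_start <- 150 + 90 + 1
  gap_end <- 150 + 90 + 60
  expect_true(all(ep$recovery_end_idx < gap_start | ep$drop_onset_idx > gap_end))
  expect_episodes_match(ep, oracle_detect(rec))
})

test_that("baselines are the windowed pre-recovery maximum", {
  # flat level before the dip
  rec <- dip_record(top = 97, bottom = 91)
  ep <- detect_episodes(rec)
  expect_equal(ep$baseline_level, 97)

  # slow drift 98 -> 96 in the 100 s before recovery onset: baseline is 98
  fs <- 3
  sig <- c(rep(98, 60), 98 - 2 * seq_len(270) / 270,          # drift to 96
           96 - 4 * seq_len(30) / 30,                         # drop to 92
           92 + 6 * seq_len(60) / 60, rep(98, 150))
  rec2 <- spo2_record(sig, fs = fs)
  ep2 <- detect_episodes(rec2)
  expect_equal(nrow(ep2), 1)
  expect_equal(compute_baseline(rec2, ep2[1, ]), 98)

  # recovery onset early in the record: window truncates at the start
  rec3 <- dip_record(top = 97, bottom = 91, flank_s = 20, down_s = 20)
  ep3 <- detect_episodes(rec3)
  expect_equal(ep3$baseline_level, 97)
})

test_that("burden matches the analytic triangle and the rectangle-rule oracle", {
  rec <- dip_record(top = 97, bottom = 91, down_s = 30, up_s = 30)
  ep <- detect_episodes(rec)
  expect_equal(nrow(ep), 1)
  expect_lt(abs(ep$burden - 180) / 180, 0.02)          # triangle area 6*60/2
  expect_lt(abs(ep$normalized_burden - 3.0) / 3.0, 0.02)

  b <- compute_burden(rec, ep[1, ])
  expect_equal(b$burden, ep$burden, tolerance = 1e-12)

  # doubling fs changes the burden by < 1% (discretization consistency)
  rec6 <- dip_record(top = 97, bottom = 91, down_s = 30, up_s = 30, fs = 6)
  ep6 <- detect_episodes(rec6)
  expect_lt(abs(ep6$burden - ep$burden) / ep$burden, 0.01)
})

test_that("burdens are invariant to level shifts of the whole signal", {
  rec <- dip_record(top = 97, bottom = 91, quantize = TRUE)
  up <- rec
  up$samples <- up$samples + 2
  expect_equal(detect_episodes(up)$burden, detect_episodes(rec)$burden)
})

test_that("detector equals the brute-force scanner on random nights", {
  withr::with_seed(77, {
    for (s in 1:150) {
      rec <- random_preprocessed_night(seed = 20000 + s)
      expect_episodes_match(detect_episodes(rec), oracle_detect(rec),
                            label = paste("night", s))
    }
  })
})

test_that("noise-free injected events are each detected exactly once", {
  cfg <- night_sim_config(duration_h = 4, event_rate_per_h = 8, noise_sd = 0,
                          baseline_drift_sd = 0, invalid_frac = 0,
                          n_events = 12, edge_margin_s = 60, seed = 5)
  sim <- simulate_night(cfg)
  rec <- median_filter_spo2(mark_invalid(sim$record))
  ep <- detect_episodes(rec)
  expect_equal(nrow(ep), 12)
  expect_lt(max(abs(sort(ep$onset_s) - sort(sim$truth$onset_s))), 5)
})

test_that("unpreprocessed records are rejected", {
  raw <- spo2_record(c(97, 0, 96))                     # zero still marked valid
  expect_error(detect_episodes(raw), "preprocess")
})

test_that("the ODI convenience counts deep episodes per valid hour", {
  rec <- dip_record(top = 97, bottom = 91, flank_s = 1800 - 30, quantize = TRUE)
  ep <- detect_episodes(rec)
  hours <- record_duration(rec, valid_only = TRUE) / 3600
  expect_equal(odi(ep, rec), 1 / hours)
  expect_equal(odi(ep, rec, min_drop = 7), 0)
})
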