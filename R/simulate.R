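#' Configuration for a simulated overnight SpO2 recording
#'
#' Defaults emulate the signal characteristics the detection pipeline assumes:
#' an 8-hour night sampled at 3 Hz with 1% quantization, a stable baseline
#' near 96.5% with slow drift, desaturation events arriving as a Poisson
#' process, Gaussian measurement noise, and contiguous invalid (zero)
#' dropouts.
#'
#' Events have a piecewise drop / nadir-plateau / exponential-recovery shape:
#' a linear decline over the first 30% of the event (capped at 12 s, since
#' airway obstruction desaturates quickly and a sharp fall keeps event onsets
#' well defined on the quantized trace), a plateau at the nadir (at least
#' 6 s, so the full depth survives the 10-s median filter), and an
#' exponential-like return to baseline. Depths are Normal(5, 1.5) truncated at
#' 3% so every injected event satisfies the detector's minimum drop; durations
#' are Normal(45, 15) truncated at 15 s.
#'
#' @param duration_h Night length in hours.
#' @param fs Sampling rate in Hz.
#' @param baseline_mean Baseline SpO2 in percent.
#' @param baseline_drift_sd SD of slow baseline drift in percent.
#' @param event_rate_per_h Poisson event rate per hour.
#' @param depth_mean,depth_sd,depth_min Event depth distribution (percent).
#' @param dur_mean,dur_sd,dur_min Event duration distribution (seconds).
#' @param noise_sd Gaussian measurement noise SD in percent.
#' @param invalid_frac Fraction of samples zeroed in contiguous blocks
#'   (must be below 0.5 to keep records eligible).
#' @param edge_margin_s Keep events out of the first/last this many seconds
#'   (0 places events anywhere; set to the trim length when injected events
#'   must survive edge trimming).
#' @param n_events If non-`NULL`, inject exactly this many events instead of
#'   drawing a Poisson count.
#' @param seed Integer seed; all of the night's randomness flows from it.
#' @return A list of class `night_sim_config`.
#' @export
night_sim_config <- function(duration_h = 8, fs = 3, baseline_mean = 96.5,
                             baseline_drift_sd = 0.3, event_rate_per_h = 15,
                             depth_mean = 5, depth_sd = 1.5, depth_min = 3,
                             dur_mean = 45, dur_sd = 15, dur_min = 15,
                             noise_sd = 0.4, invalid_frac = 0.02,
                             edge_margin_s = 0, n_events = NULL, seed = 1) {
  if (event_rate_per_h < 0) stop("event_rate_per_h must be non-negative")
  if (invalid_frac < 0 || invalid_frac >= 0.5)
    stop("invalid_frac must be in [0, 0.5)")
  if (depth_min < 0 || dur_min <= 0) stop("invalid depth/duration truncation")
  structure(as.list(environment()), class = "night_sim_config")
}

rnorm_trunc <- function(n, mean, sd, lower) {
  if (n == 0L) return(numeric())
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:50) {
    bad <- x < lower
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmax(x, lower)
}

# drop / nadir-plateau / recovery phase lengths for one event. The drop ramp
# is capped at 12 s (airway events desaturate quickly), which also bounds the
# quantization-induced lag between the physical onset and the first 1% step.
event_phases <- function(dur) {
  d_drop <- min(0.3 * dur, 12)
  d_plat <- max(6, 0.15 * dur)
  if (d_drop + d_plat >= dur) {          # very short events: drop + plateau
    d_drop <- 0.4 * dur
    d_plat <- dur - d_drop
  }
  list(drop = d_drop, plat = d_plat, rec = dur - d_drop - d_plat)
}

# deficit profile of one event on a per-sample time grid u in [0, dur]
event_deficit <- function(u, depth, dur) {
  ph <- event_phases(dur)
  d_drop <- ph$drop
  d_plat <- ph$plat
  d_rec <- ph$rec
  out <- numeric(length(u))
  in_drop <- u >= 0 & u < d_drop
  in_plat <- u >= d_drop & u < d_drop + d_plat
  in_rec <- u >= d_drop + d_plat & u <= dur
  out[in_drop] <- depth * u[in_drop] / d_drop
  out[in_plat] <- depth
  if (d_rec > 0) {
    w <- (u[in_rec] - d_drop - d_plat) / d_rec
    out[in_rec] <- depth * (exp(-3 * w) - exp(-3)) / (1 - exp(-3))
  }
  out
}

#' Simulate one overnight SpO2 recording with known ground truth
#'
#' Builds baseline + drift, places non-overlapping desaturation events by a
#' Poisson process (events that cannot be placed without overlap after
#' repeated attempts are dropped, and the returned ground truth lists exactly
#' the events present in the signal), adds Gaussian noise, quantizes to
#' integer percent, and zeroes `invalid_frac` of the samples in contiguous
#' blocks. Deterministic for a fixed config.
#'
#' @param config A [night_sim_config()].
#' @param subject_id,phase Passed to the returned [spo2_record()].
#' @return A list with elements `record` (raw, unpreprocessed
#'   [spo2_record()]) and `truth` (data.frame of injected events:
#'   `onset_s`, `nadir_s`, `end_s`, `depth`, `duration_s`).
#' @export
simulate_night <- function(config, subject_id = "sim", phase = "preop") {
  stopifnot(inherits(config, "night_sim_config"))
  cfg <- config
  n <- as.integer(round(cfg$duration_h * 3600 * cfg$fs))
  total_s <- n / cfg$fs
  t <- (seq_len(n) - 1) / cfg$fs

  with_seed(cfg$seed, {
    # slow drift: two random-phase sinusoids (periods ~2 h and ~45 min)
    drift <- if (cfg$baseline_drift_sd > 0) {
      ph <- stats::runif(2, 0, 2 * pi)
      cfg$baseline_drift_sd / sqrt(2) *
        (sin(2 * pi * t / 7200 + ph[1]) + sin(2 * pi * t / 2700 + ph[2]))
    } else rep(0, n)
    signal <- cfg$baseline_mean + drift

    k <- if (!is.null(cfg$n_events)) cfg$n_events
         else stats::rpois(1, cfg$event_rate_per_h * cfg$duration_h)
    depths <- rnorm_trunc(k, cfg$depth_mean, cfg$depth_sd, cfg$depth_min)
    durs <- rnorm_trunc(k, cfg$dur_mean, cfg$dur_sd, cfg$dur_min)

    # sequential placement with a 15-s guard gap; overlapping draws rejected
    onsets <- numeric(0)
    placed <- integer(0)
    gap <- 15
    lo <- cfg$edge_margin_s
    for (i in seq_len(k)) {
      hi <- total_s - cfg$edge_margin_s - durs[i]
      if (hi <= lo) next
      for (try in 1:200) {
        cand <- stats::runif(1, lo, hi)
        if (!any(cand < onsets + durs[placed] + gap &
                 onsets < cand + durs[i] + gap)) {
          onsets <- c(onsets, cand)
          placed <- c(placed, i)
          break
        }
      }
    }
    ord <- order(onsets)
    onsets <- onsets[ord]
    depths <- depths[placed][ord]
    durs <- durs[placed][ord]

    for (i in seq_along(onsets)) {
      i1 <- max(1L, ceiling(onsets[i] * cfg$fs) + 1L)
      i2 <- min(n, floor((onsets[i] + durs[i]) * cfg$fs) + 1L)
      if (i2 < i1) next
      u <- t[i1:i2] - onsets[i]
      signal[i1:i2] <- signal[i1:i2] - event_deficit(u, depths[i], durs[i])
    }

    if (cfg$noise_sd > 0) signal <- signal + stats::rnorm(n, 0, cfg$noise_sd)
    signal <- pmin(round(signal), 100)

    if (cfg$invalid_frac > 0) {
      n_bad <- round(cfg$invalid_frac * n)
      block <- as.integer(round(30 * cfg$fs))
      bad <- logical(n)
      attempts <- 0L
      while (sum(bad) < n_bad && attempts < 10000L) {
        attempts <- attempts + 1L
        s <- sample.int(n - block + 1L, 1L)
        bad[s:(s + block - 1L)] <- TRUE
      }
      signal[bad] <- 0
    }

    truth <- data.frame(
      onset_s = onsets,
      nadir_s = onsets + vapply(durs, function(d) event_phases(d)$drop,
                                numeric(1)),
      end_s = onsets + durs,
      depth = depths,
      duration_s = durs
    )
    list(record = spo2_record(signal, fs = cfg$fs, subject_id = subject_id,
                              phase = phase),
         truth = truth)
  })
}

#' Configuration for a simulated surgical cohort
#'
#' Defaults mirror the structure of the clinical cohort the method targets:
#' equal numbers of women and men, BMI ~ Normal(30.3, 6.9), a 59%
#' cardiorespiratory-comorbidity prevalence, per-subject desaturation event
#' rates from a gamma distribution with mean 20 and SD 19 events/h (matching
#' reported apnea-hypopnea index summaries), and a postoperative respiratory
#' depression outcome drawn from a logistic model on standardized severity
#' (the true event rate), sex, standardized BMI, and comorbidity. When
#' `outcome_coefs$intercept` is `NULL` it is calibrated by Monte Carlo so the
#' expected outcome prevalence equals `target_prevalence` (default 0.17).
#'
#' @param n_subjects Number of subjects.
#' @param rate_mean,rate_sd Mean and SD of the per-subject event rate
#'   (events/h); a gamma distribution with these moments is used.
#' @param outcome_coefs Named list: `intercept` (or `NULL` to calibrate),
#'   `severity`, `sex_f`, `bmi`, `comorbidity`. Severity and BMI enter as
#'   z-scores of their generating distributions.
#' @param target_prevalence Outcome prevalence used to calibrate the
#'   intercept when it is `NULL`.
#' @param sex_ratio Fraction of women.
#' @param bmi_mean,bmi_sd BMI distribution (kg/m^2), truncated at 16.
#' @param comorbidity_prev Cardiorespiratory-comorbidity prevalence.
#' @param night Template [night_sim_config()] for each preoperative night;
#'   its `event_rate_per_h` and `seed` are overridden per subject.
#' @param seed Integer master seed; per-subject streams are derived from it.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_subjects = 158, rate_mean = 20, rate_sd = 19,
                              outcome_coefs = list(intercept = NULL,
                                                   severity = 1.2,
                                                   sex_f = 0.5, bmi = 0.4,
                                                   comorbidity = 0.4),
                              target_prevalence = 0.17, sex_ratio = 0.5,
                              bmi_mean = 30.3, bmi_sd = 6.9,
                              comorbidity_prev = 0.59,
                              night = night_sim_config(), seed = 1) {
  if (n_subjects < 1) stop("n_subjects must be positive")
  if (rate_mean <= 0 || rate_sd <= 0) stop("rate distribution must be positive")
  structure(as.list(environment()), class = "cohort_sim_config")
}

calibrate_intercept <- function(cfg, n_mc = 20000) {
  with_seed(derive_seed(cfg$seed, 999983L), {
    z_sev <- (stats::rgamma(n_mc, shape = (cfg$rate_mean / cfg$rate_sd)^2,
                            rate = cfg$rate_mean / cfg$rate_sd^2) -
                cfg$rate_mean) / cfg$rate_sd
    sexf <- stats::rbinom(n_mc, 1, cfg$sex_ratio)
    z_bmi <- stats::rnorm(n_mc)
    com <- stats::rbinom(n_mc, 1, cfg$comorbidity_prev)
    b <- cfg$outcome_coefs
    eta <- b$severity * z_sev + b$sex_f * sexf + b$bmi * z_bmi +
      b$comorbidity * com
    stats::uniroot(function(b0) mean(stats::plogis(b0 + eta)) -
                     cfg$target_prevalence,
                   interval = c(-15, 10), tol = 1e-8)$root
  })
}

#' Simulate a full preoperative cohort with known ground truth
#'
#' For each subject: draws covariates and a true desaturation event rate
#' (the severity ground truth, exported as a pseudo apnea-hypopnea index
#' `ahi`), simulates the preoperative night, runs the preprocessing and
#' feature-extraction pipeline on it, and draws the postoperative respiratory
#' depression label from the logistic outcome model. All randomness flows
#' from the master seed through per-subject derived streams, so generation is
#' reproducible and order-independent.
#'
#' @param config A [cohort_sim_config()].
#' @param trim_min,median_window_s Preprocessing settings applied to each
#'   simulated night before feature extraction.
#' @param min_drop Episode detection threshold passed to
#'   [extract_features()].
#' @param keep_records If `TRUE`, attach the raw night records as an
#'   attribute `records` (memory-heavy; default `FALSE`).
#' @return A `data.table` with one row per subject: `subject_id`, `sex`,
#'   `bmi`, `comorbidity`, `ahi` (true event rate), `rd_label`, `eligible`,
#'   and the seven feature columns.
#' @export
simulate_cohort <- function(config, trim_min = 15, median_window_s = 10,
                            min_drop = 3, keep_records = FALSE) {
  stopifnot(inherits(config, "cohort_sim_config"))
  cfg <- config
  b <- cfg$outcome_coefs
  b0 <- if (is.null(b$intercept)) calibrate_intercept(cfg) else b$intercept

  covs <- with_seed(derive_seed(cfg$seed, 1L), {
    data.frame(
      rate = stats::rgamma(cfg$n_subjects,
                           shape = (cfg$rate_mean / cfg$rate_sd)^2,
                           rate = cfg$rate_mean / cfg$rate_sd^2),
      sexf = stats::rbinom(cfg$n_subjects, 1, cfg$sex_ratio),
      bmi = pmax(16, stats::rnorm(cfg$n_subjects, cfg$bmi_mean, cfg$bmi_sd)),
      com = stats::rbinom(cfg$n_subjects, 1, cfg$comorbidity_prev),
      u_out = stats::runif(cfg$n_subjects)
    )
  })
  z_sev <- (covs$rate - cfg$rate_mean) / cfg$rate_sd
  z_bmi <- (covs$bmi - cfg$bmi_mean) / cfg$bmi_sd
  eta <- b0 + b$severity * z_sev + b$sex_f * covs$sexf + b$bmi * z_bmi +
    b$comorbidity * covs$com
  rd <- as.integer(covs$u_out < stats::plogis(eta))

  rows <- vector("list", cfg$n_subjects)
  records <- if (keep_records) vector("list", cfg$n_subjects) else NULL
  for (i in seq_len(cfg$n_subjects)) {
    ncfg <- cfg$night
    ncfg$event_rate_per_h <- covs$rate[i]
    ncfg$seed <- derive_seed(cfg$seed, 1000L + i)
    sim <- simulate_night(ncfg, subject_id = sprintf("S%03d", i))
    pp <- preprocess_spo2(sim$record, trim_min = trim_min,
                          median_window_s = median_window_s)
    feat <- if (pp$report$eligible)
      extract_features(pp$record, min_drop = min_drop)
    else as.data.frame(setNames(as.list(rep(NA_real_, 9)),
                                c(spo2_feature_names(), "n_episodes",
                                  "analysis_duration_s")))
    rows[[i]] <- cbind(
      data.frame(subject_id = sprintf("S%03d", i),
                 sex = ifelse(covs$sexf[i] == 1, "F", "M"),
                 bmi = covs$bmi[i], comorbidity = covs$com[i],
                 ahi = covs$rate[i], rd_label = rd[i],
                 eligible = pp$report$eligible),
      as.data.frame(feat)
    )
    if (keep_records) records[[i]] <- sim$record
  }
  out <- data.table::rbindlist(rows)
  if (keep_records) attr(out, "records") <- records
  out[]
}

#' Simulate a postoperative night consistent with an outcome label
#'
#' Generates a night like [simulate_night()] but with milder background
#' desaturations, and, when `rd_label` is true, injects one hypoxemia run
#' with SpO2 near 81% lasting 200--420 s so that
#' [detect_respiratory_depression()] recovers the label.
#'
#' @param config A [night_sim_config()] (event depths are capped so
#'   background events stay above the 85% threshold minus transient dips).
#' @param rd_label Logical outcome to encode in the signal.
#' @param subject_id Subject identifier.
#' @return A list with `record` and `truth` as in [simulate_night()].
#' @export
simulate_postop_night <- function(config, rd_label, subject_id = "sim") {
  cfg <- config
  cfg$depth_mean <- min(cfg$depth_mean, 4)
  cfg$depth_sd <- min(cfg$depth_sd, 1)
  sim <- simulate_night(cfg, subject_id = subject_id, phase = "postop")
  if (isTRUE(as.logical(rd_label))) {
    rec <- sim$record
    n <- length(rec$samples)
    with_seed(derive_seed(cfg$seed, 424243L), {
      dur_s <- stats::runif(1, 200, 420)
      len <- as.integer(round(dur_s * cfg$fs))
      margin <- as.integer(round(max(cfg$edge_margin_s, 960) * cfg$fs))
      s <- sample.int(max(1L, n - 2L * margin - len), 1L) + margin
      idx <- s:(s + len - 1L)
      # direct assignment also overwrites any invalid zeros so the hypoxemia
      # run is contiguous and survives validity marking
      rec$samples[idx] <- round(81 + stats::rnorm(len, 0, 0.5))
    })
    sim$record <- rec
  }
  sim
}
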