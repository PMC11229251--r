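# small deterministic cohort with a tunable signal-to-noise link
toy_cohort <- function(n = 100, pos_frac = 0.2, signal = 2, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(1, 0), c(round(n * pos_frac), n - round(n * pos_frac)))
    data.frame(
      subject_id = sprintf("T%03d", seq_len(n)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      bmi = stats::rnorm(n, 30, 6),
      comorbidity = stats::rbinom(n, 1, 0.5),
      feat = stats::rnorm(n, mean = signal * y),
      rd_label = y)
  })
}

test_that("stratified splits match prevalence, sex ratio and BMI spread", {
  rows <- toy_cohort(n = 100, pos_frac = 0.2)
  sp <- stratified_split(rows, test_frac = 0.2, seed = 3)
  expect_equal(nrow(sp$test), 20)
  expect_equal(sum(sp$test$rd_label), 4)
  expect_equal(nrow(sp$train) + nrow(sp$test), 100)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  # sex ratio within one subject of the cohort ratio
  expect_lte(abs(mean(sp$test$sex == "F") - mean(rows$sex == "F")), 1 / 20)

  expect_identical(stratified_split(rows, seed = 3)$test$subject_id,
                   sp$test$subject_id)
  expect_false(identical(stratified_split(rows, seed = 4)$test$subject_id,
                         sp$test$subject_id))

  # stratification quality across seeds
  devs <- vapply(1:100, function(s) {
    te <- stratified_split(rows, seed = s)$test
    abs(mean(te$rd_label) - mean(rows$rd_label))
  }, numeric(1))
  expect_lt(mean(devs), 0.02)

  bad <- rows; bad$rd_label <- c(1, rep(0, 99))
  expect_error(stratified_split(bad), "fewer than 2")
})

test_that("confusion counts give the textbook sensitivity and specificity", {
  cm <- confusion_metrics(tp = 7, fp = 2, tn = 8, fn = 3)
  expect_identical(cm$sensitivity, 0.7)
  expect_identical(cm$specificity, 0.8)
})

test_that("a separable feature is classified perfectly", {
  rows <- toy_cohort(n = 80, signal = 50, seed = 5)
  sp <- stratified_split(rows, seed = 1)
  fit <- fit_predict_once(sp$train, sp$test, "feat")
  expect_equal(fit$auc, 1.0)
  expect_true(all(c(fit$sensitivity, fit$specificity) >= 0, na.rm = TRUE))
  expect_true(all(c(fit$sensitivity, fit$specificity) <= 1, na.rm = TRUE))
})

test_that("repeated evaluation is deterministic and sized correctly", {
  rows <- toy_cohort(n = 80, signal = 1.5, seed = 6)
  ev <- repeated_evaluation(rows, "feat", n_runs = 10, base_seed = 42)
  expect_equal(nrow(ev$per_run), 10)
  expect_equal(ev$n_runs, 10)
  ev2 <- repeated_evaluation(rows, "feat", n_runs = 10, base_seed = 42)
  expect_identical(ev$per_run, ev2$per_run)
  expect_true(all(ev$summary$lo <= ev$summary$mean &
                  ev$summary$mean <= ev$summary$hi))

  evw <- repeated_evaluation(rows, "feat", n_runs = 5, base_seed = 1,
                             stratum = "women")
  expect_equal(evw$stratum, "women")
  expect_equal(nrow(evw$per_run), 5)

  expect_error(repeated_evaluation(rows, "nope", n_runs = 2), "not in table")
})

test_that("an informative feature beats a pure-noise feature", {
  rows <- toy_cohort(n = 150, signal = 2, seed = 7)
  withr::with_seed(8, rows$noise <- stats::rnorm(nrow(rows)))
  ev_sig <- repeated_evaluation(rows, "feat", n_runs = 20, base_seed = 1)
  ev_noise <- repeated_evaluation(rows, "noise", n_runs = 20, base_seed = 1)
  expect_gt(ev_sig$summary["auc", "mean"], ev_noise$summary["auc", "mean"])
  expect_gt(ev_sig$summary["auc", "mean"], 0.75)
})

test_that("AUC is invariant to monotone transforms of a lone feature", {
  rows <- toy_cohort(n = 120, signal = 1.2, seed = 9)
  rows$feat_t <- exp(rows$feat / 2)                     # strictly monotone
  a <- vapply(1:10, function(s) {
    sp <- stratified_split(rows, seed = s)
    fit_predict_once(sp$train, sp$test, "feat", include_sex = FALSE,
                     covariates = character(0))$auc
  }, numeric(1))
  b <- vapply(1:10, function(s) {
    sp <- stratified_split(rows, seed = s)
    fit_predict_once(sp$train, sp$test, "feat_t", include_sex = FALSE,
                     covariates = character(0))$auc
  }, numeric(1))
  # same splits, rank-equivalent predictors: identical test-set rankings
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("Pearson correlation, Fisher interval and strength categories", {
  x <- c(1.2, 2.3, 3.1, 4.8, 5.0, 6.7, 7.1, 8.9, 9.4, 10.2)
  expect_equal(pearson_with_ci(x, x)$r, 1)
  expect_equal(pearson_with_ci(x, x)$strength, "strong")
  expect_equal(pearson_with_ci(x, -x)$r, -1)

  withr::with_seed(10, y <- x + stats::rnorm(10, 0, 2))
  res <- pearson_with_ci(x, y)
  # direct covariance/variance oracle
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_direct, tolerance = 1e-12)
  # hand-computed Fisher interval: tanh(atanh(r) +/- 1.96.../sqrt(n-3))
  half <- stats::qnorm(0.975) / sqrt(10 - 3)
  expect_equal(res$ci95, tanh(atanh(r_direct) + c(-half, half)),
               tolerance = 1e-12)

  expect_error(pearson_with_ci(x[1:3], x[1:3]), "at least 4")
  expect_error(pearson_with_ci(rep(1, 10), x), "zero variance")
})

test_that("strength cutpoints fall at 0.3, 0.6 and 0.8 on |r|", {
  mk <- function(r) structure(list(r = r, ci95 = c(r, r), n = 50,
                                   strength = NULL), class = "spo2_cor")
  # build through the real function on constructed data
  n <- 400
  withr::with_seed(11, {
    x <- stats::rnorm(n)
    for (target in c(0.1, 0.45, 0.7, 0.9)) {
      y <- target * x + sqrt(1 - target^2) * stats::rnorm(n)
      res <- pearson_with_ci(x, y)
      want <- if (abs(res$r) >= 0.8) "strong" else if (abs(res$r) >= 0.6)
        "moderate" else if (abs(res$r) >= 0.3) "fair" else "weak"
      expect_equal(res$strength, want)
    }
  })
})

test_that("sex-correlation comparison uses interval overlap", {
  mk <- function(lo, hi) structure(list(r = (lo + hi) / 2, ci95 = c(lo, hi),
                                        n = 40, strength = "fair"),
                                   class = "spo2_cor")
  expect_equal(compare_sex_correlations(mk(0.5, 0.8), mk(0.7, 0.9)),
               "non-significant")
  expect_equal(compare_sex_correlations(mk(0.1, 0.3), mk(0.5, 0.7)),
               "significant")
  expect_equal(compare_sex_correlations(mk(0.2, 0.4), mk(0.2, 0.4)),
               "non-significant")
})

test_that("feature-vs-reference correlation table reports all features", {
  rows <- toy_cohort(n = 60, seed = 12)
  rows$ahi <- rows$feat * 3 + 5
  for (f in spo2_feature_names()) rows[[f]] <- rows$feat
  tab <- correlate_features(rows)
  expect_equal(nrow(tab), 7)
  expect_true(all(tab$lo <= tab$r & tab$r <= tab$hi))
  expect_true(all(tab$r > 0.99))
})
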