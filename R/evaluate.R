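#' Stratified train/test split
#'
#' Splits subject rows into training and test sets so the test set matches
#' the cohort in outcome prevalence, sex ratio, and BMI distribution. Test
#' counts are fixed per outcome class (largest-remainder allocation across
#' sex cells within class), and within each class-by-sex cell rows are sorted
#' by BMI and sampled systematically (one draw per BMI block), which keeps the
#' BMI distribution of the test set matched to the cohort.
#'
#' @param rows A data.frame with columns `rd_label` (0/1), `sex` (F/M), `bmi`.
#' @param test_frac Fraction of rows in the test set (default 0.2).
#' @param seed Integer seed controlling the within-block draws.
#' @return A list with data.frame elements `train` and `test`.
#' @export
stratified_split <- function(rows, test_frac = 0.2, seed = 1) {
  rows <- as.data.frame(rows)
  stopifnot(all(c("rd_label", "sex", "bmi") %in% names(rows)))
  if (length(unique(rows$rd_label)) < 2L)
    stop("both outcome classes must be present")
  test_idx <- integer(0)
  with_seed(seed, {
    for (cls in sort(unique(rows$rd_label))) {
      cls_idx <- which(rows$rd_label == cls)
      n_cls <- length(cls_idx)
      if (n_cls < 2L)
        stop("outcome class ", cls, " has fewer than 2 members")
      m <- round(n_cls * test_frac)
      cells <- split(cls_idx, rows$sex[cls_idx])
      sizes <- lengths(cells)
      quota <- sizes * m / n_cls
      alloc <- floor(quota)
      short <- m - sum(alloc)
      if (short > 0) {
        extra <- order(quota - alloc, sizes, decreasing = TRUE)[seq_len(short)]
        alloc[extra] <- alloc[extra] + 1L
      }
      for (ci in seq_along(cells)) {
        k <- alloc[ci]
        if (k == 0L) next
        cell <- cells[[ci]][order(rows$bmi[cells[[ci]]])]
        block <- ceiling(seq_along(cell) * k / length(cell))
        pick <- vapply(seq_len(k), function(bk) {
          members <- cell[block == bk]
          members[sample.int(length(members), 1L)]
        }, numeric(1))
        test_idx <- c(test_idx, pick)
      }
    }
  })
  test_idx <- sort(test_idx)
  list(train = rows[-test_idx, , drop = FALSE],
       test = rows[test_idx, , drop = FALSE])
}

#' Sensitivity and specificity from confusion counts
#'
#' @param tp,fp,tn,fn Confusion-matrix counts at the classification
#'   threshold.
#' @return A list with the counts plus `sensitivity` = TP/(TP+FN) and
#'   `specificity` = TN/(TN+FP).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

build_design <- function(rows, feature_name, covariates, include_sex,
                         center, scale_) {
  X <- cbind(feature = (rows[[feature_name]] - center["feat"]) / scale_["feat"])
  if ("bmi" %in% covariates)
    X <- cbind(X, bmi = (rows$bmi - center["bmi"]) / scale_["bmi"])
  if ("comorbidity" %in% covariates)
    X <- cbind(X, comorbidity = as.numeric(rows$comorbidity))
  if (include_sex) X <- cbind(X, sex_f = as.numeric(rows$sex == "F"))
  if (ncol(X) == 1L)  # glmnet needs >= 2 columns; a zero column is inert
    X <- cbind(X, .const = 0)
  X
}

#' Fit one ridge-logistic model and evaluate it on a test set
#'
#' Fits an L2-regularized logistic regression of the outcome on one overnight
#' SpO2 measure plus sex, BMI, and the comorbidity flag. Continuous
#' predictors are standardized with training-fold statistics only. Class
#' weights are inversely proportional to class frequency in the training
#' fold. Performance is the AUC-ROC of the predicted probabilities on the
#' test set plus sensitivity and specificity at a probability threshold
#' of 0.5.
#'
#' @param train,test Data frames with the feature column plus `sex`, `bmi`,
#'   `comorbidity`, `rd_label`.
#' @param feature_name Name of the feature column to use as the predictor of
#'   interest.
#' @param lambda Ridge penalty; default `1/nrow(train)` (unit
#'   inverse-regularization strength).
#' @param include_sex Include the sex covariate (drop it inside single-sex
#'   strata).
#' @param covariates Demographic covariates to adjust for (default BMI and
#'   the comorbidity flag; sex is controlled by `include_sex`).
#' @return A list with `auc`, `sensitivity`, `specificity`, `confusion`
#'   (from [confusion_metrics()]), and `coef` (named coefficient vector on
#'   the standardized scale).
#' @export
fit_predict_once <- function(train, test, feature_name, lambda = NULL,
                             include_sex = TRUE,
                             covariates = c("bmi", "comorbidity")) {
  train <- as.data.frame(train)
  test <- as.data.frame(test)
  y <- train$rd_label
  if (length(unique(y)) < 2L)
    stop("training fold has a single outcome class")
  center <- c(feat = mean(train[[feature_name]]),
              bmi = if ("bmi" %in% covariates) mean(train$bmi) else 0)
  scale_ <- c(feat = stats::sd(train[[feature_name]]),
              bmi = if ("bmi" %in% covariates) stats::sd(train$bmi) else 1)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  Xtr <- build_design(train, feature_name, covariates, include_sex,
                      center, scale_)
  Xte <- build_design(test, feature_name, covariates, include_sex,
                      center, scale_)
  w <- length(y) / (2 * ifelse(y == 1, sum(y == 1), sum(y == 0)))
  if (is.null(lambda)) lambda <- 1 / nrow(Xtr)
  fit <- withCallingHandlers(
    glmnet::glmnet(Xtr, y, family = "binomial", alpha = 0,
                   lambda = lambda, weights = w, standardize = FALSE),
    # small minority classes are routine here (imbalanced strata); the class
    # weights are designed for exactly that, so silence glmnet's advisory
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  p <- as.numeric(stats::predict(fit, newx = Xte, type = "response"))
  ytest <- test$rd_label
  if (length(unique(ytest)) < 2L)
    stop("test fold has a single outcome class; AUC undefined ",
         "(cohort too small for the requested test fraction)")
  auc <- as.numeric(pROC::auc(
    pROC::roc(response = ytest, predictor = p, levels = c(0, 1),
              direction = "<", quiet = TRUE)))
  pred <- as.integer(p >= 0.5)
  cm <- confusion_metrics(tp = sum(pred == 1 & ytest == 1),
                          fp = sum(pred == 1 & ytest == 0),
                          tn = sum(pred == 0 & ytest == 0),
                          fn = sum(pred == 0 & ytest == 1))
  cf <- as.numeric(stats::coef(fit))
  names(cf) <- rownames(stats::coef(fit))
  list(auc = auc, sensitivity = cm$sensitivity,
       specificity = cm$specificity, confusion = cm, coef = cf)
}

#' Repeated stratified-holdout evaluation of one feature
#'
#' Repeats the stratified 80/20 split, ridge-logistic fit, and test-set
#' evaluation `n_runs` times with consecutive seeds, and reports the mean and
#' percentile 95% confidence interval of AUC, sensitivity, and specificity
#' across runs. `stratum` restricts the cohort to one sex (the sex covariate
#' is then dropped from the model).
#'
#' @param rows Cohort data.frame (see [fit_predict_once()]).
#' @param feature_name Feature column to evaluate.
#' @param n_runs Number of split/fit/evaluate cycles (default 100).
#' @param base_seed First split seed; run r uses `base_seed + r - 1`.
#' @param test_frac Test fraction per split.
#' @param stratum `"all"`, `"women"`, or `"men"`.
#' @param lambda Ridge penalty passed to [fit_predict_once()].
#' @param covariates Demographic covariates passed to [fit_predict_once()].
#' @return An object of class `spo2_eval`: list with `per_run` (data.frame
#'   of auc/sensitivity/specificity per run), `summary` (mean and 2.5/97.5
#'   percentiles per metric), `severity_coef` (per-run coefficient of the
#'   feature), `n_runs`, `feature_name`, `stratum`.
#' @export
repeated_evaluation <- function(rows, feature_name, n_runs = 100,
                                base_seed = 1, test_frac = 0.2,
                                stratum = c("all", "women", "men"),
                                lambda = NULL,
                                covariates = c("bmi", "comorbidity")) {
  stratum <- match.arg(stratum)
  rows <- as.data.frame(rows)
  if (stratum != "all")
    rows <- rows[rows$sex == if (stratum == "women") "F" else "M", ,
                 drop = FALSE]
  if (!feature_name %in% names(rows))
    stop("feature '", feature_name, "' not in table; available: ",
         paste(intersect(spo2_feature_names(), names(rows)), collapse = ", "))
  include_sex <- stratum == "all"
  per <- vector("list", n_runs)
  coefs <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    sp <- stratified_split(rows, test_frac = test_frac,
                           seed = base_seed + r - 1L)
    fit <- fit_predict_once(sp$train, sp$test, feature_name, lambda = lambda,
                            include_sex = include_sex,
                            covariates = covariates)
    per[[r]] <- data.frame(run = r, auc = fit$auc,
                           sensitivity = fit$sensitivity,
                           specificity = fit$specificity)
    coefs[r] <- fit$coef[["feature"]]
  }
  per_run <- do.call(rbind, per)
  summarise <- function(x) c(mean = mean(x, na.rm = TRUE),
                             lo = unname(stats::quantile(x, 0.025, na.rm = TRUE)),
                             hi = unname(stats::quantile(x, 0.975, na.rm = TRUE)))
  summary <- rbind(auc = summarise(per_run$auc),
                   sensitivity = summarise(per_run$sensitivity),
                   specificity = summarise(per_run$specificity))
  structure(
    list(per_run = per_run, summary = as.data.frame(summary),
         severity_coef = coefs, n_runs = n_runs,
         feature_name = feature_name, stratum = stratum),
    class = "spo2_eval"
  )
}

#' @export
print.spo2_eval <- function(x, ...) {
  cat(sprintf("<spo2_eval> feature '%s', stratum %s, %d runs\n",
              x$feature_name, x$stratum, x$n_runs))
  s <- x$summary
  for (m in rownames(s))
    cat(sprintf("  %-12s %.3f  [95%% CI %.3f, %.3f]\n",
                m, s[m, "mean"], s[m, "lo"], s[m, "hi"]))
  invisible(x)
}

#' Pearson correlation with a Fisher-transform confidence interval
#'
#' Computes the product-moment correlation, its 95% confidence interval via
#' the Fisher z transform (z +/- 1.96/sqrt(n-3)), and a strength category on
#' the magnitude of r: strong (|r| >= 0.8), moderate (0.6 <= |r| < 0.8),
#' fair (0.3 <= |r| < 0.6), weak (|r| < 0.3).
#'
#' @param x,y Numeric vectors of equal length (n >= 4, finite, non-constant).
#' @return An object of class `spo2_cor`: list with `r`, `ci95` (lo, hi),
#'   `n`, `strength`.
#' @export
pearson_with_ci <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  r <- stats::cor(x, y)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  half <- stats::qnorm(0.975) / sqrt(n - 3)
  # clamp so r is always inside its own interval (degenerate at |r| = 1)
  ci <- c(min(tanh(z - half), r), max(tanh(z + half), r))
  a <- abs(r)
  strength <- if (a >= 0.8) "strong" else if (a >= 0.6) "moderate"
              else if (a >= 0.3) "fair" else "weak"
  structure(list(r = r, ci95 = ci, n = n, strength = strength),
            class = "spo2_cor")
}

#' @export
print.spo2_cor <- function(x, ...) {
  cat(sprintf("<spo2_cor> r = %.3f [%.3f, %.3f], n = %d (%s)\n",
              x$r, x$ci95[1], x$ci95[2], x$n, x$strength))
  invisible(x)
}

#' Compare correlations between sexes by confidence-interval overlap
#'
#' The sex difference in a correlation is called non-significant when the two
#' 95% confidence intervals overlap, and significant otherwise.
#'
#' @param res_f,res_m [pearson_with_ci()] results for women and men.
#' @return `"non-significant"` or `"significant"`.
#' @export
compare_sex_correlations <- function(res_f, res_m) {
  stopifnot(inherits(res_f, "spo2_cor"), inherits(res_m, "spo2_cor"))
  overlap <- res_f$ci95[1] <= res_m$ci95[2] && res_m$ci95[1] <= res_f$ci95[2]
  if (overlap) "non-significant" else "significant"
}

#' Correlation of every SpO2 measure with a reference severity index
#'
#' Convenience wrapper producing one [pearson_with_ci()] row per feature
#' against a reference column such as the apnea-hypopnea index.
#'
#' @param rows Cohort data.frame containing feature columns and `ref`.
#' @param ref Name of the reference column (default `"ahi"`).
#' @param features Feature columns (default the seven overnight measures).
#' @return A data.frame with columns `feature`, `r`, `lo`, `hi`, `n`,
#'   `strength`.
#' @export
correlate_features <- function(rows, ref = "ahi",
                               features = spo2_feature_names()) {
  rows <- as.data.frame(rows)
  if (!ref %in% names(rows)) stop("reference column '", ref, "' not in table")
  out <- lapply(features, function(f) {
    res <- pearson_with_ci(rows[[f]], rows[[ref]])
    data.frame(feature = f, r = res$r, lo = res$ci95[1], hi = res$ci95[2],
               n = res$n, strength = res$strength)
  })
  do.call(rbind, out)
}
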