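# Performance metrics, confidence intervals and model-comparison
# statistics.

#' Confusion matrix
#' @param tp,fp,fn,tn non-negative counts.
#' @return list of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_matrix")
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; any zero
#' marginal gives 0 by convention.
#' @param cm a [confusion_matrix()].
#' @return scalar in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  d <- (cm$tp + cm$fp) * (cm$tp + cm$fn) * (cm$tn + cm$fp) * (cm$tn + cm$fn)
  if (d <= 0) return(0)
  (cm$tp * cm$tn - cm$fp * cm$fn) / sqrt(d)
}

#' Reconstruct a confusion matrix from printed sensitivity/specificity
#'
#' `tp = round(sens/100 * n_pos)`, `tn = round(spec/100 * n_neg)`,
#' complements for `fn`/`fp`.  Used to rebuild published performance rows
#' from their printed operating points.
#' @param sens,spec percentages in `[0, 100]`.
#' @param n_pos,n_neg class sizes.
#' @return a [confusion_matrix()].
#' @export
confusion_from_rates <- function(sens, spec, n_pos, n_neg) {
  stopifnot(sens >= 0, sens <= 100, spec >= 0, spec <= 100)
  tp <- round(sens / 100 * n_pos)
  tn <- round(spec / 100 * n_neg)
  confusion_matrix(tp = tp, fp = n_neg - tn, fn = n_pos - tp, tn = tn)
}

#' Summary rates of a confusion matrix
#' @param cm a [confusion_matrix()].
#' @return named vector: sensitivity, specificity, ppv, npv (percent) and
#'   mcc.
#' @export
cm_rates <- function(cm) {
  c(sensitivity = 100 * cm$tp / (cm$tp + cm$fn),
    specificity = 100 * cm$tn / (cm$tn + cm$fp),
    ppv = 100 * cm$tp / (cm$tp + cm$fp),
    npv = 100 * cm$tn / (cm$tn + cm$fn),
    mcc = mcc(cm))
}

#' Equal sensitivity-specificity threshold
#'
#' Scans the midpoints of consecutive sorted unique probabilities (plus
#' sentinels below and above) and returns the threshold minimising
#' `|sensitivity - specificity|`, ties broken toward the higher
#' sensitivity (lower threshold).
#'
#' @param preds a `prediction_set` (columns `probability`, `label`).
#' @return list `threshold`, `cm` (a [confusion_matrix()]); attribute
#'   `degenerate` when all probabilities coincide.
#' @export
equal_ss_threshold <- function(preds) {
  p <- preds$probability; y <- preds$label
  if (!any(y == 1) || !any(y == 0)) stop("both classes must be present")
  u <- sort(unique(p))
  if (length(u) == 1L) {
    warning("all probabilities identical; degenerate threshold 0.5")
    thr <- 0.5
    cm <- confusion_matrix(sum(p > thr & y == 1), sum(p > thr & y == 0),
                           sum(p <= thr & y == 1), sum(p <= thr & y == 0))
    out <- list(threshold = thr, cm = cm)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  cand <- c(u[1] - 1e-9, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1e-9)
  best <- NULL; best_d <- Inf; best_sens <- -1
  for (thr in cand) {
    sens <- mean(p[y == 1] > thr); spec <- mean(p[y == 0] <= thr)
    d <- abs(sens - spec)
    if (d < best_d - 1e-12 || (d < best_d + 1e-12 && sens > best_sens)) {
      best_d <- d; best_sens <- sens; best <- thr
    }
  }
  cm <- confusion_matrix(sum(p > best & y == 1), sum(p > best & y == 0),
                         sum(p <= best & y == 1), sum(p <= best & y == 0))
  list(threshold = best, cm = cm)
}

#' Rank-based AUC (Mann-Whitney, ties half-credit)
#' @param preds a `prediction_set`.
#' @return scalar in `[0, 1]`.
#' @export
auc <- function(preds) {
  p <- preds$probability; y <- preds$label
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(p)                               # midranks handle ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hotelling-Williams test for two dependent correlations
#'
#' Compares correlations `r1 = cor(x, z)` and `r2 = cor(y, z)` that share
#' the variable `z`, given the inter-predictor correlation
#' `r12 = cor(x, y)`, with a t statistic on `n - 3` degrees of freedom.
#' Used here to compare two models' prediction-label MCCs on the same
#' cohort.
#'
#' @param r1,r2 the two correlations sharing a variable.
#' @param r12 correlation between the two non-shared variables.
#' @param n sample size (> 3).
#' @return list `t`, `df`, `p_value`.
#' @export
williams_test <- function(r1, r2, r12, n) {
  if (n <= 3) stop("n must exceed 3")
  if (any(abs(c(r1, r2, r12)) >= 1)) stop("degenerate correlation |r| >= 1")
  detR <- 1 - r1^2 - r2^2 - r12^2 + 2 * r1 * r2 * r12
  rbar <- (r1 + r2) / 2
  denom <- 2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r12)^3
  t <- (r1 - r2) * sqrt((n - 1) * (1 + r12) / denom)
  list(t = t, df = n - 3, p_value = 2 * pt(-abs(t), df = n - 3))
}

#' Cohen's kappa for two binary raters
#'
#' `(p_o - p_e) / (1 - p_e)` with chance agreement from the marginal
#' products.  Two identical constant raters give 1 by convention; other
#' degenerate marginals (`p_e = 1`) are flagged `NA`.
#'
#' @param a,b equal-length 0/1 vectors.
#' @return scalar kappa.
#' @export
cohens_kappa <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a == 1) * mean(b == 1) + mean(a == 0) * mean(b == 0)
  if (pe >= 1 - 1e-12) {
    if (po >= 1 - 1e-12) return(1)
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Stratified percentile bootstrap confidence interval
#'
#' Resamples subjects with replacement within each class, recomputes the
#' metric on each resample (the operating threshold is re-fixed per
#' resample when the metric needs one) and returns the percentile
#' interval.
#'
#' @param preds a `prediction_set`.
#' @param metric function of a `prediction_set` returning a scalar; e.g.
#'   `function(p) mcc(equal_ss_threshold(p)$cm)` or [auc()].
#' @param n_boot number of resamples.
#' @param conf confidence level.
#' @param seed optional local seed.
#' @return numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(preds, metric, n_boot = 2000, conf = 0.95,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(preds) < 20) stop("bootstrap CI needs at least 20 subjects")
  ipos <- which(preds$label == 1); ineg <- which(preds$label == 0)
  stat <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- c(sample(ipos, replace = TRUE), sample(ineg, replace = TRUE))
    stat[b] <- suppressWarnings(metric(preds[idx, , drop = FALSE]))
  }
  quantile(stat, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE,
           na.rm = TRUE)
}

#' Full metric report for a prediction set
#'
#' MCC at the equal sensitivity-specificity threshold with bootstrap CI,
#' AUC with bootstrap CI, and the operating point's
#' sensitivity/specificity/PPV/NPV in percent.
#'
#' @param preds a `prediction_set`.
#' @param n_boot bootstrap resamples for the CIs.
#' @param seed optional local seed for the bootstrap.
#' @return list of class `metric_report`.
#' @export
metric_report <- function(preds, n_boot = 2000, seed = NULL) {
  es <- equal_ss_threshold(preds)
  r <- cm_rates(es$cm)
  mcc_fun <- function(p) mcc(equal_ss_threshold(p)$cm)
  ci_m <- bootstrap_ci(preds, mcc_fun, n_boot = n_boot, seed = seed)
  ci_a <- bootstrap_ci(preds, auc, n_boot = n_boot, seed = seed)
  structure(list(mcc = unname(r["mcc"]), mcc_ci = ci_m,
                 auc = auc(preds), auc_ci = ci_a,
                 sensitivity = unname(r["sensitivity"]),
                 specificity = unname(r["specificity"]),
                 ppv = unname(r["ppv"]), npv = unname(r["npv"]),
                 threshold = es$threshold),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("MCC %.3f (%.3f to %.3f)  AUC %.3f (%.3f to %.3f)\n",
              x$mcc, x$mcc_ci[1], x$mcc_ci[2],
              x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("sens %.1f  spec %.1f  PPV %.1f  NPV %.1f  (thr %.3f)\n",
              x$sensitivity, x$specificity, x$ppv, x$npv, x$threshold))
  invisible(x)
}

#' Published reference operating points
#'
#' The printed sensitivity/specificity (percent) and class sizes of the
#' reference cohort study's model rows: the full cohort (53 seizure / 109
#' non-seizure), the no-ASM subgroup (39/92) and the 2-channel aEEG
#' cohort (52/107), together with the printed MCC/PPV/NPV for comparison.
#' [reconstruct_performance()] rebuilds each row's confusion matrix with
#' [confusion_from_rates()] and recomputes MCC, PPV and NPV.
#'
#' @return data frame with one row per published model row.
#' @export
reference_performance <- function() {
  data.frame(
    cohort = rep(c("full", "no_asm", "aeeg"), c(5, 5, 2)),
    model = c("clinical", "qualitative", "quantitative",
              "clinical+qualitative", "clinical+quantitative",
              "clinical", "qualitative", "quantitative",
              "clinical+qualitative", "clinical+quantitative",
              "quantitative_aeeg", "clinical+quantitative_aeeg"),
    n_pos = rep(c(53, 39, 52), c(5, 5, 2)),
    n_neg = rep(c(109, 92, 107), c(5, 5, 2)),
    sens = c(60.4, 67.9, 69.8, 79.2, 75.5,
             64.1, 64.1, 71.8, 76.9, 66.7,
             71.2, 61.5),
    spec = c(77.1, 79.8, 78.9, 70.6, 78.0,
             82.6, 85.9, 78.3, 78.3, 90.2,
             69.2, 77.6),
    mcc_printed = c(0.368, 0.467, 0.473, 0.470, 0.513,
                    0.461, 0.504, 0.475, 0.519, 0.588,
                    0.381, 0.384),
    ppv_printed = c(56.1, 62.1, 61.7, 56.8, 62.5,
                    61.0, 65.8, 58.3, 60.0, 74.3,
                    52.9, 57.1),
    npv_printed = c(80.0, 83.7, 84.3, 87.5, 86.7,
                    84.4, 84.9, 86.7, 88.9, 86.5,
                    83.1, 80.6),
    stringsAsFactors = FALSE)
}

#' @rdname reference_performance
#' @export
reconstruct_performance <- function() {
  ref <- reference_performance()
  rec <- t(apply(ref, 1, function(row) {
    cm <- confusion_from_rates(as.numeric(row["sens"]),
                               as.numeric(row["spec"]),
                               as.numeric(row["n_pos"]),
                               as.numeric(row["n_neg"]))
    r <- cm_rates(cm)
    c(mcc = unname(r["mcc"]), ppv = unname(r["ppv"]),
      npv = unname(r["npv"]))
  }))
  cbind(ref, mcc_recomputed = rec[, "mcc"], ppv_recomputed = rec[, "ppv"],
        npv_recomputed = rec[, "npv"])
}
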