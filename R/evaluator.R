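# Evaluation: threshold-free ranking metrics (AUROC, AUPRC), F1-maximizing
# threshold calibration on validation data, thresholded metrics, regression
# MSE, and per-posture subgroup reports.

#' Area under the ROC curve
#'
#' Equals the probability that a random positive outranks a random negative,
#' with ties counting one half (the trapezoidal ROC area).
#'
#' @param scores numeric ranking scores.
#' @param labels binary labels (0/1, both classes present).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("AUROC undefined: only one class present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Step-wise (average-precision style) integration over thresholds at the
#' unique scores, descending; no trapezoidal interpolation.
#'
#' @param scores numeric ranking scores.
#' @param labels binary labels (at least one positive).
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1)
  if (np == 0) stop("AUPRC undefined: no positives")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l); fp <- cumsum(1 - l)
  keep <- c(s[-length(s)] != s[-1], TRUE)  # last index of each unique score
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' Calibrate the decision threshold by maximizing F1
#'
#' Sweeps candidate thresholds at the midpoints between consecutive unique
#' sorted scores, plus -Inf/+Inf sentinels (predict-all-positive /
#' predict-none), and returns the threshold maximizing F1 on the validation
#' data; ties break toward the smaller threshold (higher recall).
#'
#' @param scores validation scores.
#' @param labels validation binary labels (both classes present).
#' @return the calibrated threshold tau.
#' @export
calibrate_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("threshold calibration requires both classes")
  }
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, Inf)
  f1s <- vapply(cand, function(tau) {
    thresholded_metrics(scores, labels, tau)[["f1"]]
  }, numeric(1))
  cand[which.max(f1s)]  # which.max takes the first (smallest tau) on ties
}

#' Thresholded classification metrics
#'
#' Predictions are `score >= tau`. Zero-denominator conventions: precision
#' is 0 with no predicted positives, recall 0 with no positives, F1 is 0
#' when precision + recall = 0.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param tau decision threshold (finite or +-Inf sentinel).
#' @return named vector: `accuracy`, `precision`, `recall`, `f1`.
#' @export
thresholded_metrics <- function(scores, labels, tau) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= tau)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(accuracy = (tp + tn) / length(labels), precision = precision,
    recall = recall, f1 = f1)
}

#' Mean squared error against the continuous label
#'
#' @param predictions numeric predictions.
#' @param labels continuous labels of the same length.
#' @return mean of squared residuals.
#' @export
mse <- function(predictions, labels) {
  if (length(predictions) == 0) stop("MSE undefined on empty input")
  if (length(predictions) != length(labels)) stop("length mismatch")
  mean((predictions - labels)^2)
}

eval_report_row <- function(scores, c_labels, y_labels, tau, subgroup) {
  both <- length(unique(as.integer(c_labels))) == 2
  tm <- thresholded_metrics(scores, c_labels, tau)
  data.frame(
    subgroup = subgroup,
    n_samples = length(scores),
    auroc = if (both) auroc(scores, c_labels) else NA_real_,
    auprc = if (sum(c_labels) > 0) auprc(scores, c_labels) else NA_real_,
    accuracy = tm[["accuracy"]], precision = tm[["precision"]],
    recall = tm[["recall"]], f1 = tm[["f1"]],
    mse = mse(scores, y_labels),
    threshold = tau,
    stringsAsFactors = FALSE
  )
}

#' Overall and per-posture evaluation report
#'
#' Evaluates scores against the binary fall label (ranking and thresholded
#' metrics) and the continuous label (MSE), overall and within each posture
#' mode, reusing the SAME globally calibrated threshold for every subgroup.
#' A subgroup with a single class gets `NA` for its undefined ranking
#' metrics; the others are still reported.
#'
#' @param scores predicted risk scores on the evaluation set.
#' @param c_labels binary fall labels.
#' @param y_labels continuous risk labels.
#' @param modes posture-mode tags (`NA` allowed), or `NULL` for overall only.
#' @param tau decision threshold calibrated on validation data.
#' @return data.frame with one row per subgroup plus the overall row.
#' @export
per_posture_report <- function(scores, c_labels, y_labels, modes = NULL,
                               tau) {
  out <- eval_report_row(scores, c_labels, y_labels, tau, "overall")
  if (!is.null(modes)) {
    for (m in posture_modes()) {
      idx <- which(!is.na(modes) & modes == m)
      if (length(idx) > 0) {
        out <- rbind(out, eval_report_row(scores[idx], c_labels[idx],
                                          y_labels[idx], tau, m))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Aggregate per-seed reports into mean +- sd rows
#'
#' @param reports list of per-seed report data.frames (same layout).
#' @return data.frame with `mean` and `sd` columns per metric and subgroup.
#' @export
aggregate_reports <- function(reports) {
  metrics <- c("auroc", "auprc", "accuracy", "precision", "recall", "f1",
               "mse")
  subgroups <- reports[[1]]$subgroup
  rows <- lapply(seq_along(subgroups), function(i) {
    vals <- sapply(reports, function(r) unlist(r[i, metrics]))
    df <- data.frame(subgroup = subgroups[i],
                     n_samples = reports[[1]]$n_samples[i],
                     n_seeds = length(reports))
    for (m in metrics) {
      df[[paste0(m, "_mean")]] <- mean(vals[m, ])
      df[[paste0(m, "_sd")]] <- sd(vals[m, ])
    }
    df
  })
  do.call(rbind, rows)
}
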