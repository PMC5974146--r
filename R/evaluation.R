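#' Confusion counts from labels and calls
#'
#' @param labels true labels (`positive`/`negative` or logical).
#' @param calls predicted calls (same encodings).
#' @return object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(labels, calls) {
  y <- as_binary_label(labels) == "positive"
  p <- as_binary_label(calls) == "positive"
  if (length(y) != length(p)) stop("labels and calls lengths differ")
  structure(list(tp = sum(y & p), fp = sum(!y & p),
                 tn = sum(!y & !p), fn = sum(y & !p)),
            class = "confusion_counts")
}

#' Confusion counts from printed sensitivity/specificity rates
#'
#' Reconstructs integer counts from rounded published rates:
#' `TP = round(sens * n_pos)` and `TN = round(spec * n_neg)` under
#' round-half-up, with FN/FP as complements. Useful for recomputing
#' derived metrics (accuracy, precision, F1, MCC) from reported
#' sensitivity/specificity pairs.
#'
#' @param sensitivity,specificity rates in \[0, 1\].
#' @param n_pos,n_neg class sizes.
#' @return a `confusion_counts` object.
#' @export
counts_from_rates <- function(sensitivity, specificity, n_pos, n_neg) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  tp <- round_half_up(sensitivity * n_pos)
  tn <- round_half_up(specificity * n_neg)
  structure(list(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Confusion counts: TP", x$tp, " FP", x$fp,
      " TN", x$tn, " FN", x$fn, "\n")
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Computes sensitivity, specificity, accuracy, precision, F1 and the
#' Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A metric with a zero denominator is reported as `NA` and listed in
#' the `undefined` field; a zero MCC denominator gives MCC 0 by
#' convention (also flagged).
#'
#' @param counts a `confusion_counts` object.
#' @return object of class `metrics_report`.
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  undef <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); return(NA_real_) }
    num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  acc <- safe(tp + tn, tp + fp + tn + fn, "accuracy")
  prec <- safe(tp, tp + fp, "precision")
  f1 <- safe(2 * tp, 2 * tp + fp + fn, "F1")
  mden <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mden == 0) { undef <- c(undef, "MCC"); 0 }
         else (tp * tn - fp * fn) / sqrt(mden)
  structure(list(sensitivity = sens, specificity = spec, accuracy = acc,
                 precision = prec, F1 = f1, MCC = mcc,
                 undefined = undef, counts = counts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  v <- unlist(x[c("sensitivity", "specificity", "accuracy",
                  "precision", "F1", "MCC")])
  print(round(v, digits))
  if (length(x$undefined) > 0)
    cat("  undefined (zero denominator):",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve points
#'
#' One (FPR, TPR) point per distinct score threshold (descending),
#' tied scores grouped at a single threshold, plus the (0, 0)
#' endpoint.
#'
#' @param labels true labels.
#' @param scores classifier scores (larger = more positive).
#' @return data.frame with columns `threshold`, `fpr`, `tpr`, ordered
#'   by increasing FPR.
#' @export
roc_points <- function(labels, scores) {
  y <- as_binary_label(labels) == "positive"
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("need both classes to build a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  grp_end <- c(which(diff(ss) != 0), length(ss))  # last index per threshold
  tp <- cumsum(ys)[grp_end]
  fp <- cumsum(!ys)[grp_end]
  data.frame(threshold = c(Inf, ss[grp_end]),
             fpr = c(0, fp / n0),
             tpr = c(0, tp / n1))
}

#' Precision-recall curve points
#'
#' One (recall, precision) point per distinct score threshold
#' (descending), tied scores grouped.
#'
#' @inheritParams roc_points
#' @return data.frame with columns `threshold`, `recall`, `precision`.
#' @export
pr_points <- function(labels, scores) {
  y <- as_binary_label(labels) == "positive"
  if (sum(y) == 0L || sum(!y) == 0L)
    stop("need both classes to build a precision-recall curve")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  grp_end <- c(which(diff(ss) != 0), length(ss))
  tp <- cumsum(ys)[grp_end]
  called <- grp_end
  data.frame(threshold = ss[grp_end],
             recall = tp / sum(y),
             precision = tp / called)
}

#' Trapezoidal area under a curve
#'
#' Integrates (x, y) points with the trapezoidal rule. On ROC points
#' from tie-free scores this equals the Mann-Whitney concordance
#' probability.
#'
#' @param points data.frame whose first two numeric columns are x and
#'   y (e.g. `fpr`/`tpr` from [roc_points()]), ordered by x.
#' @return the trapezoidal integral.
#' @export
auc_trapezoid <- function(points) {
  x <- if (!is.null(points$fpr)) points$fpr else points[[1]]
  y <- if (!is.null(points$tpr)) points$tpr else points[[2]]
  if (is.unsorted(x)) stop("points must be ordered by x")
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' ROC AUC of a score vector
#'
#' Convenience composition of [roc_points()] and [auc_trapezoid()].
#'
#' @inheritParams roc_points
#' @return the area under the ROC curve.
#' @export
roc_auc <- function(labels, scores) {
  auc_trapezoid(roc_points(labels, scores))
}

#' One-sided bootstrap comparison of two AUCs
#'
#' Paired stratified bootstrap: example indices are resampled with
#' replacement within each class (so every replicate contains both
#' classes), both score vectors are re-evaluated on the same
#' replicate, and the returned p-value is the fraction of replicates
#' in which `AUC(a) <= AUC(b)` (exact AUC ties counted with weight
#' 1/2, so comparing a score vector against itself gives 0.5) --
#' small values support a genuinely higher AUC for `scores_a`.
#'
#' @param scores_a,scores_b two score vectors over the same examples.
#' @param labels shared true labels.
#' @param n_boot bootstrap replicates (warns below 100).
#' @param seed integer seed.
#' @return one-sided p-value in \[0, 1\].
#' @export
bootstrap_auc_compare <- function(scores_a, scores_b, labels,
                                  n_boot = 2000L, seed = 1L) {
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  if (n_boot < 100L) warning("n_boot < 100: p-value will be unstable")
  y <- as_binary_label(labels) == "positive"
  ipos <- which(y); ineg <- which(!y)
  with_seed(seed, {
    wins <- 0
    for (b in seq_len(n_boot)) {
      ix <- c(sample(ipos, replace = TRUE), sample(ineg, replace = TRUE))
      aa <- auc_rank(y[ix], scores_a[ix])
      ab <- auc_rank(y[ix], scores_b[ix])
      wins <- wins + (aa < ab) + 0.5 * (aa == ab)
    }
    wins / n_boot
  })
}

#' N-terminal window-length sweep
#'
#' Re-runs stratified SVM cross-validation with the N-terminal
#' feature blocks (amino-acid frequency and N-terminal PSSM by
#' default) built at each window length, reusing one fold assignment
#' across windows so the comparison is paired.
#'
#' @param records labeled record table.
#' @param profiles named list of `profile_matrix` objects (or `NULL`
#'   for the substitution fallback).
#' @param windows window lengths to evaluate (default 5:50).
#' @param blocks feature blocks to rebuild per window.
#' @param cost SVM cost.
#' @param gamma SVM gamma (default 0.1, the package's default RBF
#'   width, so windows are compared under the standard
#'   hyperparameters); `NULL` uses 1/(feature count) per window.
#' @param k folds.
#' @param seed integer seed.
#' @return data.frame with columns `window` and `mean_auc`.
#' @export
window_sweep <- function(records, profiles = NULL, windows = 5:50,
                         blocks = c("AAFreq.NT", "PSSM.NT"),
                         cost = 10, gamma = 0.1, k = 10L, seed = 1L) {
  fold <- stratified_kfold(records$label, k = k, seed = seed)
  mean_auc <- numeric(length(windows))
  for (wi in seq_along(windows)) {
    cfg <- feature_config(nterm_window = windows[wi], blocks = blocks)
    x <- build_feature_matrix(records, profiles = profiles, config = cfg)
    g <- if (is.null(gamma)) 1 / ncol(x) else gamma
    aucs <- numeric(k)
    for (i in seq_len(k)) {
      tr <- fold != i
      fit <- fit_svm(x[tr, , drop = FALSE], records$label[tr],
                     cost = cost, gamma = g)
      aucs[i] <- auc_rank(records$label[fold == i],
                          svm_decision(fit, x[fold == i, , drop = FALSE]))
    }
    mean_auc[wi] <- mean(aucs)
  }
  data.frame(window = windows, mean_auc = mean_auc)
}
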