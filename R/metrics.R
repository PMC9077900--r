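# Imbalance-aware evaluation: confusion matrix, threshold metrics
# (accuracy, TPR, FPR, balanced accuracy, MCC, precision, F1), ROC / PR
# curves with AUC and AUCPR, and the cross-method ranking.
#
# On heavily imbalanced panels plain accuracy is dominated by the true
# negatives; balanced accuracy, MCC, F1 and AUCPR are the metrics that keep
# the minority (active) class visible, and they are the selection and
# reporting metrics throughout the package.

#' Confusion matrix counts
#'
#' @param y_true,y_pred equal-length binary (0/1) vectors.
#' @return object of class `confusion`: list with `tp`, `fp`, `tn`, `fn`.
#' @export
#' @examples
#' confusion_matrix(c(1, 1, 0, 0), c(1, 0, 1, 0))
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length", call. = FALSE)
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) {
    stop("entries must be 0/1", call. = FALSE)
  }
  structure(list(
    tp = sum(y_true == 1L & y_pred == 1L),
    fp = sum(y_true == 0L & y_pred == 1L),
    tn = sum(y_true == 0L & y_pred == 0L),
    fn = sum(y_true == 1L & y_pred == 0L)
  ), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(actual = c("active", "inactive"),
                              predicted = c("active", "inactive")))
  print(m)
  invisible(x)
}

#' Threshold classification metrics from a confusion matrix
#'
#' Computes accuracy, recall (TPR), FPR, balanced accuracy
#' `(TPR + TNR) / 2`, the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, precision (PPV)
#' and `F1 = TP / (TP + (FP + FN)/2)`.
#'
#' Degenerate denominators never crash: MCC is 0 when any factor of its
#' denominator is 0, precision is 0 when nothing is predicted positive, and
#' F1 is 0 when TP is 0.
#'
#' @param cm a `confusion` object (or list with `tp`, `fp`, `tn`, `fn`).
#' @return named list of metrics.
#' @export
classification_metrics <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  p <- tp + fn
  n <- tn + fp
  tpr <- if (p > 0) tp / p else 0
  tnr <- if (n > 0) tn / n else 0
  fpr <- if (n > 0) fp / n else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  } else 0
  f1 <- if (tp + (fp + fn) / 2 > 0) tp / (tp + (fp + fn) / 2) else 0
  list(
    accuracy = (tp + tn) / (p + n),
    tpr = tpr,
    fpr = fpr,
    balanced_accuracy = (tpr + tnr) / 2,
    mcc = mcc,
    precision = precision,
    f1 = f1
  )
}

#' Balanced accuracy of probabilistic predictions
#'
#' Thresholds the scores (default 0.5, the fixed classification threshold of
#' the sigmoid output) and returns `(TPR + TNR) / 2`. When one class is
#' absent from `y_true` — possible for small minibatches during training —
#' the absent class's recall term is skipped and the present class's recall
#' is returned; full-validation-set monitoring always sees both classes on
#' stratified splits.
#'
#' @param y_true binary labels.
#' @param y_prob scores in `[0, 1]`.
#' @param threshold classification cutoff (default 0.5).
#' @return balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(y_true, y_prob, threshold = 0.5) {
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_prob >= threshold)
  p <- sum(y_true == 1L)
  n <- sum(y_true == 0L)
  terms <- c(
    if (p > 0) sum(y_true == 1L & y_pred == 1L) / p,
    if (n > 0) sum(y_true == 0L & y_pred == 0L) / n
  )
  mean(terms)
}

#' ROC and precision-recall curves with AUC / AUCPR
#'
#' Sweeps the decision threshold over the unique scores. The ROC curve runs
#' from (0, 0) to (1, 1) and its area is computed by the trapezoid rule. The
#' PR area is computed as average precision (the step-wise integral
#' `sum (R_k - R_{k-1}) * P_k`), avoiding the optimistic linear interpolation
#' that the trapezoid rule produces in PR space; for uninformative scores it
#' converges to the prevalence.
#'
#' @param y_true binary labels (both classes must be present for AUC).
#' @param y_prob scores in `[0, 1]`.
#' @return list with `roc` (data.frame `threshold`, `fpr`, `tpr`), `pr`
#'   (data.frame `threshold`, `recall`, `precision`), `auc`, `aucpr`.
#' @export
roc_pr_curves <- function(y_true, y_prob) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(y_prob))
  p <- sum(y_true == 1L)
  n <- sum(y_true == 0L)
  if (p == 0 || n == 0) {
    if (p == 0) {
      stop("AUC undefined: no positive samples in y_true", call. = FALSE)
    }
    stop("AUC undefined: no negative samples in y_true", call. = FALSE)
  }
  ord <- order(y_prob, decreasing = TRUE)
  y <- y_true[ord]
  s <- y_prob[ord]
  # cumulative counts at each distinct threshold (score ties grouped)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  cum_tp <- cumsum(y)[last_of_tie]
  cum_fp <- cumsum(1 - y)[last_of_tie]
  thr <- s[last_of_tie]
  roc <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, cum_fp / n),
    tpr = c(0, cum_tp / p)
  )
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  recall <- cum_tp / p
  precision <- ifelse(cum_tp + cum_fp > 0, cum_tp / (cum_tp + cum_fp), 0)
  pr <- data.frame(threshold = thr, recall = recall, precision = precision)
  aucpr <- sum(diff(c(0, recall)) * precision)
  list(roc = roc, pr = pr, auc = auc, aucpr = aucpr)
}

#' Full metrics report for probabilistic predictions
#'
#' Thresholds at `threshold` for the confusion-matrix statistics and adds
#' AUC / AUCPR from the score sweep.
#'
#' @inheritParams roc_pr_curves
#' @param threshold classification cutoff (default 0.5).
#' @return list with `confusion`, all threshold metrics, `auc`, `aucpr`, and
#'   `curves`.
#' @export
metrics_report <- function(y_true, y_prob, threshold = 0.5) {
  cm <- confusion_matrix(y_true, as.integer(y_prob >= threshold))
  out <- classification_metrics(cm)
  curves <- roc_pr_curves(y_true, y_prob)
  c(list(confusion = cm), out,
    list(auc = curves$auc, aucpr = curves$aucpr, curves = curves))
}

#' Cross-method ranking
#'
#' For each metric, counts on how many targets each method achieves the best
#' value. Exact ties credit every tied method (order-independent), so per
#' metric the counts sum to at least the number of targets.
#'
#' @param reports data.frame with columns `target_id`, `method`, and one
#'   column per metric (default `balanced_accuracy`, `mcc`, `f1`).
#' @param metrics metric columns to rank on.
#' @return data.frame with columns `metric`, `method`, `n_best`.
#' @export
rank_methods <- function(reports,
                         metrics = c("balanced_accuracy", "mcc", "f1")) {
  stopifnot(all(c("target_id", "method", metrics) %in% names(reports)))
  methods <- sort(unique(reports$method))
  complete <- table(reports$target_id)
  usable <- names(complete)[complete == length(methods)]
  dropped <- setdiff(unique(reports$target_id), usable)
  if (length(dropped)) {
    warning("target(s) excluded from ranking (missing method cells): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  out <- expand.grid(metric = metrics, method = methods,
                     stringsAsFactors = FALSE)
  out$n_best <- 0L
  for (tg in usable) {
    sub <- reports[reports$target_id == tg, , drop = FALSE]
    for (m in metrics) {
      best <- max(sub[[m]])
      winners <- sub$method[sub[[m]] == best]
      sel <- out$metric == m & out$method %in% winners
      out$n_best[sel] <- out$n_best[sel] + 1L
    }
  }
  attr(out, "n_targets") <- length(usable)
  out
}

#' Plot ROC and PR curves side by side
#'
#' @param curves result of [roc_pr_curves()].
#' @param main title prefix.
#' @param file optional PNG path; when given the plot is written there.
#' @return `NULL`, invisibly.
#' @export
plot_roc_pr <- function(curves, main = "", file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 450)
    on.exit(grDevices::dev.off())
  }
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old), add = TRUE)
  graphics::plot(curves$roc$fpr, curves$roc$tpr, type = "l", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("%s ROC (AUC = %.3f)", main, curves$auc))
  graphics::abline(0, 1, lty = 3)
  graphics::plot(curves$pr$recall, curves$pr$precision, type = "s", lwd = 2,
                 ylim = c(0, 1), xlab = "Recall", ylab = "Precision",
                 main = sprintf("%s PR (AUCPR = %.3f)", main, curves$aucpr))
  invisible(NULL)
}
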