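# Model evaluation against frozen held-out test sets, with a leak guard:
# a model bundle records the checksum of the split it was trained under, and
# evaluation refuses to score it against a different partition.

#' Evaluate a trained model on a frozen test set
#'
#' Produces the full metrics report (threshold metrics at 0.5 plus AUC /
#' AUCPR and curve data) for one trained model on held-out features. When
#' both the model (bundle) and the split carry checksums they must agree —
#' evaluating a model against a partition other than the one it was trained
#' under is a protocol violation, not a warning.
#'
#' @param model an `offpanel_nn` or `offpanel_rf` (anything with a `predict`
#'   method returning probabilities).
#' @param x_test,y_test held-out features and labels.
#' @param split_checksum checksum of the frozen split providing `x_test`.
#' @param trained_checksum checksum recorded at training time (e.g.
#'   `bundle$split_checksum`).
#' @return metrics report (see [metrics_report()]).
#' @export
evaluate_model <- function(model, x_test, y_test, split_checksum = NULL,
                           trained_checksum = NULL) {
  if (!is.null(split_checksum) && !is.null(trained_checksum) &&
      !identical(split_checksum, trained_checksum)) {
    stop("split checksum mismatch: model was trained under ",
         trained_checksum, " but evaluated against ", split_checksum,
         call. = FALSE)
  }
  p <- predict(model, x_test)
  metrics_report(y_test, p)
}

metrics_row <- function(report, target_id, method, criterion = NA_character_) {
  data.frame(
    target_id = target_id, method = method, criterion = criterion,
    accuracy = report$accuracy, tpr = report$tpr, fpr = report$fpr,
    balanced_accuracy = report$balanced_accuracy, mcc = report$mcc,
    precision = report$precision, f1 = report$f1,
    auc = report$auc, aucpr = report$aucpr,
    stringsAsFactors = FALSE
  )
}
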