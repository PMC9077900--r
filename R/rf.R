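# Random Forest baseline, trained under the comparison protocol: 100 trees,
# mtry tuned by stratified 10-fold cross-validation on the training pool to
# maximize balanced accuracy, same frozen splits and feature matrices as the
# network. Class weighting is off by default — the baseline is reported
# as-is, minority-class weakness included; a weighted mode exists for users
# who want it.

#' Tune the mtry parameter by stratified cross-validation
#'
#' Evaluates each candidate `mtry` (features sampled per split) with a
#' stratified k-fold cross-validation on the training pool, scoring mean
#' balanced accuracy of out-of-fold probability predictions thresholded at
#' 0.5, and returns the best candidate with the full CV table. Deterministic
#' given `seed`. When the pool has fewer positives than folds, the fold count
#' is reduced with a warning.
#'
#' @param x feature matrix (training pool).
#' @param y binary labels.
#' @param candidates integer vector of mtry candidates (default
#'   `{32, 64, 128, 256}`: the square root of the 1024-bit width plus
#'   neighbors probing sensitivity). Duplicates are removed with a warning.
#' @param folds number of CV folds (default 10).
#' @param ntree trees per forest (default 100).
#' @param seed integer seed.
#' @param classwt optional class weights passed to
#'   [randomForest::randomForest()].
#' @return list with `best_mtry` and `cv` (data.frame `mtry`,
#'   `balanced_accuracy`).
#' @export
tune_mtry <- function(x, y, candidates = c(32L, 64L, 128L, 256L),
                      folds = 10L, ntree = 100L, seed, classwt = NULL) {
  y <- as.integer(y)
  if (anyDuplicated(candidates)) {
    warning("duplicate mtry candidates removed", call. = FALSE)
    candidates <- unique(candidates)
  }
  candidates <- candidates[candidates <= ncol(x)]
  if (!length(candidates)) stop("no usable mtry candidates", call. = FALSE)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (min(n_pos, n_neg) < folds) {
    folds <- max(2L, min(n_pos, n_neg))
    warning("too few minority samples for requested folds; reduced to ",
            folds, call. = FALSE)
  }
  fold_id <- integer(length(y))
  with_seed(seed, {
    for (k in c(0L, 1L)) {
      members <- sample(which(y == k))
      fold_id[members] <- rep_len(seq_len(folds), length(members))
    }
  })
  fold_seeds <- derive_seeds(seed, folds * length(candidates))
  cv <- data.frame(mtry = candidates, balanced_accuracy = NA_real_)
  si <- 0L
  for (ci in seq_along(candidates)) {
    bas <- numeric(folds)
    for (f in seq_len(folds)) {
      si <- si + 1L
      hold <- fold_id == f
      fit <- rf_fit(x[!hold, , drop = FALSE], y[!hold],
                    mtry = candidates[ci], ntree = ntree,
                    seed = fold_seeds[si], classwt = classwt)
      prob <- predict(fit, x[hold, , drop = FALSE])
      bas[f] <- balanced_accuracy(y[hold], prob)
    }
    cv$balanced_accuracy[ci] <- mean(bas)
  }
  list(best_mtry = cv$mtry[which.max(cv$balanced_accuracy)], cv = cv)
}

#' Train the Random Forest baseline
#'
#' Thin wrapper around [randomForest::randomForest()]: 100 bootstrap trees,
#' probability output from the tree vote fractions, classification threshold
#' 0.5 to match the network convention, reproducible given `seed`.
#'
#' @inheritParams tune_mtry
#' @param mtry features sampled per split (tune with [tune_mtry()]).
#' @return object of class `offpanel_rf`.
#' @export
rf_fit <- function(x, y, mtry, ntree = 100L, seed, classwt = NULL) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("single-class labels: cannot train a classifier", call. = FALSE)
  }
  fit <- with_seed(seed, randomForest::randomForest(
    x = x, y = factor(y, levels = c(0, 1)),
    ntree = ntree, mtry = mtry, classwt = classwt
  ))
  structure(list(forest = fit, mtry = mtry, ntree = ntree, seed = seed,
                 input_width = ncol(x)),
            class = "offpanel_rf")
}

#' @export
predict.offpanel_rf <- function(object, newdata, type = c("prob", "class"),
                                ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$input_width) {
    stop("feature width ", ncol(newdata), " does not match the model's ",
         object$input_width, call. = FALSE)
  }
  p <- unname(predict(object$forest, newdata, type = "prob")[, "1"])
  if (type == "class") as.integer(p >= 0.5) else p
}

#' @export
print.offpanel_rf <- function(x, ...) {
  cat("Random Forest baseline: ", x$ntree, " trees, mtry ", x$mtry,
      ", ", x$input_width, " features\n", sep = "")
  invisible(x)
}
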