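# Panel-level model fitting: the one front end that takes a curated panel
# and returns per-target trained classifiers with their evaluation, in the
# classic fit-object idiom (print / summary / predict methods).

#' Fit off-target activity models for every target of a panel
#'
#' Runs the full modelling protocol per target: ECFP4 featurization,
#' stratified 60/20/20 train/validation/test partitioning (or frozen
#' `splits`), a grid-sampled feed-forward network search retaining three
#' models per target, a Random Forest baseline with cross-validated `mtry`,
#' evaluation of every retained model on the held-out test set, and a
#' bounding-box applicability domain fitted on each target's training-pool
#' descriptors.
#'
#' The network trains on the 60 % training part monitoring the 20 %
#' validation part; the Random Forest trains on the full 80 % pool (its
#' tuning uses internal cross-validation). Both are evaluated on the same
#' frozen 20 % test set.
#'
#' Targets that cannot be modelled (single-class after curation, too few
#' samples) are skipped with a warning and reported in the result.
#'
#' @param panel a `panel_table` from [curate_panel()].
#' @param seed master seed; every stochastic stage derives from it.
#' @param methods subset of `c("nn", "rf")`.
#' @param splits optional `panel_splits` (default: [make_splits()] with
#'   `seed`).
#' @param reduced_grid use the single-combination reduced network grid
#'   (default `TRUE`; the full 324-point grid at 50 % sampling is the
#'   large-scale protocol).
#' @param grid_fraction fraction of the full grid to sample when
#'   `reduced_grid = FALSE`.
#' @param max_epochs epoch budget per network run.
#' @param mtry_candidates Random Forest `mtry` candidates.
#' @param headline_criterion which retained network feeds the headline
#'   metrics (default `"best_ba"`, the best-validation-balanced-accuracy
#'   model; all three criteria are evaluated and reported).
#' @return object of class `offtarget_panel_fit`.
#' @export
fit_offtarget_panel <- function(panel, seed, methods = c("nn", "rf"),
                                splits = NULL, reduced_grid = TRUE,
                                grid_fraction = 0.5, max_epochs = 250L,
                                mtry_candidates = c(32L, 64L, 128L, 256L),
                                headline_criterion = "best_ba") {
  stopifnot(inherits(panel, "panel_table"))
  methods <- match.arg(methods, several.ok = TRUE)
  splits <- splits %||% make_splits(panel, seed = seed)
  all_smiles <- unique(panel$smiles)
  fp <- ecfp4_fingerprints(all_smiles)
  desc <- compute_descriptors(all_smiles)
  rownames(desc) <- desc$smiles
  target_seeds <- derive_seeds(seed + 13L, length(splits))

  fits <- list()
  metrics_rows <- list()
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    tg <- sp$target_id
    sub <- panel[panel$target_id == tg, , drop = FALSE]
    x <- fp[sub$smiles, , drop = FALSE]
    y <- sub$activity
    idx <- split_indices(sp, sub$smiles)
    pool <- c(idx$train, idx$validation)
    entry <- list(target_id = tg, split = sp)
    entry$domain_box <- fit_domain_box(desc[sub$smiles[pool], , drop = FALSE])

    if ("nn" %in% methods) {
      entry$nn <- tune_nn(
        x[idx$train, , drop = FALSE], y[idx$train],
        x[idx$validation, , drop = FALSE], y[idx$validation],
        seed = target_seeds[i], reduced = reduced_grid,
        fraction = grid_fraction, split_checksum = sp$checksum,
        max_epochs = max_epochs
      )
      for (cr in names(entry$nn$models)) {
        rep <- evaluate_model(entry$nn$models[[cr]],
                              x[idx$test, , drop = FALSE], y[idx$test],
                              split_checksum = sp$checksum,
                              trained_checksum = entry$nn$split_checksum)
        entry$nn_reports[[cr]] <- rep
        metrics_rows[[length(metrics_rows) + 1L]] <-
          metrics_row(rep, tg, "nn", cr)
      }
    }
    if ("rf" %in% methods) {
      tuned <- tune_mtry(x[pool, , drop = FALSE], y[pool],
                         candidates = mtry_candidates,
                         seed = target_seeds[i] + 1L)
      entry$rf <- rf_fit(x[pool, , drop = FALSE], y[pool],
                         mtry = tuned$best_mtry,
                         seed = target_seeds[i] + 2L)
      entry$rf$split_checksum <- sp$checksum
      entry$rf_tuning <- tuned$cv
      rep <- evaluate_model(entry$rf, x[idx$test, , drop = FALSE],
                            y[idx$test], split_checksum = sp$checksum,
                            trained_checksum = entry$rf$split_checksum)
      entry$rf_report <- rep
      metrics_rows[[length(metrics_rows) + 1L]] <-
        metrics_row(rep, tg, "rf", "cv_mtry")
    }
    fits[[tg]] <- entry
  }

  structure(list(
    targets = fits,
    splits = splits,
    summary = suppressWarnings(summarize_targets(panel)),
    metrics = do.call(rbind, metrics_rows),
    seed = seed,
    methods = methods,
    headline_criterion = headline_criterion
  ), class = "offtarget_panel_fit")
}

#' @export
print.offtarget_panel_fit <- function(x, ...) {
  cat("Off-target panel fit: ", length(x$targets), " target model(s), ",
      "methods: ", paste(x$methods, collapse = " + "), "\n", sep = "")
  hl <- headline_metrics(x)
  print(hl[, c("target_id", "method", "balanced_accuracy", "mcc", "f1",
               "aucpr")], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Headline per-target metrics of a panel fit
#'
#' One row per (target, method): the network row uses the headline criterion
#' model (best validation balanced accuracy by default), the Random Forest
#' row its cross-validated fit.
#'
#' @param x an `offtarget_panel_fit`.
#' @return data.frame of test-set metrics.
#' @export
headline_metrics <- function(x) {
  m <- x$metrics
  keep <- (m$method == "nn" & m$criterion == x$headline_criterion) |
    m$method != "nn"
  out <- m[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
summary.offtarget_panel_fit <- function(object, ...) {
  structure(list(
    summary = object$summary,
    metrics = object$metrics,
    headline = headline_metrics(object),
    ranking = if (length(object$methods) > 1) {
      rank_methods(headline_metrics(object))
    }
  ), class = "summary.offtarget_panel_fit")
}

#' @export
print.summary.offtarget_panel_fit <- function(x, ...) {
  cat("Targets:\n")
  print(x$summary, row.names = FALSE, digits = 4)
  cat("\nHeld-out test metrics (headline models):\n")
  print(x$headline[, c("target_id", "method", "balanced_accuracy",
                       "accuracy", "mcc", "f1", "auc", "aucpr")],
        row.names = FALSE, digits = 3)
  if (!is.null(x$ranking)) {
    cat("\nMethod ranking (targets scored best per metric, ties credited):\n")
    print(x$ranking, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.offtarget_panel_fit <- function(x, target = names(x$targets)[1],
                                     method = "nn", ...) {
  entry <- x$targets[[target]]
  if (is.null(entry)) stop("no such target: ", target, call. = FALSE)
  rep <- if (method == "nn") {
    entry$nn_reports[[x$headline_criterion]]
  } else {
    entry$rf_report
  }
  plot_roc_pr(rep$curves, main = paste(target, method))
}

#' @export
predict.offtarget_panel_fit <- function(object, newdata,
                                        criterion = NULL, ...) {
  predict_panel(object, newdata, criterion = criterion, ...)
}
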