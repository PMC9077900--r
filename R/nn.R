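# Per-target feed-forward network trainer.
#
# Architecture: input (fingerprint width) -> dense(h, ReLU) -> dense(h, ReLU)
# -> dense(1, sigmoid), with dropout on the input and after each hidden
# activation, and an L2 kernel penalty on every dense layer. Optimized with
# Adam on binary cross-entropy. Training monitors validation balanced
# accuracy with three callbacks: checkpoint of the best epoch, learning-rate
# reduction on plateau, and early stopping. Everything is driven by R's RNG
# so a run is exactly reproducible from (seed, hyperparameters, splits).

#' Hyperparameter grid for the network search
#'
#' The full grid crosses hidden units \{256, 512, 1024, 2048\}, input dropout
#' \{0, 0.1, 0.2\}, hidden dropout \{0.2, 0.3, 0.4\}, learning rate
#' \{0.01, 0.001, 0.0001\} and batch size \{64, 128, 256\} — 324 combinations
#' in canonical (expand.grid) order. The reduced grid is a single desk-scale
#' combination using the same code path, intended for demonstration runs and
#' tests.
#'
#' @param reduced return the single-combination reduced grid.
#' @return data.frame with columns `hidden_units`, `dropout_input`,
#'   `dropout_hidden`, `learning_rate`, `batch_size`.
#' @export
nn_hyper_grid <- function(reduced = FALSE) {
  if (reduced) {
    return(data.frame(hidden_units = 256L, dropout_input = 0.1,
                      dropout_hidden = 0.2, learning_rate = 0.001,
                      batch_size = 64L))
  }
  expand.grid(
    hidden_units = c(256L, 512L, 1024L, 2048L),
    dropout_input = c(0, 0.1, 0.2),
    dropout_hidden = c(0.2, 0.3, 0.4),
    learning_rate = c(0.01, 0.001, 0.0001),
    batch_size = c(64L, 128L, 256L),
    KEEP.OUT.ATTRS = FALSE
  )
}

nn_grid_values <- list(
  hidden_units = c(256L, 512L, 1024L, 2048L),
  dropout_input = c(0, 0.1, 0.2),
  dropout_hidden = c(0.2, 0.3, 0.4),
  learning_rate = c(0.01, 0.001, 0.0001),
  batch_size = c(64L, 128L, 256L)
)

validate_hyper <- function(hyper, strict = TRUE) {
  need <- names(nn_grid_values)
  miss <- setdiff(need, names(hyper))
  if (length(miss)) {
    stop("hyperparameter field(s) missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (strict) {
    for (f in need) {
      if (!hyper[[f]] %in% nn_grid_values[[f]]) {
        stop("hyperparameter '", f, "' value ", hyper[[f]],
             " is not in the search grid", call. = FALSE)
      }
    }
  }
  invisible(hyper)
}

#' Random subsample of the hyperparameter grid
#'
#' Uniform sample without replacement of `ceiling(fraction * nrow(grid))`
#' rows, returned in canonical grid order; `fraction = 1` returns the full
#' grid unchanged. A 50 % sample of the full grid yields 162 distinct
#' combinations. Deterministic given `seed`.
#'
#' @param grid data.frame from [nn_hyper_grid()].
#' @param fraction sampled fraction in (0, 1].
#' @param seed integer seed.
#' @return subset of `grid` (row names record the original grid rows).
#' @export
sample_grid <- function(grid, fraction = 0.5, seed) {
  stopifnot(is.data.frame(grid), fraction > 0, fraction <= 1)
  if (fraction == 1) return(grid)
  m <- ceiling(fraction * nrow(grid))
  idx <- with_seed(seed, sort(sample.int(nrow(grid), m)))
  grid[idx, , drop = FALSE]
}

# Glorot-uniform initialized parameter list
nn_init_weights <- function(hyper, input_width, seed) {
  h <- hyper$hidden_units
  glorot <- function(n_in, n_out) {
    lim <- sqrt(6 / (n_in + n_out))
    matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
  }
  with_seed(seed, list(
    W1 = glorot(input_width, h), b1 = rep(0, h),
    W2 = glorot(h, h), b2 = rep(0, h),
    W3 = glorot(h, 1), b3 = 0
  ))
}

#' Build an untrained network
#'
#' Instantiates the fixed two-hidden-layer architecture for one
#' hyperparameter combination with Glorot-uniform initial weights:
#' `input_width -> dense(h, ReLU) -> dense(h, ReLU) -> dense(1, sigmoid)`.
#' Both hidden layers share the same width. Parameter count for width `h` is
#' `input_width*h + h + h*h + h + h + 1`.
#'
#' @param hyper one row of [nn_hyper_grid()] (list or 1-row data.frame).
#' @param input_width number of input features (1024 for ECFP4).
#' @param seed seed for weight initialization.
#' @param strict_grid require tunables to come from the search grid.
#' @return object of class `offpanel_nn` (untrained: `history` is empty).
#' @export
nn_build <- function(hyper, input_width = 1024L, seed = 1L,
                     strict_grid = TRUE) {
  hyper <- as.list(hyper)
  validate_hyper(hyper, strict = strict_grid)
  structure(list(
    weights = nn_init_weights(hyper, input_width, seed),
    hyper = hyper,
    input_width = as.integer(input_width),
    l2 = 0.001,
    seed = as.integer(seed),
    history = NULL,
    best_epoch = NA_integer_,
    stopped_epoch = NA_integer_
  ), class = "offpanel_nn")
}

nn_n_params <- function(object) {
  sum(vapply(object$weights, length, 1L))
}

relu <- function(x) (x > 0) * x
sigmoid <- function(x) 1 / (1 + exp(-x))

nn_forward_predict <- function(w, x) {
  h1 <- relu(sweep(x %*% w$W1, 2, w$b1, `+`))
  h2 <- relu(sweep(h1 %*% w$W2, 2, w$b2, `+`))
  as.vector(sigmoid(h2 %*% w$W3 + w$b3))
}

bce_loss <- function(y, p, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

l2_penalty <- function(w, l2) {
  l2 * (sum(w$W1^2) + sum(w$W2^2) + sum(w$W3^2))
}

# forward + backward on one minibatch with dropout; returns gradients & loss
nn_batch_grads <- function(w, x, y, hyper, l2) {
  n <- nrow(x)
  keep_in <- 1 - hyper$dropout_input
  keep_h <- 1 - hyper$dropout_hidden
  # inverted dropout masks (train-time scaling)
  x_d <- if (keep_in < 1) {
    x * (matrix(stats::runif(length(x)), n) < keep_in) / keep_in
  } else x
  z1 <- sweep(x_d %*% w$W1, 2, w$b1, `+`)
  a1 <- relu(z1)
  a1_d <- if (keep_h < 1) {
    a1 * (matrix(stats::runif(length(a1)), n) < keep_h) / keep_h
  } else a1
  z2 <- sweep(a1_d %*% w$W2, 2, w$b2, `+`)
  a2 <- relu(z2)
  a2_d <- if (keep_h < 1) {
    a2 * (matrix(stats::runif(length(a2)), n) < keep_h) / keep_h
  } else a2
  p <- as.vector(sigmoid(a2_d %*% w$W3 + w$b3))

  dz3 <- matrix((p - y) / n, ncol = 1)       # BCE + sigmoid shortcut
  gW3 <- crossprod(a2_d, dz3) + 2 * l2 * w$W3
  gb3 <- sum(dz3)
  da2 <- dz3 %*% t(w$W3)
  da2 <- da2 * (if (keep_h < 1) (a2_d != 0) / keep_h else 1)  # through dropout
  dz2 <- da2 * (z2 > 0)
  gW2 <- crossprod(a1_d, dz2) + 2 * l2 * w$W2
  gb2 <- colSums(dz2)
  da1 <- dz2 %*% t(w$W2)
  da1 <- da1 * (if (keep_h < 1) (a1_d != 0) / keep_h else 1)
  dz1 <- da1 * (z1 > 0)
  gW1 <- crossprod(x_d, dz1) + 2 * l2 * w$W1
  gb1 <- colSums(dz1)

  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = gW3, b3 = gb3),
       loss = bce_loss(y, p))
}

#' Train one network run
#'
#' Trains [nn_build()]'s architecture with Adam on binary cross-entropy for
#' at most `max_epochs` epochs, monitoring validation balanced accuracy.
#' Active callbacks:
#' * model checkpoint: the weights of the epoch with the best validation
#'   balanced accuracy are retained and become the run's model;
#' * reduce-LR-on-plateau: the learning rate is halved (floor `lr_min`) after
#'   `patience_lr` epochs without improvement;
#' * early stopping: training stops after `patience_stop` epochs without
#'   improvement.
#'
#' An improvement means the monitored value exceeds the previous best by more
#' than `min_delta`. Runs whose loss becomes non-finite are aborted with an
#' error (callers exclude them from selection).
#'
#' @param x_train,y_train training features (0/1 matrix) and labels.
#' @param x_val,y_val validation features and labels.
#' @param hyper one grid row (list / 1-row data.frame).
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @param max_epochs epoch budget (250 in the full protocol).
#' @param patience_stop early-stopping patience (epochs, default 20).
#' @param patience_lr plateau patience before an LR reduction (default 10).
#' @param lr_factor multiplicative LR reduction factor (default 0.5).
#' @param lr_min learning-rate floor (default 1e-6).
#' @param min_delta minimum monitored improvement (default 1e-4).
#' @param strict_grid require tunables from the search grid.
#' @return trained `offpanel_nn`; `$history` holds the per-epoch log
#'   (learning rate, train loss, validation loss / binary accuracy / balanced
#'   accuracy), `$weights` the checkpointed best-epoch weights, and
#'   `$selection` the validation metrics at the checkpointed epoch.
#' @export
nn_fit <- function(x_train, y_train, x_val, y_val, hyper, seed,
                   max_epochs = 250L, patience_stop = 20L, patience_lr = 10L,
                   lr_factor = 0.5, lr_min = 1e-6, min_delta = 1e-4,
                   strict_grid = TRUE) {
  stopifnot(nrow(x_train) == length(y_train), nrow(x_val) == length(y_val))
  hyper <- as.list(hyper)
  validate_hyper(hyper, strict = strict_grid)
  y_train <- as.numeric(y_train)
  y_val <- as.numeric(y_val)
  net <- nn_build(hyper, input_width = ncol(x_train), seed = seed,
                  strict_grid = strict_grid)
  w <- net$weights
  l2 <- net$l2
  lr <- hyper$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-7
  mstate <- lapply(w, function(p) p * 0)
  vstate <- lapply(w, function(p) p * 0)
  t_step <- 0

  best_ba <- -Inf
  best_epoch <- 0L
  checkpoint <- w
  best_metrics <- NULL
  wait_stop <- 0L
  wait_lr <- 0L
  history <- vector("list", max_epochs)
  n <- nrow(x_train)
  epoch <- 0L

  with_seed(seed, {
    for (epoch in seq_len(max_epochs)) {
      idx <- sample.int(n)
      batch_starts <- seq(1, n, by = hyper$batch_size)
      epoch_losses <- numeric(length(batch_starts))
      for (bi in seq_along(batch_starts)) {
        b <- idx[batch_starts[bi]:min(batch_starts[bi] + hyper$batch_size - 1, n)]
        res <- nn_batch_grads(w, x_train[b, , drop = FALSE], y_train[b],
                              hyper, l2)
        epoch_losses[bi] <- res$loss
        t_step <- t_step + 1
        corr1 <- 1 - beta1^t_step
        corr2 <- 1 - beta2^t_step
        for (pn in names(w)) {
          g <- res$grads[[pn]]
          mstate[[pn]] <- beta1 * mstate[[pn]] + (1 - beta1) * g
          vstate[[pn]] <- beta2 * vstate[[pn]] + (1 - beta2) * g^2
          w[[pn]] <- w[[pn]] - lr * (mstate[[pn]] / corr1) /
            (sqrt(vstate[[pn]] / corr2) + adam_eps)
        }
      }
      train_loss <- mean(epoch_losses) + l2_penalty(w, l2)
      p_val <- nn_forward_predict(w, x_val)
      val_loss <- bce_loss(y_val, p_val) + l2_penalty(w, l2)
      if (!is.finite(train_loss) || !is.finite(val_loss)) {
        stop("non-finite loss at epoch ", epoch, "; run aborted",
             call. = FALSE)
      }
      val_acc <- mean((p_val >= 0.5) == (y_val == 1))
      val_ba <- balanced_accuracy(y_val, p_val)
      history[[epoch]] <- data.frame(
        epoch = epoch, lr = lr, train_loss = train_loss,
        val_loss = val_loss, val_acc = val_acc, val_ba = val_ba
      )
      improved <- val_ba > best_ba + min_delta
      if (improved) {
        best_ba <- val_ba
        best_epoch <- epoch
        checkpoint <- w
        best_metrics <- list(val_loss = val_loss, val_acc = val_acc,
                             val_ba = val_ba, epoch = epoch)
        wait_stop <- 0L
        wait_lr <- 0L
      } else {
        wait_stop <- wait_stop + 1L
        wait_lr <- wait_lr + 1L
      }
      if (wait_lr >= patience_lr && lr > lr_min) {
        lr <- max(lr * lr_factor, lr_min)
        wait_lr <- 0L
      }
      if (wait_stop >= patience_stop) break
    }
  })

  net$weights <- checkpoint
  net$history <- do.call(rbind, history[!vapply(history, is.null, TRUE)])
  net$best_epoch <- best_epoch
  net$stopped_epoch <- epoch
  net$selection <- best_metrics
  net$trained <- TRUE
  net
}

#' @export
predict.offpanel_nn <- function(object, newdata, type = c("prob", "class"),
                                ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$input_width) {
    stop("feature width ", ncol(newdata), " does not match the model's ",
         object$input_width, call. = FALSE)
  }
  p <- nn_forward_predict(object$weights, newdata)
  if (type == "class") as.integer(p >= 0.5) else p
}

#' @export
print.offpanel_nn <- function(x, ...) {
  cat("Feed-forward network (", x$input_width, " -> ",
      x$hyper$hidden_units, " -> ", x$hyper$hidden_units, " -> 1), ",
      format(nn_n_params(x), big.mark = ","), " parameters\n", sep = "")
  cat("  dropout in/hidden: ", x$hyper$dropout_input, "/",
      x$hyper$dropout_hidden, ", lr ", x$hyper$learning_rate,
      ", batch ", x$hyper$batch_size, ", L2 ", x$l2, "\n", sep = "")
  if (!is.null(x$history)) {
    cat("  trained ", x$stopped_epoch, " epoch(s); checkpoint at epoch ",
        x$best_epoch, " (val BA ", sprintf("%.4f", x$selection$val_ba),
        ")\n", sep = "")
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

#' Grid search for one target
#'
#' Trains one run per row of the (sampled) hyperparameter grid on a target's
#' frozen train/validation features, then retains three models: best
#' validation loss, best validation balanced accuracy, and best validation
#' binary accuracy — each chosen across the checkpointed runs, ties broken by
#' canonical grid order. Runs that diverge (non-finite loss) are excluded
#' with a warning.
#'
#' @inheritParams nn_fit
#' @param grid hyperparameter grid (default: full grid, 50 % sampled).
#' @param fraction grid fraction to sample (ignored when `grid` is given).
#' @param reduced use the reduced single-combination grid.
#' @param seed master seed; per-run seeds are derived from it.
#' @param split_checksum checksum of the frozen split used (stored in the
#'   manifest as a leak guard).
#' @param ... passed to [nn_fit()] (e.g. `max_epochs`).
#' @return object of class `model_bundle` with elements `models` (named
#'   `best_loss`, `best_ba`, `best_acc`), `runs`, and `manifest`.
#' @export
tune_nn <- function(x_train, y_train, x_val, y_val, seed, grid = NULL,
                    fraction = 0.5, reduced = FALSE, split_checksum = NULL,
                    ...) {
  if (is.null(grid)) {
    grid <- nn_hyper_grid(reduced = reduced)
    if (!reduced) grid <- sample_grid(grid, fraction, seed)
  }
  run_seeds <- derive_seeds(seed, nrow(grid))
  runs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    runs[[i]] <- tryCatch(
      nn_fit(x_train, y_train, x_val, y_val, grid[i, , drop = FALSE],
             seed = run_seeds[i], ...),
      error = function(e) {
        warning("grid run ", i, " excluded: ", conditionMessage(e),
                call. = FALSE)
        NULL
      }
    )
  }
  ok <- !vapply(runs, is.null, TRUE)
  if (!any(ok)) stop("all grid runs failed", call. = FALSE)
  bundle <- select_models(runs[ok])
  bundle$grid <- grid
  bundle$seed <- seed
  bundle$split_checksum <- split_checksum
  bundle$manifest$split_checksum <- split_checksum %||% NA_character_
  bundle
}

#' Retain the three models of a grid search
#'
#' From the checkpointed runs, picks (i) the lowest validation loss, (ii) the
#' highest validation balanced accuracy and (iii) the highest validation
#' binary accuracy. The three selections may reference the same run. Ties go
#' to the earliest run in canonical grid order.
#'
#' @param runs list of trained `offpanel_nn` runs.
#' @return `model_bundle` with `models` (named list), `runs`, and a
#'   `manifest` data.frame recording each selection's hyperparameters, seed
#'   and validation metrics.
#' @export
select_models <- function(runs) {
  runs <- runs[!vapply(runs, is.null, TRUE)]
  if (!length(runs)) stop("no successful runs to select from", call. = FALSE)
  val_loss <- vapply(runs, function(r) r$selection$val_loss, 1.0)
  val_ba <- vapply(runs, function(r) r$selection$val_ba, 1.0)
  val_acc <- vapply(runs, function(r) r$selection$val_acc, 1.0)
  pick <- c(
    best_loss = which.min(val_loss),   # which.min/max take the first tie
    best_ba = which.max(val_ba),
    best_acc = which.max(val_acc)
  )
  manifest <- do.call(rbind, lapply(names(pick), function(cr) {
    r <- runs[[pick[[cr]]]]
    data.frame(
      criterion = cr, run = pick[[cr]],
      hidden_units = r$hyper$hidden_units,
      dropout_input = r$hyper$dropout_input,
      dropout_hidden = r$hyper$dropout_hidden,
      learning_rate = r$hyper$learning_rate,
      batch_size = r$hyper$batch_size,
      seed = r$seed, best_epoch = r$best_epoch,
      stopped_epoch = r$stopped_epoch,
      val_loss = r$selection$val_loss,
      val_ba = r$selection$val_ba,
      val_acc = r$selection$val_acc,
      stringsAsFactors = FALSE
    )
  }))
  structure(list(
    models = list(best_loss = runs[[pick[["best_loss"]]]],
                  best_ba = runs[[pick[["best_ba"]]]],
                  best_acc = runs[[pick[["best_acc"]]]]),
    runs = runs,
    manifest = manifest
  ), class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat("Model bundle: ", length(x$runs), " run(s), 3 retained criteria\n",
      sep = "")
  print(x$manifest[, c("criterion", "run", "hidden_units", "learning_rate",
                       "batch_size", "val_loss", "val_ba", "val_acc")])
  invisible(x)
}
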