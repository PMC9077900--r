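test_that("grid enumeration and sampling are exact", {
  g <- nn_hyper_grid()
  expect_equal(nrow(g), 4 * 3 * 3 * 3 * 3)
  expect_equal(nrow(g), 324)
  s <- sample_grid(g, 0.5, seed = 1)
  expect_equal(nrow(s), 162)
  expect_equal(anyDuplicated(s), 0)
  expect_identical(sample_grid(g, 0.5, seed = 1), s)
  expect_identical(sample_grid(g, 1.0, seed = 99), g)
  expect_equal(nrow(nn_hyper_grid(reduced = TRUE)), 1)
})

test_that("architecture has the documented parameter count and range", {
  hp <- list(hidden_units = 256L, dropout_input = 0.1, dropout_hidden = 0.2,
             learning_rate = 0.001, batch_size = 64L)
  net <- nn_build(hp, input_width = 1024L, seed = 1)
  expect_equal(offpanel:::nn_n_params(net),
               1024 * 256 + 256 + 256 * 256 + 256 + 256 * 1 + 1)
  # both hidden layers share the width
  expect_equal(dim(net$weights$W2), c(256, 256))
  # untrained output is a valid probability
  x <- matrix(rbinom(5 * 1024, 1, 0.05), 5, 1024)
  p <- predict(net, x)
  expect_true(all(p > 0 & p < 1))
  expect_error(nn_build(list(hidden_units = 300L, dropout_input = 0.1,
                             dropout_hidden = 0.2, learning_rate = 0.001,
                             batch_size = 64L)), "hidden_units")
})

test_that("balanced accuracy metric handles batches and absent classes", {
  expect_equal(balanced_accuracy(c(1, 1, 0, 0), c(.9, .8, .1, .2)), 1.0)
  expect_equal(balanced_accuracy(c(1, rep(0, 99)), rep(0.1, 100)), 0.5)
  # confusion-count oracle: TP=1, FN=1, TN=1, FP=1
  expect_equal(balanced_accuracy(c(1, 1, 0, 0), c(.9, .2, .1, .8)), 0.5)
  # absent class: recall of the present class only
  expect_equal(balanced_accuracy(c(1, 1), c(0.9, 0.2)), 0.5)
  expect_error(balanced_accuracy(numeric(), numeric()), "empty")
})

test_that("backpropagation matches numerical gradients", {
  set.seed(5)
  hp <- list(hidden_units = 256L, dropout_input = 0, dropout_hidden = 0.2,
             learning_rate = 0.001, batch_size = 64L)
  # dropout off for the check (masks would differ between evaluations)
  hp$dropout_hidden <- 0.2  # grid value, but disable via keep prob below
  hp_nodrop <- hp; hp_nodrop$dropout_hidden <- 0; hp_nodrop$dropout_input <- 0
  x <- matrix(rbinom(6 * 20, 1, 0.3), 6, 20)
  y <- c(1, 0, 1, 0, 1, 0)
  w <- offpanel:::nn_init_weights(list(hidden_units = 8L), 20, seed = 2)
  l2 <- 0.001
  res <- offpanel:::nn_batch_grads(w, x, y, hp_nodrop, l2)
  loss_at <- function(w) {
    p <- offpanel:::nn_forward_predict(w, x)
    offpanel:::bce_loss(y, p) + offpanel:::l2_penalty(w, l2)
  }
  eps <- 1e-6
  for (pn in c("W1", "W2", "W3", "b2")) {
    for (k in sample(seq_along(w[[pn]]), min(5, length(w[[pn]])))) {
      wp <- w; wp[[pn]][k] <- wp[[pn]][k] + eps
      wm <- w; wm[[pn]][k] <- wm[[pn]][k] - eps
      num <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      expect_equal(res$grads[[pn]][k], num, tolerance = 1e-4)
    }
  }
})

test_that("training runs are exactly reproducible and checkpointed", {
  ld <- learnable_data()
  hp <- nn_hyper_grid(reduced = TRUE)
  fit1 <- nn_fit(ld$fp[ld$idx$train, ], ld$y[ld$idx$train],
                 ld$fp[ld$idx$validation, ], ld$y[ld$idx$validation],
                 hp, seed = 31, max_epochs = 25)
  fit2 <- nn_fit(ld$fp[ld$idx$train, ], ld$y[ld$idx$train],
                 ld$fp[ld$idx$validation, ], ld$y[ld$idx$validation],
                 hp, seed = 31, max_epochs = 25)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$weights, fit2$weights)

  # the checkpointed epoch dominates the whole validation-BA trace
  expect_equal(fit1$selection$val_ba, max(fit1$history$val_ba))
  expect_equal(fit1$best_epoch,
               which(fit1$history$val_ba == max(fit1$history$val_ba))[1])
  # learning-rate trace never increases
  expect_true(all(diff(fit1$history$lr) <= 0))
  # the stored weights really are the best epoch's weights
  p_val <- predict(fit1, ld$fp[ld$idx$validation, ])
  expect_equal(balanced_accuracy(ld$y[ld$idx$validation], p_val),
               fit1$selection$val_ba)
})

test_that("model selection retains three criteria with canonical ties", {
  ld <- learnable_data()
  grid <- rbind(
    nn_hyper_grid(reduced = TRUE),
    transform(nn_hyper_grid(reduced = TRUE), learning_rate = 0.01)
  )
  bundle <- tune_nn(ld$fp[ld$idx$train, ], ld$y[ld$idx$train],
                    ld$fp[ld$idx$validation, ], ld$y[ld$idx$validation],
                    seed = 17, grid = grid, max_epochs = 12,
                    split_checksum = "abc")
  expect_s3_class(bundle, "model_bundle")
  expect_named(bundle$models, c("best_loss", "best_ba", "best_acc"))
  expect_equal(nrow(bundle$manifest), 3)
  expect_equal(unique(bundle$manifest$split_checksum), "abc")
  vals <- vapply(bundle$runs, function(r) r$selection$val_ba, 1.0)
  expect_equal(bundle$models$best_ba$selection$val_ba, max(vals))

  # single run: all three selections reference it
  one <- select_models(bundle$runs[1])
  expect_identical(one$models$best_loss, one$models$best_ba)

  # exact ties resolve to the earliest run in grid order
  tie <- select_models(list(bundle$runs[[1]], bundle$runs[[1]]))
  expect_equal(unique(tie$manifest$run), 1)
})
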