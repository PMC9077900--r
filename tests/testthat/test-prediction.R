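test_that("bundles round-trip losslessly and refuse corruption", {
  ld <- learnable_data()
  bundle <- tune_nn(ld$fp[ld$idx$train, ], ld$y[ld$idx$train],
                    ld$fp[ld$idx$validation, ], ld$y[ld$idx$validation],
                    seed = 19, reduced = TRUE, max_epochs = 10,
                    split_checksum = ld$splits$L1$checksum)
  dir <- withr::local_tempdir()
  save_bundle(bundle, dir, target_id = "L1")
  back <- load_bundle(dir)
  expect_named(back$models, c("best_loss", "best_ba", "best_acc"),
               ignore.order = TRUE)
  probe <- ld$fp[ld$idx$test, ]
  expect_identical(predict(back$models$best_ba, probe),
                   predict(bundle$models$best_ba, probe))

  # manifest claiming a different feature width is refused
  mf <- offpanel:::read_json_file(file.path(dir, "manifest.json"))
  mf$input_width <- 512
  offpanel:::write_json_file(mf, file.path(dir, "manifest.json"))
  expect_error(load_bundle(dir), "width")

  # corrupted weight file fails its checksum
  mf$input_width <- 1024
  offpanel:::write_json_file(mf, file.path(dir, "manifest.json"))
  f <- file.path(dir, "nn_best_ba.rds")
  writeBin(as.raw(1:64), f)
  expect_error(load_bundle(dir), "checksum")
})

test_that("evaluation enforces the frozen-split leak guard", {
  ld <- learnable_data()
  bundle <- tune_nn(ld$fp[ld$idx$train, ], ld$y[ld$idx$train],
                    ld$fp[ld$idx$validation, ], ld$y[ld$idx$validation],
                    seed = 19, reduced = TRUE, max_epochs = 5,
                    split_checksum = ld$splits$L1$checksum)
  r1 <- evaluate_model(bundle$models$best_ba, ld$fp[ld$idx$test, ],
                       ld$y[ld$idx$test],
                       split_checksum = ld$splits$L1$checksum,
                       trained_checksum = bundle$split_checksum)
  r2 <- evaluate_model(bundle$models$best_ba, ld$fp[ld$idx$test, ],
                       ld$y[ld$idx$test])
  expect_equal(r1$balanced_accuracy, r2$balanced_accuracy)
  expect_error(
    evaluate_model(bundle$models$best_ba, ld$fp[ld$idx$test, ],
                   ld$y[ld$idx$test], split_checksum = "deadbeef",
                   trained_checksum = bundle$split_checksum),
    "checksum mismatch"
  )
})

test_that("panel prediction scores valid structures and records rejects", {
  rec <- recovery_fit()
  fit <- rec$fit
  smiles <- c(ok1 = "CCOc1ccccc1", bad = "C1CC", ok2 = "c1ccncc1")
  pred <- predict_panel(fit, smiles)
  expect_s3_class(pred, "panel_prediction")
  expect_equal(nrow(pred), 2 * length(fit$targets))
  expect_equal(attr(pred, "rejected")$id, "bad")
  expect_true(all(pred$probability > 0 & pred$probability < 1))
  expect_equal(pred$call, as.integer(pred$probability >= 0.5))
  # deterministic
  pred2 <- predict_panel(fit, smiles)
  expect_equal(as.data.frame(pred), as.data.frame(pred2))
  # wide matrix aligned with the long form
  wide <- attr(pred, "wide")
  expect_equal(unname(wide["ok1", "T1"]),
               pred$probability[pred$id == "ok1" & pred$target_id == "T1"])
})

test_that("training compounds are in-domain and score identically in serving", {
  rec <- recovery_fit()
  fit <- rec$fit
  sp <- fit$splits$T1
  train_smiles <- sp$train[1:10]
  sub <- rec$panel[rec$panel$target_id == "T1", ]
  fp <- ecfp4_fingerprints(train_smiles)
  fitted_probs <- predict(fit$targets$T1$nn$models$best_ba, fp)
  pred <- predict_panel(fit, train_smiles)
  expect_equal(pred$probability[pred$target_id == "T1"], fitted_probs,
               tolerance = 1e-15)
  expect_true(all(pred$in_domain[pred$target_id == "T1"]))
})
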