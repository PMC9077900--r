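# Shared fixtures, generated in code. Heavyweight objects are memoised per
# test session so several test files can reuse one training run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# small two-target raw panel with curation hazards baked in
tiny_panel_rows <- function(seed = 42) {
  gen <- generate_panel(panel_spec(
    data.frame(target_id = c("T1", "T2"), n = c(80L, 60L),
               hit_rate = c(0.25, 0.2)),
    noise = 0, seed = seed, inject_invalid = 2L, inject_duplicates = 3L
  ))
  gen
}

# learnable single-target panel: n = 240, hit rate 20 %, no label noise
learnable_data <- function() {
  memo("learnable_data", {
    gen <- generate_panel(panel_spec(
      data.frame(target_id = "L1", n = 240L, hit_rate = 0.2),
      noise = 0, seed = 101
    ))
    panel <- suppressWarnings(curate_panel(gen$rows))
    splits <- suppressWarnings(make_splits(panel, seed = 5))
    sub <- panel[panel$target_id == "L1", ]
    fp <- ecfp4_fingerprints(sub$smiles)
    idx <- offpanel:::split_indices(splits$L1, sub$smiles)
    list(panel = panel, splits = splits, sub = sub, fp = fp, idx = idx,
         y = sub$activity)
  })
}

# the full-protocol recovery run shared by the acceptance tests:
# n = 600, hit rate 20 %, label noise 10 %, reduced grid, 250-epoch budget
recovery_fit <- function() {
  memo("recovery_fit", {
    gen <- generate_panel(panel_spec(
      data.frame(target_id = "T1", n = 600L, hit_rate = 0.2),
      noise = 0.1, seed = 7
    ))
    panel <- suppressWarnings(curate_panel(gen$rows))
    fit <- suppressWarnings(fit_offtarget_panel(
      panel, seed = 11, reduced_grid = TRUE, max_epochs = 250L
    ))
    list(gen = gen, panel = panel, fit = fit)
  })
}

# brute-force metric oracle: recomputes every statistic from raw 0/1
# vectors, independently of classification_metrics() (MCC via Pearson
# correlation of the binary vectors)
oracle_metrics <- function(y, p) {
  acc <- mean(y == p)
  tpr <- if (any(y == 1)) mean(p[y == 1] == 1) else 0
  tnr <- if (any(y == 0)) mean(p[y == 0] == 0) else 0
  fpr <- if (any(y == 0)) mean(p[y == 0] == 1) else 0
  prec <- if (any(p == 1)) mean(y[p == 1] == 1) else 0
  mcc <- if (length(unique(y)) > 1 && length(unique(p)) > 1) {
    stats::cor(y, p)
  } else 0
  f1 <- if (prec + tpr > 0) 2 * prec * tpr / (prec + tpr) else 0
  list(accuracy = acc, tpr = tpr, fpr = fpr,
       balanced_accuracy = (tpr + tnr) / 2, mcc = mcc,
       precision = prec, f1 = f1)
}

# expand confusion counts back into label/prediction vectors
cm_to_vectors <- function(tp, fp, tn, fn) {
  list(y = c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn)),
       p = c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn)))
}
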