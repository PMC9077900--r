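test_that("libraries are deterministic, valid and carry duplicate fixtures", {
  l1 <- generate_library(60, seed = 1)
  l2 <- generate_library(60, seed = 1)
  expect_identical(l1, l2)
  can <- canonical_smiles(l1$smiles)
  expect_false(anyNA(can))
  # at least one pair canonicalizes identically (fixture pairs)
  expect_gt(sum(duplicated(can)), 0)
  expect_false(identical(generate_library(60, seed = 2)$smiles, l1$smiles))
})

test_that("generated panels realize the requested hit rates exactly", {
  spec <- panel_spec(data.frame(target_id = c("A", "B"),
                                n = c(400L, 250L),
                                hit_rate = c(0.2, 0.05)),
                     noise = 0.1, seed = 3)
  gen <- generate_panel(spec)
  raw_summ <- suppressWarnings(summarize_targets(gen$rows))
  expect_equal(raw_summ$hit_percent[raw_summ$target_id == "A"], 20)
  expect_equal(raw_summ$hit_percent[raw_summ$target_id == "B"],
               100 * round(0.05 * 250) / 250)
  # curation can only nudge the rate slightly
  panel <- suppressWarnings(curate_panel(gen$rows))
  summ <- suppressWarnings(summarize_targets(panel))
  expect_true(all(abs(summ$hit_percent - c(20, 5)[match(summ$target_id,
                                                        c("A", "B"))]) < 2))
  # ground truth is returned for recovery checks
  expect_named(gen$truth, c("A", "B"))
  expect_equal(length(gen$truth$A$rule_active), round(0.2 * 400))
})

test_that("panel sparsity produces the expected row count", {
  spec <- panel_spec(data.frame(target_id = paste0("T", 1:4),
                                n = NA_integer_, hit_rate = 0.2),
                     noise = 0, seed = 5, library_size = 500L,
                     sparsity = 0.3)
  gen <- generate_panel(spec)
  expect_equal(nrow(gen$rows), 4 * round(0.3 * 500))
  # compounds recur across targets: the matrix is incomplete but shared
  tabs <- table(gen$rows$compound_id)
  expect_gt(max(tabs), 1)
  expect_lt(length(unique(gen$rows$compound_id)),
            nrow(gen$rows))
})

test_that("unachievable specs are rejected with advice", {
  expect_error(
    generate_panel(panel_spec(data.frame(target_id = "X", n = 50L,
                                         hit_rate = 0.005),
                              noise = 0, seed = 1)),
    "unachievable"
  )
  expect_error(
    generate_panel(panel_spec(data.frame(target_id = "X", n = 300L,
                                         hit_rate = 0.3),
                              noise = 0, seed = 1, library_size = 100L)),
    "library"
  )
  # demands beyond the fragment grammar are refused too
  expect_error(
    generate_panel(panel_spec(data.frame(target_id = "X", n = 3000L,
                                         hit_rate = 0.4),
                              noise = 0, seed = 1)),
    "grammar"
  )
})

test_that("label shuffling preserves marginals and is seeded", {
  gen <- tiny_panel_rows()
  panel <- suppressWarnings(curate_panel(gen$rows))
  sh1 <- shuffle_labels(panel, seed = 4)
  sh2 <- shuffle_labels(panel, seed = 4)
  expect_identical(sh1$activity, sh2$activity)
  expect_false(identical(sh1$activity, panel$activity))
  s0 <- suppressWarnings(summarize_targets(panel))
  s1 <- suppressWarnings(summarize_targets(sh1))
  expect_equal(s1$hit_percent, s0$hit_percent)
})

test_that("label noise degrades the planted rule monotonically", {
  # Bayes-rule recovery: score the noise-free rule labels against the noisy
  # panel labels; balanced accuracy must fall as noise rises
  ba_at_noise <- function(noise) {
    mean(vapply(1:5, function(s) {
      gen <- generate_panel(panel_spec(
        data.frame(target_id = "T", n = 300L, hit_rate = 0.2),
        noise = noise, seed = 100 + s
      ))
      truth <- gen$truth[["T"]]
      rule <- as.integer(gen$rows$compound_id %in% truth$rule_active)
      balanced_accuracy(gen$rows$activity, rule)
    }, 1.0))
  }
  b0 <- ba_at_noise(0)
  b1 <- ba_at_noise(0.1)
  b3 <- ba_at_noise(0.3)
  expect_equal(b0, 1.0)
  expect_gt(b0, b1)
  expect_gt(b1, b3)
})
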