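test_that("read_panel parses csv, excape and empty files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,smiles,target,activity",
               "c1,CCO,T1,1", "c2,CCN,T1,0", "c3,CCO,T2,1"), f)
  rows <- read_panel(f)
  expect_equal(nrow(rows), 3)
  expect_equal(rows$activity, c(1L, 0L, 1L))

  fe <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Ambit_InchiKey,SMILES,Activity_Flag,Gene_Symbol",
               "IK1,CCO,A,ABL1", "IK2,CCN,N,ABL1"), fe)
  rows <- read_panel(fe, dialect = "excape")
  expect_equal(rows$activity, c(1L, 0L))
  expect_equal(rows$target_id, c("ABL1", "ABL1"))

  f0 <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,smiles,target,activity", f0)
  expect_warning(rows <- read_panel(f0), "empty")
  expect_equal(nrow(rows), 0)

  fm <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,structure,target,activity", "c1,CCO,T1,1"), fm)
  expect_error(read_panel(fm), "smiles")
})

test_that("percent inhibition binarizes at the inclusive 50 % cutoff", {
  expect_equal(binarize_activity(c(87.3, 49.9, 50.0)), c(1L, 0L, 1L))
  expect_warning(out <- binarize_activity(c(180, -80)), "outside")
  expect_equal(out, c(1L, 0L))
  expect_true(is.na(suppressWarnings(binarize_activity("not a number"))))
})

test_that("curation keeps inter-target and collapses intra-target duplicates", {
  rows <- data.frame(
    compound_id = c("a", "b", "c"),
    smiles = c("C1CC1", "C1CC1", "C1CC1"),
    target_id = c("T1", "T1", "T2"),
    activity = c(1L, 1L, 0L), stringsAsFactors = FALSE
  )
  panel <- suppressWarnings(curate_panel(rows))
  expect_equal(nrow(panel), 2)
  expect_setequal(panel$target_id, c("T1", "T2"))

  # unparsable structures are dropped with a warning
  rows_bad <- rbind(rows, data.frame(compound_id = "d", smiles = "C1CC",
                                     target_id = "T1", activity = 1L))
  w <- capture_warnings(panel2 <- curate_panel(rows_bad))
  expect_true(any(grepl("invalid SMILES", w)))
  expect_equal(nrow(panel2), 2)

  # conflicting duplicates (OCC canonicalizes to CCO) drop all copies
  conflict <- data.frame(compound_id = c("e", "f"),
                         smiles = c("CCO", "OCC"),
                         target_id = "T1", activity = c(1L, 0L),
                         stringsAsFactors = FALSE)
  expect_warning(panel3 <- curate_panel(conflict), "conflicting")
  expect_equal(nrow(panel3), 0)
})

test_that("re-curating a curated panel is a no-op", {
  gen <- tiny_panel_rows()
  panel <- suppressWarnings(curate_panel(gen$rows))
  again <- suppressWarnings(curate_panel(as.data.frame(panel)))
  expect_equal(as.data.frame(again), as.data.frame(panel),
               ignore_attr = TRUE)
})

test_that("target summaries reproduce printed screening arithmetic", {
  df <- data.frame(
    target_id = rep(c("SLC6A2", "AGTR1"), c(2360, 1762)),
    activity = c(rep(1L, 393), rep(0L, 2360 - 393),
                 rep(1L, 45), rep(0L, 1762 - 45))
  )
  summ <- suppressWarnings(summarize_targets(df))
  expect_equal(round(summ$hit_percent[summ$target_id == "SLC6A2"], 2), 16.65)
  expect_equal(round(summ$hit_percent[summ$target_id == "AGTR1"], 2), 2.55)
  expect_equal(summ$hit_class, c("low", "low"))

  zero <- data.frame(target_id = rep("Z", 100), activity = rep(0L, 100))
  expect_warning(sz <- summarize_targets(zero), "low hit rate")
  expect_equal(sz$hit_percent, 0)
  expect_equal(sz$hit_class, "low")
})

test_that("screened counts over targets add up to the table size", {
  gen <- tiny_panel_rows()
  panel <- suppressWarnings(curate_panel(gen$rows))
  summ <- suppressWarnings(summarize_targets(panel))
  expect_equal(sum(summ$screened), nrow(panel))
  expect_true(all(summ$positives <= summ$screened))
})

test_that("merging panels unions rows, dedups, and recounts", {
  a <- suppressWarnings(curate_panel(data.frame(
    compound_id = paste0("a", 1:3), smiles = c("CCO", "CCN", "CCC"),
    target_id = "T1", activity = c(1L, 0L, 0L), provenance = "inhouse"
  )))
  b <- suppressWarnings(curate_panel(data.frame(
    compound_id = paste0("b", 1:3), smiles = c("CCCl", "CCBr", "CCO"),
    target_id = "T1", activity = c(0L, 1L, 1L), provenance = "public"
  )))
  m <- suppressWarnings(merge_panels(a, b))
  # CCO/T1/1 appears in both sources -> kept once
  expect_equal(nrow(m), 5)
  expect_equal(sum(m$smiles == "CCO"), 1)
  summ <- suppressWarnings(summarize_targets(m))
  expect_equal(summ$screened, 5L)
  expect_equal(summ$positives, 2L)

  # order-insensitive up to row order
  m2 <- suppressWarnings(merge_panels(b, a))
  expect_equal(
    m[order(m$smiles), c("smiles", "activity")],
    m2[order(m2$smiles), c("smiles", "activity")],
    ignore_attr = TRUE
  )
})

test_that("curated panels round-trip through csv", {
  gen <- tiny_panel_rows()
  panel <- suppressWarnings(curate_panel(gen$rows))
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, f)
  back <- read_curated_panel(f)
  expect_equal(as.data.frame(back), as.data.frame(panel),
               ignore_attr = TRUE)
})
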