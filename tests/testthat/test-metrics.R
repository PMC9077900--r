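test_that("confusion counts are exact", {
  cm <- confusion_matrix(c(1, 0), c(1, 0))
  expect_equal(unlist(cm[c("tp", "tn", "fp", "fn")]),
               c(tp = 1L, tn = 1L, fp = 0L, fn = 0L))
  cm2 <- confusion_matrix(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(unlist(cm2[c("tp", "fn", "fp", "tn")]),
               c(tp = 0L, fn = 2L, fp = 2L, tn = 0L))
  # brute-force tally oracle on random pairs
  set.seed(1)
  y <- rbinom(1000, 1, 0.3); p <- rbinom(1000, 1, 0.5)
  cm3 <- confusion_matrix(y, p)
  tally <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (i in seq_along(y)) {
    k <- if (y[i] == 1 && p[i] == 1) "tp" else if (y[i] == 0 && p[i] == 1)
      "fp" else if (y[i] == 0) "tn" else "fn"
    tally[k] <- tally[k] + 1L
  }
  expect_equal(unlist(cm3[names(tally)]), tally)
  expect_error(confusion_matrix(integer(), integer()), "empty")
})

test_that("threshold metrics match hand-evaluated formulas", {
  # the misleading-accuracy scenario: all-negative predictions on a 10 %
  # prevalence set look 90 % accurate but carry no signal
  m <- classification_metrics(list(tp = 0, fn = 10, tn = 90, fp = 0))
  expect_equal(m$accuracy, 0.90)
  expect_equal(m$balanced_accuracy, 0.50)
  expect_equal(m$f1, 0)
  expect_equal(m$mcc, 0)

  perfect <- classification_metrics(list(tp = 10, fn = 0, tn = 90, fp = 0))
  expect_equal(perfect[c("accuracy", "balanced_accuracy", "mcc", "f1")],
               list(accuracy = 1, balanced_accuracy = 1, mcc = 1, f1 = 1))

  m2 <- classification_metrics(list(tp = 40, fp = 10, fn = 20, tn = 30))
  expect_equal(m2$precision, 0.8)
  expect_equal(m2$tpr, 40 / 60)
  expect_equal(m2$f1, 40 / (40 + 15))
  expect_equal(m2$balanced_accuracy, (40 / 60 + 30 / 40) / 2)
  expect_equal(m2$mcc,
               (40 * 30 - 10 * 20) / sqrt(50 * 60 * 40 * 50))
})

test_that("all metrics agree with the brute-force oracle on 1000 matrices", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    counts <- rmultinom(1, sample(4:400, 1), prob = runif(4, 0.05, 1))
    v <- cm_to_vectors(counts[1], counts[2], counts[3], counts[4])
    if (length(v$y) == 0) next
    ours <- classification_metrics(
      confusion_matrix(v$y, v$p))
    ref <- oracle_metrics(v$y, v$p)
    for (k in names(ref)) {
      worst <- max(worst, abs(ours[[k]] - ref[[k]]))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("inversion flips MCC sign and reflects balanced accuracy", {
  set.seed(7)
  for (i in 1:20) {
    y <- rbinom(60, 1, 0.4); p <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2 || length(unique(p)) < 2) next
    m <- classification_metrics(confusion_matrix(y, p))
    mi <- classification_metrics(confusion_matrix(y, 1 - p))
    expect_equal(mi$mcc, -m$mcc, tolerance = 1e-12)
    expect_equal(mi$balanced_accuracy, 1 - m$balanced_accuracy,
                 tolerance = 1e-12)
  }
  # when classes are balanced, accuracy equals balanced accuracy exactly
  m <- classification_metrics(list(tp = 13, fn = 37, fp = 8, tn = 42))
  expect_equal(m$accuracy, m$balanced_accuracy)
})

test_that("AUC matches the Mann-Whitney statistic and pROC", {
  set.seed(11)
  y <- rbinom(80, 1, 0.3)
  s <- runif(80) + y * 0.4
  curves <- roc_pr_curves(y, pmin(s, 1))
  s2 <- pmin(s, 1)
  u <- 0
  for (i in which(y == 1)) {
    u <- u + sum(s2[i] > s2[y == 0]) + 0.5 * sum(s2[i] == s2[y == 0])
  }
  expect_equal(curves$auc, u / (sum(y == 1) * sum(y == 0)),
               tolerance = 1e-12)
  expect_equal(curves$auc,
               as.numeric(suppressMessages(pROC::auc(y, s2))),
               tolerance = 1e-10)
})

test_that("curve endpoints, degenerate scores and AUCPR behave", {
  y <- c(1, 1, 0, 0)
  perfect <- roc_pr_curves(y, c(0.9, 0.8, 0.2, 0.1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$aucpr, 1)
  expect_equal(perfect$roc$fpr[1], 0)
  expect_equal(utils::tail(perfect$roc$tpr, 1), 1)

  flat <- roc_pr_curves(y, rep(0.5, 4))
  expect_equal(flat$auc, 0.5)

  # average precision of uninformative scores converges to the prevalence
  set.seed(3)
  yy <- rbinom(4000, 1, 0.15)
  pp <- runif(4000)
  expect_lt(abs(roc_pr_curves(yy, pp)$aucpr - 0.15), 0.02)

  expect_error(roc_pr_curves(rep(1, 5), runif(5)), "AUC undefined")
})

test_that("method ranking counts wins per metric and credits ties", {
  reports <- data.frame(
    target_id = rep(c("T1", "T2", "T3"), each = 2),
    method = rep(c("A", "B"), 3),
    balanced_accuracy = c(0.9, 0.8, 0.7, 0.6, 0.8, 0.7),
    mcc = c(0.5, 0.6, 0.4, 0.4, 0.3, 0.2),
    f1 = c(0.7, 0.6, 0.5, 0.6, 0.4, 0.3)
  )
  r <- rank_methods(reports)
  get <- function(m, meth) r$n_best[r$metric == m & r$method == meth]
  expect_equal(get("balanced_accuracy", "A"), 3L)
  expect_equal(get("balanced_accuracy", "B"), 0L)
  # exact MCC tie on T2 credits both methods
  expect_equal(get("mcc", "A") + get("mcc", "B"), 4L)
  expect_equal(get("f1", "A"), 2L)
  # shuffled input order gives the identical ranking
  r2 <- rank_methods(reports[sample(nrow(reports)), ])
  expect_equal(r2[order(r2$metric, r2$method), "n_best"],
               r[order(r$metric, r$method), "n_best"])
  # a missing cell excludes that target with a warning
  expect_warning(r3 <- rank_methods(reports[-1, ]), "excluded")
  expect_equal(attr(r3, "n_targets"), 2L)
})
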