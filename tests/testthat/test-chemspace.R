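# constructed two-cluster descriptor fixture: source B is displaced from A
# along correlated descriptors (a coherent shift direction survives
# per-column standardization), one column is constant, the rest is noise
make_clusters <- function(n = 40, shift = 50, seed = 1) {
  set.seed(seed)
  base <- function(n) data.frame(
    mw = rnorm(n, 300, 30), logp = rnorm(n, 2, 0.8),
    hbd = rpois(n, 2), hba = rpois(n, 4),
    rotb = rpois(n, 5), constant = 7
  )
  a <- base(n)
  b <- base(n)
  b$mw <- b$mw + shift
  b$logp <- b$logp + shift / 50
  b$hba <- b$hba + shift / 10
  list(a = a, b = b)
}

test_that("zero-variance columns drop and components separate the sources", {
  cl <- make_clusters(shift = 500)
  res <- pca_overlap(cl$a, cl$b)
  expect_equal(res$dropped, "constant")
  expect_true(all(res$explained_variance >= 0))
  expect_true(all(diff(res$explained_variance) <= 1e-12))
  # first component separates the shifted clouds (sign-agnostic)
  pc1_a <- res$scores$PC1[res$scores$source == "A"]
  pc1_b <- res$scores$PC1[res$scores$source == "B"]
  expect_true(max(pc1_a) < min(pc1_b) || min(pc1_a) > max(pc1_b))
})

test_that("identical clouds coincide and fully overlap", {
  cl <- make_clusters()
  res <- pca_overlap(cl$a, cl$a)
  a_scores <- res$scores[res$scores$source == "A", -1]
  b_scores <- res$scores[res$scores$source == "B", -1]
  expect_equal(unname(as.matrix(a_scores)), unname(as.matrix(b_scores)))
  expect_equal(overlap_fraction(res), 1.0)
  # disjoint, well-separated clouds do not overlap at all
  far <- pca_overlap(make_clusters(shift = 5000)$a,
                     make_clusters(shift = 5000)$b)
  expect_equal(overlap_fraction(far), 0.0)
})

test_that("overlap is directional for nested clouds", {
  set.seed(2)
  wide <- data.frame(mw = rnorm(60, 300, 80), logp = rnorm(60, 2, 3),
                     hbd = rnorm(60, 3, 2), hba = rnorm(60, 5, 2))
  narrow <- data.frame(mw = rnorm(60, 300, 4), logp = rnorm(60, 2, 0.1),
                       hbd = rnorm(60, 3, 0.1), hba = rnorm(60, 5, 0.1))
  res <- pca_overlap(narrow, wide, labels = c("narrow", "wide"))
  inner_in_outer <- overlap_fraction(res, of = "narrow", within = "wide")
  outer_in_inner <- overlap_fraction(res, of = "wide", within = "narrow")
  expect_equal(inner_in_outer, 1.0)
  expect_lt(outer_in_inner, inner_in_outer)
})

test_that("explained variance is complete and scores are standardized", {
  cl <- make_clusters()
  res <- pca_overlap(cl$a, cl$b, k = 5)
  expect_equal(sum(res$explained_variance), 1, tolerance = 1e-12)
  # row order does not change the fitted space (up to component sign)
  res2 <- pca_overlap(cl$a[rev(seq_len(nrow(cl$a))), ], cl$b)
  ev1 <- res$explained_variance
  ev2 <- res2$explained_variance
  expect_equal(ev1, ev2, tolerance = 1e-12)
  pc1 <- res$scores$PC1[res$scores$source == "A"]
  pc1r <- res2$scores$PC1[res2$scores$source == "A"]
  expect_true(isTRUE(all.equal(pc1, rev(pc1r))) ||
                isTRUE(all.equal(pc1, -rev(pc1r))))
})

test_that("tiny reference sources fall back to the bounding box", {
  cl <- make_clusters()
  res <- pca_overlap(cl$a, cl$b[1:2, ])
  expect_warning(overlap_fraction(res), "bounding box")
})
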