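# PCA chemical-space overlap diagnostics for dataset-combination studies:
# project two descriptor tables (e.g. an in-house and a public dataset for
# the same target) into a joint principal-component space and quantify how
# much of one cloud the other covers.

#' Joint PCA of two descriptor tables
#'
#' Stacks the two tables, drops columns with zero variance over the combined
#' data, standardizes the remainder (mixed-unit descriptor sets are otherwise
#' dominated by molecular weight), and fits a PCA on the combined table via
#' [stats::prcomp()]. Scores keep a source tag per point.
#'
#' @param descriptors_a,descriptors_b data.frames sharing descriptor
#'   columns (non-numeric columns such as `smiles` are ignored).
#' @param k number of components to retain (default 2).
#' @param labels length-2 source labels.
#' @return object of class `chemspace_pca`: list with `scores` (data.frame
#'   `source`, `PC1..PCk`), `explained_variance` (fractions, all
#'   components), `dropped` (zero-variance column names), `rotation`.
#' @export
pca_overlap <- function(descriptors_a, descriptors_b, k = 2,
                        labels = c("A", "B")) {
  num_cols <- function(d) names(d)[vapply(d, is.numeric, TRUE)]
  shared <- intersect(num_cols(descriptors_a), num_cols(descriptors_b))
  if (!length(shared)) stop("no shared numeric descriptor columns",
                            call. = FALSE)
  combined <- rbind(descriptors_a[, shared, drop = FALSE],
                    descriptors_b[, shared, drop = FALSE])
  source <- rep(labels, c(nrow(descriptors_a), nrow(descriptors_b)))
  cc <- stats::complete.cases(combined)
  combined <- combined[cc, , drop = FALSE]
  source <- source[cc]
  if (nrow(combined) < k + 1) stop("need at least k + 1 complete rows",
                                   call. = FALSE)
  vars <- vapply(combined, stats::var, 1.0)
  dropped <- names(vars)[vars == 0]
  keep <- names(vars)[vars > 0]
  if (!length(keep)) stop("all descriptor columns have zero variance",
                          call. = FALSE)
  pca <- stats::prcomp(combined[, keep, drop = FALSE], center = TRUE,
                       scale. = TRUE)
  k <- min(k, ncol(pca$x))
  scores <- data.frame(source = source, pca$x[, seq_len(k), drop = FALSE],
                       stringsAsFactors = FALSE)
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  structure(list(scores = scores, explained_variance = ev,
                 dropped = dropped, rotation = pca$rotation, k = k,
                 labels = labels),
            class = "chemspace_pca")
}

#' @export
print.chemspace_pca <- function(x, ...) {
  cat("Chemical-space PCA: ", nrow(x$scores), " compounds, ",
      length(x$explained_variance), " component(s)\n", sep = "")
  cat("Explained variance: ",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained_variance, x$k)),
            collapse = ", "), "\n", sep = "")
  if (length(x$dropped)) {
    cat("Dropped zero-variance descriptor(s): ",
        paste(x$dropped, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Fraction of one cloud covered by the other
#'
#' Fraction of source-A score points lying within the region spanned by the
#' source-B points: the convex hull for two components, the axis-aligned
#' bounding box for more (or when B has fewer than 3 points, with a
#' warning). Points coinciding with B points count as covered. Identical
#' clouds give 1; well-separated clouds give 0; the measure is directional
#' (A nested inside a wider B gives 1, the reverse less).
#'
#' @param result a `chemspace_pca` from [pca_overlap()].
#' @param of source whose coverage is measured (default: first label).
#' @param within source providing the reference region (default: second
#'   label).
#' @return fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(result, of = NULL, within = NULL) {
  stopifnot(inherits(result, "chemspace_pca"))
  of <- of %||% result$labels[1]
  within <- within %||% result$labels[2]
  sc <- result$scores
  pcs <- paste0("PC", seq_len(result$k))
  a <- as.matrix(sc[sc$source == of, pcs, drop = FALSE])
  b <- as.matrix(sc[sc$source == within, pcs, drop = FALSE])
  if (!nrow(a) || !nrow(b)) stop("both sources need points", call. = FALSE)
  use_box <- result$k != 2 || nrow(b) < 3
  if (result$k == 2 && nrow(b) < 3) {
    warning("reference source has fewer than 3 points; ",
            "bounding box used instead of the convex hull", call. = FALSE)
  }
  inside <- if (use_box) {
    lo <- apply(b, 2, min)
    hi <- apply(b, 2, max)
    apply(a, 1, function(p) all(p >= lo & p <= hi))
  } else {
    hull <- b[grDevices::chull(b), , drop = FALSE]
    as.logical(mgcv::in.out(rbind(hull, hull[1, ]), a))
  }
  # boundary / coincident points count as covered
  coincident <- apply(a, 1, function(p) {
    any(sqrt(rowSums(sweep(b, 2, p)^2)) < 1e-9)
  })
  mean(inside | coincident)
}

#' Plot the joint chemical space
#'
#' First two components, colored by source, with 95 % normal-theory
#' confidence ellipses per source and explained-variance percentages on the
#' axes.
#'
#' @param x a `chemspace_pca`.
#' @param file optional PNG path.
#' @param ... ignored.
#' @return `NULL`, invisibly.
#' @export
plot.chemspace_pca <- function(x, file = NULL, ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  sc <- x$scores
  cols <- c("#1f77b4", "#e377c2")
  src <- unique(sc$source)
  graphics::plot(sc$PC1, sc$PC2,
                 col = cols[match(sc$source, src)], pch = 16, cex = 0.7,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained_variance[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained_variance[2]),
                 main = "Chemical-space overlap")
  for (i in seq_along(src)) {
    pts <- as.matrix(sc[sc$source == src[i], c("PC1", "PC2")])
    if (nrow(pts) >= 3) {
      graphics::lines(conf_ellipse(pts), col = cols[i], lwd = 2)
    }
  }
  graphics::legend("topright", legend = src, col = cols[seq_along(src)],
                   pch = 16, bty = "n")
  invisible(NULL)
}

# 95 % normal-theory ellipse of a 2-column point matrix
conf_ellipse <- function(pts, level = 0.95, n = 100) {
  ctr <- colMeans(pts)
  cv <- stats::cov(pts)
  r <- sqrt(stats::qchisq(level, df = 2))
  theta <- seq(0, 2 * pi, length.out = n)
  circle <- cbind(cos(theta), sin(theta)) * r
  t(ctr + t(circle %*% chol(cv)))
}
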