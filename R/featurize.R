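# Structure featurization: 1024-bit ECFP4 fingerprints for the models and the
# eight physchem descriptors used for the bounding-box applicability domain.

domain_descriptors <- c("mw", "logp", "hbd", "hba", "rotb", "mr",
                        "polarizability", "lipinski_failures")

#' ECFP4 fingerprints
#'
#' Computes binary extended-connectivity (Morgan) fingerprints of diameter 4
#' (atom-neighborhood radius 2 — the standard ECFP4 convention), folded to
#' `nbits` bits. Identical canonical structures map to identical rows.
#'
#' @param smiles character vector of valid SMILES (pre-validate with
#'   [curate_panel()]; unparsable input is an error here).
#' @param radius Morgan neighborhood radius (default 2, i.e. ECFP4).
#' @param nbits folded width (default 1024).
#' @param standardize standardize structures before fingerprinting (default
#'   `FALSE`: curated panels are already canonical parent structures).
#' @return integer 0/1 matrix with `length(smiles)` rows, `nbits` columns and
#'   `smiles` as row names.
#' @export
ecfp4_fingerprints <- function(smiles, radius = 2L, nbits = 1024L,
                               standardize = FALSE) {
  res <- chem_process(smiles, fingerprints = TRUE, standardize = standardize,
                      radius = radius, nbits = nbits)
  if (any(!res$ok)) {
    stop("unparsable SMILES passed to ecfp4_fingerprints: ",
         paste(utils::head(smiles[!res$ok], 5), collapse = ", "),
         call. = FALSE)
  }
  bits <- matrix(0L, nrow = length(smiles), ncol = nbits,
                 dimnames = list(smiles, NULL))
  for (i in seq_along(smiles)) {
    v <- as.integer(strsplit(res$fp[i], "")[[1]])
    if (length(v) != nbits) {
      stop("backend returned a fingerprint of width ", length(v),
           " (expected ", nbits, ")", call. = FALSE)
    }
    bits[i, ] <- v
  }
  bits
}

#' Physchem descriptor table
#'
#' Computes the eight descriptors used for the applicability-domain bounding
#' box and for chemical-space analysis: molecular weight (Da), logP, hydrogen
#' bond donor and acceptor counts, rotatable bond count, molar refractivity
#' (cm^3/mol), polarizability (A^3, estimated from molar refractivity via the
#' Lorentz-Lorenz relation), and the number of Lipinski rule-of-five failures
#' (0-4).
#'
#' @param smiles character vector of valid SMILES.
#' @param standardize standardize structures first (default `FALSE`).
#' @return data.frame with one row per structure and the eight descriptor
#'   columns; structures the backend cannot process yield `NA` rows and a
#'   warning.
#' @export
compute_descriptors <- function(smiles, standardize = FALSE) {
  res <- chem_process(smiles, fingerprints = FALSE, standardize = standardize)
  if (any(!res$ok)) {
    warning(sum(!res$ok), " structure(s) failed descriptor calculation; ",
            "rows flagged missing", call. = FALSE)
  }
  out <- res[, domain_descriptors]
  out[!res$ok, ] <- NA
  rownames(out) <- NULL
  cbind(data.frame(smiles = smiles, stringsAsFactors = FALSE), out)
}

#' Fit a bounding-box applicability domain
#'
#' Records the observed minimum and maximum of every descriptor over the
#' training compounds. A prediction-time structure is inside the domain when
#' all its descriptors fall within these closed intervals; the box therefore
#' always contains its own training set.
#'
#' @param table descriptor table from [compute_descriptors()] (rows with
#'   missing values are ignored).
#' @return object of class `domain_box`: data.frame with columns
#'   `descriptor`, `min`, `max`.
#' @export
fit_domain_box <- function(table) {
  cols <- intersect(domain_descriptors, names(table))
  if (!length(cols)) stop("no descriptor columns present", call. = FALSE)
  x <- table[, cols, drop = FALSE]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) == 0) stop("no complete descriptor rows to fit a domain box",
                         call. = FALSE)
  box <- data.frame(
    descriptor = cols,
    min = vapply(x, min, 1.0),
    max = vapply(x, max, 1.0),
    stringsAsFactors = FALSE
  )
  rownames(box) <- NULL
  structure(box, class = c("domain_box", "data.frame"), n_train = nrow(x))
}

#' Applicability-domain membership
#'
#' Checks descriptor rows against a fitted bounding box. Boundary values are
#' in-domain (closed intervals). Rows with missing descriptor values are
#' flagged out-of-domain with violation `"missing"`. The flag is advisory:
#' prediction functions report it but never suppress predictions.
#'
#' @param box a `domain_box` from [fit_domain_box()].
#' @param rows descriptor table (one or more rows).
#' @return data.frame with logical `in_domain` and a comma-separated
#'   `violations` column naming the out-of-range descriptors.
#' @export
in_domain <- function(box, rows) {
  stopifnot(inherits(box, "domain_box"))
  miss <- setdiff(box$descriptor, names(rows))
  if (length(miss)) {
    stop("descriptor column(s) missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(rows)
  in_dom <- logical(n)
  viol <- character(n)
  for (i in seq_len(n)) {
    v <- character()
    for (j in seq_len(nrow(box))) {
      d <- box$descriptor[j]
      val <- rows[[d]][i]
      if (is.na(val)) {
        v <- c(v, paste0(d, ":missing"))
      } else if (val < box$min[j] || val > box$max[j]) {
        v <- c(v, d)
      }
    }
    in_dom[i] <- length(v) == 0
    viol[i] <- paste(v, collapse = ",")
  }
  data.frame(in_domain = in_dom, violations = viol, stringsAsFactors = FALSE)
}
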