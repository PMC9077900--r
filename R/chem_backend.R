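# Bridge to the RDKit backend (inst/python/chem_backend.py).
#
# All chemistry (SMILES standardization, ECFP4 fingerprints, physchem
# descriptors) is computed by RDKit through one batched subprocess call per
# unseen set of structures; results are memoised per session so repeated
# curation / featurization of the same structures is free.

chem_python <- function() {
  p <- getOption("offpanel.python", "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  as.character(p)
}

chem_script <- function() {
  system.file("python", "chem_backend.py", package = "offpanel", mustWork = TRUE)
}

#' Is the RDKit chemistry backend available?
#'
#' The package computes all structure-derived quantities through RDKit,
#' invoked as a Python subprocess (see `SystemRequirements`). This probe runs
#' once per session and caches its result.
#'
#' @return `TRUE` if `python` with RDKit is callable.
#' @export
chem_backend_available <- function() {
  if (!is.null(.offpanel$backend_ok)) return(.offpanel$backend_ok)
  py <- chem_python()
  ok <- FALSE
  if (nzchar(py)) {
    status <- suppressWarnings(system2(
      py, c("-c", shQuote("import rdkit")),
      stdout = FALSE, stderr = FALSE
    ))
    ok <- identical(status, 0L)
  }
  .offpanel$backend_ok <- ok
  ok
}

chem_cache <- function() {
  if (is.null(.offpanel$chem_cache)) {
    .offpanel$chem_cache <- new.env(parent = emptyenv())
  }
  .offpanel$chem_cache
}

# Run the backend on a character vector of SMILES. Returns a data.frame with
# one row per input (ok, error, canonical_smiles, descriptors, fp bit string).
chem_process <- function(smiles, fingerprints = TRUE, standardize = TRUE,
                         radius = 2L, nbits = 1024L) {
  stopifnot(is.character(smiles))
  if (!chem_backend_available()) {
    stop("RDKit backend unavailable: need 'python' with rdkit on the PATH ",
         "(or set options(offpanel.python = ...))", call. = FALSE)
  }
  key_of <- function(s) {
    paste0(if (standardize) "s|" else "r|",
           if (fingerprints) "f" else "-", radius, "x", nbits, "|", s)
  }
  cache <- chem_cache()
  keys <- vapply(smiles, key_of, "", USE.NAMES = FALSE)
  miss <- !vapply(keys, exists, TRUE, envir = cache, USE.NAMES = FALSE)
  todo <- unique(smiles[miss])
  if (length(todo)) {
    fin <- tempfile(fileext = ".tsv")
    fout <- tempfile(fileext = ".tsv")
    on.exit(unlink(c(fin, fout)), add = TRUE)
    writeLines(paste(seq_along(todo), todo, sep = "\t"), fin)
    args <- c(chem_script(), "--infile", fin, "--outfile", fout,
              "--radius", radius, "--nbits", nbits)
    if (fingerprints) args <- c(args, "--fp")
    if (!standardize) args <- c(args, "--no-standardize")
    status <- system2(chem_python(), shQuote(args), stdout = FALSE, stderr = FALSE)
    if (!identical(status, 0L) || !file.exists(fout)) {
      stop("chemistry backend call failed (exit status ", status, ")",
           call. = FALSE)
    }
    res <- utils::read.delim(fout, colClasses = "character")
    if (nrow(res) != length(todo)) {
      stop("chemistry backend returned ", nrow(res), " rows for ",
           length(todo), " structures", call. = FALSE)
    }
    for (i in seq_len(nrow(res))) {
      row <- res[i, , drop = FALSE]
      assign(key_of(todo[i]), row, envir = cache)
    }
  }
  out <- do.call(rbind, lapply(keys, get, envir = cache))
  out$idx <- NULL
  out$ok <- out$ok == "1"
  for (col in c("mw", "logp", "mr", "polarizability")) {
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }
  for (col in c("hbd", "hba", "rotb", "lipinski_failures")) {
    out[[col]] <- suppressWarnings(as.integer(out[[col]]))
  }
  out$input_smiles <- smiles
  rownames(out) <- NULL
  out
}

#' Canonicalize and standardize SMILES strings
#'
#' Parses each SMILES with RDKit, applies structure cleanup, keeps the largest
#' fragment (stripping salts and solvents), neutralizes charges, and returns
#' the canonical SMILES of the parent structure. Unparsable inputs yield `NA`.
#'
#' @param smiles character vector of SMILES.
#' @param standardize apply salt stripping / neutralization (default `TRUE`);
#'   if `FALSE` only canonicalization is performed.
#' @return character vector of canonical SMILES (`NA` where invalid), with the
#'   failure messages in attribute `"errors"`.
#' @export
#' @examples
#' \dontrun{canonical_smiles(c("OCC", "c1ccccc1", "C1CC"))}
canonical_smiles <- function(smiles, standardize = TRUE) {
  res <- chem_process(smiles, fingerprints = FALSE, standardize = standardize)
  out <- ifelse(res$ok, res$canonical_smiles, NA_character_)
  attr(out, "errors") <- ifelse(res$ok, NA_character_, res$error)
  out
}
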