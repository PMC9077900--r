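# Reading, validation and curation of tabulated activity panels.
#
# The canonical in-memory form is the "panel_table": a long-format data.frame
# with one curated record per (compound, target) pair and columns
# compound_id, smiles (canonical), target_id, activity (0/1), provenance.
# Curation warnings are accumulated in attribute "warnings".

default_column_maps <- list(
  csv = c(compound_id = "id", smiles = "smiles", target_id = "target",
          activity = "activity", inhibition = "inhibition"),
  xlsx = c(compound_id = "id", smiles = "smiles", target_id = "target",
           activity = "activity", inhibition = "inhibition"),
  excape = c(compound_id = "Ambit_InchiKey", smiles = "SMILES",
             target_id = "Gene_Symbol", activity = "Activity_Flag")
)

#' Read a tabulated activity panel
#'
#' Reads a long-format activity table with one row per (compound, target)
#' measurement. Three dialects are supported: plain `csv`, `xlsx` (first
#' sheet; requires the readxl package), and `excape`-style exports whose
#' `Activity_Flag` column holds "A"/"N" labels. Column names are mapped, not
#' positional, so in-house exports with different headers can be ingested by
#' passing `column_map`.
#'
#' Exactly one of an `activity` column (binary or "A"/"N") and an
#' `inhibition` column (percent inhibition at 10 uM) must be present. No
#' curation is performed here; see [curate_panel()].
#'
#' @param path input file.
#' @param dialect one of `"csv"`, `"xlsx"`, `"excape"`.
#' @param column_map named character vector mapping canonical names
#'   (`compound_id`, `smiles`, `target_id`, `activity`, `inhibition`) to the
#'   file's column headers; defaults per dialect.
#' @param provenance source tag stored with every row (e.g. `"inhouse"`,
#'   `"public"`).
#' @return data.frame of raw rows with columns `compound_id`, `smiles`,
#'   `target_id` and one of `activity` / `inhibition`.
#' @export
read_panel <- function(path, dialect = c("csv", "xlsx", "excape"),
                       column_map = NULL, provenance = dialect[1]) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  map <- column_map %||% default_column_maps[[dialect]]
  raw <- switch(dialect,
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading xlsx requires the readxl package", call. = FALSE)
      }
      as.data.frame(readxl::read_excel(path, sheet = 1))
    },
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  )
  if (nrow(raw) == 0) {
    warning("empty panel file: ", path, call. = FALSE)
  }
  for (field in c("compound_id", "smiles", "target_id")) {
    if (!map[[field]] %in% names(raw)) {
      stop("required column '", map[[field]], "' (", field, ") missing from ",
           path, call. = FALSE)
    }
  }
  out <- data.frame(
    compound_id = as.character(raw[[map[["compound_id"]]]]),
    smiles = as.character(raw[[map[["smiles"]]]]),
    target_id = as.character(raw[[map[["target_id"]]]]),
    stringsAsFactors = FALSE
  )
  has_act <- !is.na(map["activity"]) && map[["activity"]] %in% names(raw)
  has_inh <- !is.na(map["inhibition"]) && map[["inhibition"]] %in% names(raw)
  if (has_act) {
    act <- raw[[map[["activity"]]]]
    if (is.character(act) || is.factor(act)) {
      act <- as.character(act)
      conv <- ifelse(act %in% c("A", "a", "1"), 1L,
                     ifelse(act %in% c("N", "n", "0"), 0L, NA_integer_))
      out$activity <- conv
    } else {
      out$activity <- as.integer(act)
    }
  } else if (has_inh) {
    out$inhibition <- suppressWarnings(as.numeric(raw[[map[["inhibition"]]]]))
    bad <- is.na(out$inhibition) & !is.na(raw[[map[["inhibition"]]]])
    if (any(bad)) out$inhibition[bad] <- NaN  # flagged for curation rejection
  } else {
    stop("no activity or inhibition column found in ", path, call. = FALSE)
  }
  out$provenance <- rep(provenance, nrow(out))
  out
}

#' Binarize percent inhibition into activity labels
#'
#' Applies the fixed activity cutoff: a compound is active when its percent
#' inhibition at 10 uM is at least 50 (boundary inclusive: 50.0 is active),
#' inactive below 50. Values far outside the plausible assay range (outside
#' \[-50, 150\]) are kept and binarized normally but trigger a warning, since
#' they usually indicate assay artefacts.
#'
#' @param inhibition_pct numeric vector of percent-inhibition values.
#' @param cutoff activity cutoff (default 50).
#' @return integer vector of 0/1 labels (`NA` where input is not numeric).
#' @export
#' @examples
#' binarize_activity(c(87.3, 49.9, 50))
binarize_activity <- function(inhibition_pct, cutoff = 50) {
  x <- suppressWarnings(as.numeric(inhibition_pct))
  out_of_range <- !is.na(x) & (x < -50 | x > 150)
  if (any(out_of_range)) {
    warning(sum(out_of_range), " inhibition value(s) outside [-50, 150]; ",
            "kept and binarized (possible assay artefacts)", call. = FALSE)
  }
  ifelse(is.na(x), NA_integer_, as.integer(x >= cutoff))
}

#' Curate raw panel rows into a canonical panel table
#'
#' Applies the workflow's curation rules:
#' * SMILES are standardized (canonical parent structure; salts stripped,
#'   charges neutralized) via the RDKit backend; unparsable structures are
#'   dropped with a logged warning.
#' * Percent-inhibition rows are binarized at the 50 % cutoff; rows with
#'   non-numeric measurements are rejected.
#' * Within each target, duplicated canonical structures are collapsed: the
#'   first row is kept when all labels agree, and all copies are dropped (with
#'   a warning) when labels conflict, since an arbitrary label would inject
#'   noise.
#' * The same structure measured on several targets (inter-target duplicates)
#'   is retained — those rows are what make a panel a panel.
#'
#' @param rows data.frame from [read_panel()] (or of the same shape).
#' @param standardize standardize structures (default `TRUE`); `FALSE`
#'   canonicalizes only.
#' @return an object of class `panel_table`: a data.frame with columns
#'   `compound_id`, `smiles`, `target_id`, `activity`, `provenance`, carrying
#'   curation messages in `attr(, "warnings")`.
#' @export
curate_panel <- function(rows, standardize = TRUE) {
  stopifnot(is.data.frame(rows))
  need <- c("compound_id", "smiles", "target_id")
  if (!all(need %in% names(rows))) {
    stop("rows must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"provenance" %in% names(rows)) rows$provenance <- "input"
  warnings_log <- character()
  n0 <- nrow(rows)
  if (n0 == 0) {
    return(new_panel_table(rows[, c(need, "provenance")], character()))
  }

  # labels
  if (!"activity" %in% names(rows)) {
    if (!"inhibition" %in% names(rows)) {
      stop("rows must carry an 'activity' or 'inhibition' column", call. = FALSE)
    }
    rows$activity <- suppressWarnings(binarize_activity(rows$inhibition))
  }
  bad_label <- is.na(rows$activity) | !rows$activity %in% c(0L, 1L)
  if (any(bad_label)) {
    warnings_log <- c(warnings_log, op_warning(
      sum(bad_label), " row(s) rejected: missing or non-binary activity ",
      "(rows ", paste(utils::head(which(bad_label), 5), collapse = ","),
      if (sum(bad_label) > 5) ",..." else "", ")"
    ))
    rows <- rows[!bad_label, , drop = FALSE]
  }

  # structure validation + canonicalization
  can <- canonical_smiles(rows$smiles, standardize = standardize)
  invalid <- is.na(can)
  if (any(invalid)) {
    warnings_log <- c(warnings_log, op_warning(
      sum(invalid), " row(s) dropped: invalid SMILES (",
      paste(utils::head(unique(rows$smiles[invalid]), 5), collapse = ", "),
      if (length(unique(rows$smiles[invalid])) > 5) ", ..." else "", ")"
    ))
  }
  rows$smiles <- as.character(can)
  rows <- rows[!invalid, , drop = FALSE]

  # intra-target duplicate handling
  if (nrow(rows)) {
    key <- paste(rows$target_id, rows$smiles, sep = "\r")
    keep <- !logical(nrow(rows))
    dup_groups <- split(seq_len(nrow(rows)), key)
    n_collapsed <- 0L
    n_conflict <- 0L
    for (idx in dup_groups) {
      if (length(idx) == 1) next
      labs <- unique(rows$activity[idx])
      if (length(labs) == 1) {
        keep[idx[-1]] <- FALSE
        n_collapsed <- n_collapsed + length(idx) - 1L
      } else {
        keep[idx] <- FALSE
        n_conflict <- n_conflict + length(idx)
      }
    }
    if (n_collapsed > 0) {
      warnings_log <- c(warnings_log, op_warning(
        n_collapsed, " intra-target duplicate row(s) collapsed (labels agree)"
      ))
    }
    if (n_conflict > 0) {
      warnings_log <- c(warnings_log, op_warning(
        n_conflict, " row(s) dropped: intra-target duplicates with ",
        "conflicting labels"
      ))
    }
    rows <- rows[keep, , drop = FALSE]
  }

  rows <- rows[, c("compound_id", "smiles", "target_id", "activity",
                   "provenance")]
  rownames(rows) <- NULL
  new_panel_table(rows, warnings_log)
}

new_panel_table <- function(df, warnings_log) {
  stopifnot(is.data.frame(df))
  structure(df, warnings = warnings_log,
            class = c("panel_table", "data.frame"))
}

#' @export
print.panel_table <- function(x, ...) {
  cat("Curated activity panel: ", nrow(x), " rows, ",
      length(unique(x$target_id)), " target(s), ",
      length(unique(x$smiles)), " unique structure(s)\n", sep = "")
  w <- attr(x, "warnings")
  if (length(w)) cat("Curation warnings:\n", paste0("  - ", w, "\n"), sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' Summarize a curated panel per target
#'
#' Computes, for every target, the number of screened compounds, the number
#' of actives, the hit percent `100 * positives / screened`, and the hit-rate
#' class (`"high"` when the hit percent exceeds 20, else `"low"`). Targets
#' with a hit percent below 1 % or fewer than 10 actives are flagged with a
#' warning — such datasets are kept (the workflow must attempt any dataset)
#' but their models are expected to perform poorly.
#'
#' @param table a `panel_table` (or a data.frame with `target_id`,
#'   `activity`).
#' @param high_cutoff hit-percent boundary between the low and high class
#'   (default 20).
#' @return data.frame with columns `target_id`, `screened`, `positives`,
#'   `hit_percent`, `hit_class`.
#' @export
summarize_targets <- function(table, high_cutoff = 20) {
  stopifnot(all(c("target_id", "activity") %in% names(table)))
  tg <- split(table$activity, table$target_id)
  tg <- tg[lengths(tg) > 0]
  out <- data.frame(
    target_id = names(tg),
    screened = vapply(tg, length, 1L),
    positives = vapply(tg, function(a) sum(a == 1L), 1L),
    stringsAsFactors = FALSE
  )
  out$hit_percent <- 100 * out$positives / out$screened
  out$hit_class <- ifelse(out$hit_percent > high_cutoff, "high", "low")
  low <- out$hit_percent < 1 | out$positives < 10
  if (any(low)) {
    warning("very low hit rate / active count for target(s): ",
            paste(out$target_id[low], collapse = ", "),
            " - models for these datasets are likely to be poor",
            call. = FALSE)
  }
  rownames(out) <- NULL
  out[order(-out$screened), , drop = FALSE]
}

#' Merge two curated panels
#'
#' Takes the union of two curated panel tables (e.g. an in-house and a public
#' export of the same targets), keeping provenance tags, and re-applies the
#' intra-target duplicate policy across the union: identical
#' (structure, target, label) records appear once; conflicting cross-source
#' labels for the same structure and target drop all copies with a warning.
#'
#' @param a,b `panel_table` objects from [curate_panel()].
#' @return a merged `panel_table`.
#' @export
merge_panels <- function(a, b) {
  stopifnot(inherits(a, "panel_table"), inherits(b, "panel_table"))
  combined <- rbind(as.data.frame(a), as.data.frame(b))
  only_a <- setdiff(unique(a$target_id), unique(b$target_id))
  only_b <- setdiff(unique(b$target_id), unique(a$target_id))
  notes <- character()
  if (length(only_a) || length(only_b)) {
    notes <- op_warning(
      "target(s) present in only one source: ",
      paste(c(only_a, only_b), collapse = ", ")
    )
  }
  # rows are already canonical; re-apply the duplicate policy only
  merged <- suppressWarnings(curate_panel(combined, standardize = FALSE))
  attr(merged, "warnings") <- c(attr(a, "warnings"), attr(b, "warnings"),
                                notes, attr(merged, "warnings"))
  merged
}

#' Write / read a curated panel as CSV
#'
#' @param panel a `panel_table`.
#' @param path output CSV path.
#' @return `write_panel` returns `path` invisibly; `read_curated_panel`
#'   returns a `panel_table` (rows are trusted as already curated).
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "panel_table"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_curated_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "smiles", "target_id", "activity", "provenance")
  if (!all(need %in% names(df))) {
    stop("not a curated panel CSV (need columns ",
         paste(need, collapse = ", "), ")", call. = FALSE)
  }
  df$activity <- as.integer(df$activity)
  new_panel_table(df, character())
}
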