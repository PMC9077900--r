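# The prediction branch: load a trained model set, curate and fingerprint
# input structures, and emit the off-target profile with applicability-
# domain annotation. Prediction uses exactly the same curation and
# featurization path as training, so a training-set structure reproduces its
# training-time fitted probability bit for bit.

#' Predict the off-target profile of input structures
#'
#' Scores every valid input structure against every target model of a fitted
#' panel (an `offtarget_panel_fit` or a directory loaded with
#' [load_panel_models()]). Invalid SMILES produce rejection records with the
#' failure reason, never a failure of the whole call. Each prediction
#' carries the bounding-box applicability-domain flag of its target's
#' training compounds; out-of-domain predictions are flagged as
#' extrapolations but still emitted.
#'
#' @param models an `offtarget_panel_fit` or the result of
#'   [load_panel_models()].
#' @param smiles character vector of SMILES (or data.frame with `id`,
#'   `smiles` columns).
#' @param criterion which retained network model to use (default: the fit's
#'   headline criterion, normally `"best_ba"`); `"rf"` scores with the
#'   Random Forest baseline instead.
#' @return object of class `panel_prediction`: long data.frame with columns
#'   `id`, `smiles`, `canonical_smiles`, `target_id`, `probability`, `call`,
#'   `in_domain`, `violations`; rejected inputs in `attr(, "rejected")`; the
#'   wide probability matrix (compounds x targets) in `attr(, "wide")`.
#' @export
predict_panel <- function(models, smiles, criterion = NULL) {
  if (is.data.frame(smiles)) {
    ids <- as.character(smiles$id %||% seq_len(nrow(smiles)))
    smi <- as.character(smiles$smiles)
  } else {
    ids <- names(smiles) %||% as.character(seq_along(smiles))
    smi <- as.character(smiles)
  }
  set <- as_model_set(models)
  criterion <- criterion %||% set$headline_criterion
  if (!length(set$targets)) stop("no target models found", call. = FALSE)

  proc <- chem_process(smi, fingerprints = TRUE, standardize = TRUE)
  rejected <- data.frame(id = ids[!proc$ok], smiles = smi[!proc$ok],
                         reason = proc$error[!proc$ok],
                         stringsAsFactors = FALSE)
  keep <- which(proc$ok)
  rows <- list()
  wide <- NULL
  if (length(keep)) {
    nbits <- set$input_width
    x <- matrix(0L, length(keep), nbits)
    for (j in seq_along(keep)) {
      x[j, ] <- as.integer(strsplit(proc$fp[keep[j]], "")[[1]])
    }
    desc <- compute_descriptors(proc$canonical_smiles[keep])
    wide <- matrix(NA_real_, length(keep), length(set$targets),
                   dimnames = list(ids[keep], names(set$targets)))
    for (tg in names(set$targets)) {
      entry <- set$targets[[tg]]
      model <- if (identical(criterion, "rf")) {
        entry$rf
      } else {
        entry$models[[criterion]]
      }
      if (is.null(model)) {
        warning("no '", criterion, "' model for target ", tg, "; skipped",
                call. = FALSE)
        next
      }
      p <- predict(model, x)
      dom <- if (!is.null(entry$domain_box)) {
        in_domain(entry$domain_box, desc)
      } else {
        data.frame(in_domain = NA, violations = "")
      }
      rows[[tg]] <- data.frame(
        id = ids[keep], smiles = smi[keep],
        canonical_smiles = proc$canonical_smiles[keep],
        target_id = tg, probability = p,
        call = as.integer(p >= 0.5),
        in_domain = dom$in_domain, violations = dom$violations,
        stringsAsFactors = FALSE
      )
      wide[, tg] <- p
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), smiles = character(),
               canonical_smiles = character(), target_id = character(),
               probability = numeric(), call = integer(),
               in_domain = logical(), violations = character())
  rownames(out) <- NULL
  structure(out, rejected = rejected, wide = wide,
            class = c("panel_prediction", "data.frame"))
}

#' @export
print.panel_prediction <- function(x, ...) {
  cat("Off-target panel prediction: ",
      length(unique(x$id)), " compound(s) x ",
      length(unique(x$target_id)), " target(s)\n", sep = "")
  rej <- attr(x, "rejected")
  if (nrow(rej)) {
    cat("Rejected inputs:\n")
    print(rej, row.names = FALSE)
  }
  print.data.frame(utils::head(as.data.frame(x), 12), digits = 3)
  invisible(x)
}

# normalize an offtarget_panel_fit / loaded model set to a common shape
as_model_set <- function(models) {
  if (inherits(models, "offtarget_panel_fit")) {
    targets <- lapply(models$targets, function(e) {
      list(models = e$nn$models, rf = e$rf, domain_box = e$domain_box)
    })
    list(targets = targets,
         headline_criterion = models$headline_criterion,
         input_width = models$targets[[1]]$nn$models$best_ba$input_width %||%
           models$targets[[1]]$rf$input_width)
  } else if (inherits(models, "panel_model_set")) {
    models
  } else {
    stop("models must be an offtarget_panel_fit or load_panel_models() result",
         call. = FALSE)
  }
}

#' Persist / load a target's retained models
#'
#' `save_bundle` writes one directory per model bundle: the three retained
#' networks as serialized weight files plus `manifest.json` recording the
#' hyperparameters, seeds, selection metrics, split checksum, feature width,
#' per-file integrity checksums and package version (and, when given, the
#' target's applicability-domain box). `load_bundle` reverses it, refusing
#' bundles whose weight files fail their checksum or whose feature width
#' disagrees with the manifest.
#'
#' @param bundle a `model_bundle` from [tune_nn()] / [select_models()].
#' @param dir output directory (created).
#' @param target_id stored in the manifest.
#' @param domain_box optional `domain_box` to store alongside.
#' @param rf optional `offpanel_rf` baseline to store alongside.
#' @return `save_bundle` returns `dir` invisibly; `load_bundle` returns a
#'   list with `models`, `rf`, `domain_box`, `manifest`.
#' @export
save_bundle <- function(bundle, dir, target_id = NA_character_,
                        domain_box = NULL, rf = NULL) {
  stopifnot(inherits(bundle, "model_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (cr in names(bundle$models)) {
    f <- paste0("nn_", cr, ".rds")
    saveRDS(bundle$models[[cr]], file.path(dir, f))
    files[[cr]] <- list(file = f, checksum = file_checksum(file.path(dir, f)))
  }
  if (!is.null(rf)) {
    saveRDS(rf, file.path(dir, "rf.rds"))
    files[["rf"]] <- list(file = "rf.rds",
                          checksum = file_checksum(file.path(dir, "rf.rds")))
  }
  manifest <- list(
    target_id = target_id,
    input_width = bundle$models$best_ba$input_width,
    split_checksum = bundle$split_checksum,
    selection = bundle$manifest,
    files = files,
    domain_box = if (!is.null(domain_box)) as.data.frame(domain_box),
    package_version = as.character(utils::packageVersion("offpanel"))
  )
  write_json_file(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

file_checksum <- function(path) {
  unname(tools::md5sum(path))
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) {
    stop("no manifest.json in ", dir, call. = FALSE)
  }
  manifest <- read_json_file(mf_path)
  models <- list()
  rf <- NULL
  for (nm in names(manifest$files)) {
    entry <- manifest$files[[nm]]
    path <- file.path(dir, entry$file)
    if (!file.exists(path)) stop("missing weight file ", entry$file,
                                 call. = FALSE)
    if (!identical(file_checksum(path), entry$checksum)) {
      stop("checksum mismatch for ", entry$file, " - bundle corrupted",
           call. = FALSE)
    }
    obj <- readRDS(path)
    if (nm == "rf") {
      rf <- obj
    } else {
      if (!identical(obj$input_width, as.integer(manifest$input_width))) {
        stop("feature width in ", entry$file, " (", obj$input_width,
             ") disagrees with the manifest (", manifest$input_width, ")",
             call. = FALSE)
      }
      models[[nm]] <- obj
    }
  }
  box <- NULL
  if (!is.null(manifest$domain_box)) {
    box <- as.data.frame(manifest$domain_box)
    class(box) <- c("domain_box", "data.frame")
  }
  list(models = models, rf = rf, domain_box = box, manifest = manifest)
}

#' Persist / load a whole fitted panel
#'
#' One subdirectory per target (see [save_bundle()]); the loaded set is
#' directly usable with [predict_panel()].
#'
#' @param fit an `offtarget_panel_fit`.
#' @param dir output directory.
#' @return `save_panel_models` returns `dir` invisibly; `load_panel_models`
#'   returns a `panel_model_set`.
#' @export
save_panel_models <- function(fit, dir) {
  stopifnot(inherits(fit, "offtarget_panel_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tg in names(fit$targets)) {
    e <- fit$targets[[tg]]
    save_bundle(e$nn, file.path(dir, tg), target_id = tg,
                domain_box = e$domain_box, rf = e$rf)
  }
  write_json_file(list(
    targets = names(fit$targets),
    headline_criterion = fit$headline_criterion,
    seed = fit$seed
  ), file.path(dir, "panel.json"))
  invisible(dir)
}

#' @rdname save_panel_models
#' @export
load_panel_models <- function(dir) {
  meta_path <- file.path(dir, "panel.json")
  if (!file.exists(meta_path)) stop("no panel.json in ", dir, call. = FALSE)
  meta <- read_json_file(meta_path)
  targets <- list()
  width <- NULL
  for (tg in meta$targets) {
    b <- load_bundle(file.path(dir, tg))
    targets[[tg]] <- list(models = b$models, rf = b$rf,
                          domain_box = b$domain_box)
    width <- width %||% b$manifest$input_width
  }
  structure(list(targets = targets,
                 headline_criterion = meta$headline_criterion,
                 input_width = as.integer(width)),
            class = "panel_model_set")
}
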