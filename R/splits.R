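# Reproducible stratified train/validation/test partitioning.
#
# The split contract mirrors the modelling protocol: 80:20 train-pool/test,
# then a stratified 25 %-of-pool validation split, i.e. 60/20/20 overall.
# Per-class counts use largest-remainder rounding so the total matches
# round(n * fraction) while each class deviates by at most one sample.

# per-class holdout counts via largest-remainder rounding
class_holdout_counts <- function(class_n, fraction) {
  total <- round(sum(class_n) * fraction)
  raw <- class_n * fraction
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    order_rem <- order(-(raw - base), -class_n, seq_along(class_n))
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  } else if (rem < 0) {
    order_rem <- order(raw - base, class_n, seq_along(class_n))
    take <- order_rem[seq_len(-rem)]
    base[take] <- base[take] - 1
  }
  as.integer(base)
}

#' Stratified holdout split
#'
#' Splits sample indices into a training pool and a held-out set, preserving
#' the class balance: each class contributes as close to `fraction` of its
#' members as integer rounding allows (largest-remainder correction, so the
#' total held-out size equals `round(n * fraction)`). Deterministic given
#' `seed`.
#'
#' @param labels binary (0/1) label vector.
#' @param fraction held-out fraction (default 0.2).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
#' @examples
#' s <- stratified_split(rep(c(0, 1), c(800, 200)), 0.2, seed = 1)
#' length(s$test)          # 200
#' sum(s$test <= 1000 & s$test > 800)  # 40 actives held out
stratified_split <- function(labels, fraction = 0.2, seed) {
  stopifnot(is.numeric(labels) || is.integer(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab < 2)) {
    stop("cannot stratify: need at least 2 samples in each class ",
         "(single-class or near-empty datasets are unmodelable)",
         call. = FALSE)
  }
  counts <- class_holdout_counts(as.numeric(tab), fraction)
  if (sum(counts) == 0 || sum(counts) == length(labels)) {
    stop("fraction ", fraction, " leaves an empty partition for n = ",
         length(labels), call. = FALSE)
  }
  test_idx <- integer()
  with_seed(seed, {
    for (k in c(0L, 1L)) {
      members <- which(labels == k)
      n_take <- counts[k + 1L]
      if (n_take > 0) {
        test_idx <- c(test_idx, sample(members, n_take))
      }
    }
  })
  test_idx <- sort(test_idx)
  list(train = setdiff(seq_along(labels), test_idx), test = test_idx)
}

#' Stratified validation split of a training pool
#'
#' Carves a stratified random validation set out of the training pool. With
#' the defaults (20 % test, then 25 % of the remaining pool) the overall
#' partition is 60 % training, 20 % validation, 20 % test.
#'
#' @param pool_labels binary labels of the pool samples.
#' @param fraction_of_pool validation fraction of the pool (default 0.25).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `validation`
#'   (positions within the pool).
#' @export
validation_split <- function(pool_labels, fraction_of_pool = 0.25, seed) {
  s <- stratified_split(pool_labels, fraction_of_pool, seed)
  list(train = s$train, validation = s$test)
}

#' Per-target train/validation/test splits for a curated panel
#'
#' Builds a three-way stratified split for every target in the panel. One
#' master seed fans out per-target seeds deterministically (recorded in the
#' result) so per-target splits are independent yet reproducible. Compounds
#' are identified by canonical SMILES, which are unique within a target after
#' curation.
#'
#' @param panel a `panel_table`.
#' @param test_fraction held-out test fraction of each target's dataset
#'   (default 0.2).
#' @param val_fraction validation fraction of the training pool (default
#'   0.25, i.e. 20 % of the full dataset).
#' @param seed master seed.
#' @return object of class `panel_splits`: named list (per target) of lists
#'   with `train`, `validation`, `test` (canonical SMILES vectors), `seed`,
#'   and `checksum`; targets that cannot be stratified are skipped with a
#'   warning.
#' @export
make_splits <- function(panel, test_fraction = 0.2, val_fraction = 0.25,
                        seed) {
  stopifnot(inherits(panel, "panel_table"))
  targets <- sort(unique(panel$target_id))
  seeds <- derive_seeds(seed, max(length(targets), 1))
  out <- list()
  for (i in seq_along(targets)) {
    tg <- targets[i]
    sub <- panel[panel$target_id == tg, , drop = FALSE]
    sp <- tryCatch({
      outer_split <- stratified_split(sub$activity, test_fraction, seeds[i])
      inner <- validation_split(sub$activity[outer_split$train],
                                val_fraction, seeds[i] + 1L)
      list(
        target_id = tg,
        seed = seeds[i],
        train = sub$smiles[outer_split$train][inner$train],
        validation = sub$smiles[outer_split$train][inner$validation],
        test = sub$smiles[outer_split$test]
      )
    }, error = function(e) {
      warning("target ", tg, " skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(sp)) next
    sp$checksum <- split_checksum(sp)
    out[[tg]] <- sp
  }
  structure(out, class = "panel_splits", master_seed = seed)
}

split_checksum <- function(sp) {
  fnv1a_hash(paste(
    sp$target_id, sp$seed,
    paste(sp$train, collapse = ","),
    paste(sp$validation, collapse = ","),
    paste(sp$test, collapse = ","),
    sep = "|"
  ))
}

#' Freeze splits to disk / load frozen splits
#'
#' Frozen splits are the contract that lets every modelling method (neural
#' network, Random Forest) train and be evaluated on identical partitions.
#' The JSON file stores, per target, the seed, the three id sets, and an
#' integrity checksum; `load_splits` refuses files whose checksum does not
#' match the stored ids.
#'
#' @param splits a `panel_splits` object.
#' @param path JSON file path.
#' @return `freeze_splits` returns `path` invisibly; `load_splits` returns a
#'   `panel_splits`.
#' @export
freeze_splits <- function(splits, path) {
  stopifnot(inherits(splits, "panel_splits"))
  payload <- list(
    master_seed = attr(splits, "master_seed"),
    targets = unname(lapply(splits, function(sp) {
      sp[c("target_id", "seed", "train", "validation", "test", "checksum")]
    }))
  )
  write_json_file(payload, path)
  invisible(path)
}

#' @rdname freeze_splits
#' @export
load_splits <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  out <- list()
  for (sp in payload$targets) {
    sp$train <- as.character(unlist(sp$train))
    sp$validation <- as.character(unlist(sp$validation))
    sp$test <- as.character(unlist(sp$test))
    sp$seed <- as.integer(sp$seed)
    if (!identical(split_checksum(sp), sp$checksum)) {
      stop("split checksum mismatch for target ", sp$target_id,
           " - frozen split file corrupted or edited", call. = FALSE)
    }
    out[[sp$target_id]] <- sp
  }
  structure(out, class = "panel_splits",
            master_seed = payload$master_seed)
}

# index triples for a target's rows given its frozen split
split_indices <- function(sp, smiles) {
  list(
    train = match(sp$train, smiles),
    validation = match(sp$validation, smiles),
    test = match(sp$test, smiles)
  )
}
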