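# Synthetic activity panels with the statistical structure of a real
# off-target screening database: 10-50 targets, per-target dataset sizes in
# the hundreds to thousands, hit rates from a fraction of a percent to ~36 %,
# an incompletely populated compound-by-target matrix, and structures shared
# between targets. Activity is generated from planted substructure rules (a
# compound is active on a target when it carries the target's motif
# fragment), so fingerprint-based learners can genuinely recover the signal
# — which is what makes held-out accuracy on these panels a meaningful
# recovery test rather than a fit to noise.

# two-slot ring cores: slot 1 carries the linker + terminal decoration
# (which defines planted activity), slot 2 a secondary ring decoration
synth_cores <- c(
  "c1cc(%s)cc%sc1",        # benzene
  "c1cc(%s)nc%sc1",        # pyridine
  "C1CC(%s)CN%sC1",        # piperidine
  "C1CC(%s)CC%sC1",        # cyclohexane
  "c1c(%s)sc%sc1",         # thiophene
  "c1c(%s)[nH]c%sc1"       # pyrrole
)

synth_linkers <- c("", "C", "CC", "CCC", "OC", "NC", "C(=O)N", "COC", "CNC")

synth_tails <- c("C", "CC", "O", "N", "C(C)C", "OC", "C#N", "Cl", "F",
                 "C(F)(F)F", "c3ccccc3", "c3ccncc3", "S(=O)(=O)N",
                 "C(=O)O", "Br", "C(=O)NC")

# secondary decorations carry their own parentheses ("" = unsubstituted)
synth_decos <- c("", "(C)", "(F)", "(Cl)", "(Br)", "(O)", "(N)", "(OC)",
                 "(CC)", "(OCC)", "(C#N)", "(C(C)C)")

# default planted motifs, cycled over targets
synth_motifs <- c("C(F)(F)F", "S(=O)(=O)N", "c3ccncc3", "C#N", "C(=O)O",
                  "Br")

# equivalent-SMILES pairs appended to libraries as curation fixtures
synth_duplicate_pairs <- list(
  c("CCOc1ccccc1", "c1ccccc1OCC"),
  c("CC(=O)Nc1ccccc1", "c1ccccc1NC(=O)C"),
  c("OCCN1CCCCC1", "C1CCCCN1CCO")
)

assemble_smiles <- function(core, linker, tail, deco) {
  sprintf(core, paste0(linker, tail), deco)
}

#' Generate a synthetic compound library
#'
#' Assembles `n` chemically valid structures from a curated fragment grammar
#' (ring cores, linkers, terminal decorations), deterministic given `seed`.
#' The terminal decoration of each compound is recorded: planted activity
#' rules key on it. When `include_duplicates` is `TRUE` (default) the library
#' ends with a few pairs of differently written but identical structures, as
#' fixtures for duplicate-collapsing curation.
#'
#' @param n library size.
#' @param seed integer seed.
#' @param tail_quota optional named integer vector: minimum number of
#'   compounds whose decoration equals each name (used to make planted hit
#'   rates achievable).
#' @param include_duplicates append the equivalent-SMILES fixture pairs.
#' @return data.frame with columns `compound_id`, `smiles`, `core`,
#'   `linker`, `tail`, `deco`.
#' @export
generate_library <- function(n, seed, tail_quota = NULL,
                             include_duplicates = TRUE) {
  stopifnot(n >= 1)
  dup <- if (include_duplicates && n >= 2 * length(synth_duplicate_pairs)) {
    unlist(synth_duplicate_pairs)
  } else character()
  n_random <- n - length(dup)
  # every compound is a distinct (core, linker, tail, deco) combination,
  # drawn from the seeded-shuffled full grammar, so written SMILES are
  # (near-)unique; a handful of symmetry-equivalent structures remain as
  # natural curation fixtures
  grid <- expand.grid(core = synth_cores, linker = synth_linkers,
                      deco = synth_decos, tail = synth_tails,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- with_seed(seed, grid[sample.int(nrow(grid)), , drop = FALSE])
  take <- logical(nrow(grid))
  if (!is.null(tail_quota)) {
    for (tl in names(tail_quota)) {
      avail <- which(grid$tail == tl & !take)
      if (length(avail) < tail_quota[[tl]]) {
        stop("fragment grammar cannot provide ", tail_quota[[tl]],
             " distinct compounds with decoration '", tl,
             "'; reduce the requested hit counts", call. = FALSE)
      }
      take[avail[seq_len(tail_quota[[tl]])]] <- TRUE
    }
  }
  n_quota <- sum(take)
  if (n_quota > n_random) {
    stop("library of size ", n, " cannot satisfy the requested tail ",
         "quotas (", n_quota, " compounds needed); increase the library ",
         "size", call. = FALSE)
  }
  fill <- which(!take)
  if (n_random - n_quota > length(fill)) {
    stop("library size ", n, " exceeds the fragment grammar (",
         nrow(grid) + length(dup), " distinct structures)", call. = FALSE)
  }
  take[fill[seq_len(n_random - n_quota)]] <- TRUE
  df <- grid[take, , drop = FALSE]
  df <- with_seed(seed + 1L, df[sample.int(nrow(df)), , drop = FALSE])
  df <- data.frame(
    smiles = assemble_smiles(df$core, df$linker, df$tail, df$deco),
    core = df$core, linker = df$linker, tail = df$tail, deco = df$deco,
    stringsAsFactors = FALSE
  )
  if (length(dup)) {
    df <- rbind(df, data.frame(smiles = dup, core = NA_character_,
                               linker = NA_character_, tail = "",
                               deco = NA_character_, stringsAsFactors = FALSE))
  }
  rownames(df) <- NULL
  cbind(data.frame(compound_id = sprintf("CPD%05d", seq_len(nrow(df))),
                   stringsAsFactors = FALSE), df)
}

#' Specify a synthetic panel
#'
#' @param targets data.frame with columns `target_id`, `n` (measured
#'   compounds; may be `NA` when `sparsity` is given), `hit_rate` (fraction
#'   in (0, 1)), and optionally `motif` (terminal decoration defining
#'   activity; defaults cycle through a built-in list).
#' @param noise label-noise rate (default 0.1). Noise flips
#'   `round(noise * n_active)` actives to inactive and the same number of
#'   inactives to active, so the marginal hit rate is preserved exactly while
#'   both classes carry mislabeled samples.
#' @param seed master seed.
#' @param library_size compound-library size (default: sized to the panel's
#'   needs).
#' @param sparsity fraction of library compounds measured per target; used
#'   for targets whose `n` is `NA`.
#' @param inject_invalid number of unparsable-SMILES rows to append (curation
#'   fixtures).
#' @param inject_duplicates number of exact duplicate rows to append
#'   (curation fixtures).
#' @return object of class `panel_spec`.
#' @export
panel_spec <- function(targets, noise = 0.1, seed = 1L, library_size = NULL,
                       sparsity = NULL, inject_invalid = 0L,
                       inject_duplicates = 0L) {
  stopifnot(is.data.frame(targets),
            all(c("target_id", "n", "hit_rate") %in% names(targets)))
  if (!"motif" %in% names(targets)) {
    targets$motif <- rep_len(synth_motifs, nrow(targets))
  }
  if (any(targets$hit_rate <= 0 | targets$hit_rate >= 1, na.rm = TRUE)) {
    stop("hit_rate must lie in (0, 1)", call. = FALSE)
  }
  if (noise < 0 || noise >= 0.5) {
    stop("noise must lie in [0, 0.5)", call. = FALSE)
  }
  structure(list(targets = targets, noise = noise, seed = seed,
                 library_size = library_size, sparsity = sparsity,
                 inject_invalid = as.integer(inject_invalid),
                 inject_duplicates = as.integer(inject_duplicates)),
            class = "panel_spec")
}

#' The six-archetype demonstration panel
#'
#' Mirrors the shapes found in real safety panels: large/high-hit,
#' large/low-hit, small/high-hit, small/low-hit, and two mid-sized cases,
#' at desk scale.
#'
#' @param seed master seed.
#' @param noise label-noise rate.
#' @return a `panel_spec`.
#' @export
demo_panel_spec <- function(seed = 1L, noise = 0.1) {
  panel_spec(
    data.frame(
      target_id = c("T_large_high", "T_large_low", "T_small_high",
                    "T_small_low", "T_mid_a", "T_mid_b"),
      n = c(1000L, 1200L, 300L, 150L, 600L, 600L),
      hit_rate = c(0.36, 0.03, 0.21, 0.04, 0.20, 0.10),
      stringsAsFactors = FALSE
    ),
    noise = noise, seed = seed
  )
}

#' Generate a synthetic activity panel
#'
#' Draws each target's measured compounds from a shared library (so
#' structures recur across targets while the compound-by-target matrix stays
#' incompletely populated), assigns activity by the target's planted motif
#' rule, and applies hit-rate-preserving label noise. The realized hit rate
#' equals `round(hit_rate * n) / n` exactly.
#'
#' @param spec a [panel_spec()].
#' @return list with `rows` (raw panel rows ready for [curate_panel()]),
#'   `library` (the compound library), and `truth` (per-target motif,
#'   measured ids and flipped ids — the ground truth for recovery tests).
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  tg <- spec$targets
  if (any(is.na(tg$n))) {
    if (is.null(spec$sparsity) || is.null(spec$library_size)) {
      stop("targets with n = NA require both sparsity and library_size",
           call. = FALSE)
    }
    tg$n[is.na(tg$n)] <- round(spec$sparsity * spec$library_size)
  }
  tg$n_pos <- round(tg$hit_rate * tg$n)
  if (any(tg$n_pos < 1)) {
    stop("hit rate unachievable for target(s) ",
         paste(tg$target_id[tg$n_pos < 1], collapse = ", "),
         ": fewer than one active; increase n or hit_rate", call. = FALSE)
  }
  quota <- tapply(ceiling(tg$n_pos * 1.3) + 5L, tg$motif, sum)
  lib_needed <- sum(quota) + max(tg$n) + 50L
  lib_size <- spec$library_size %||% lib_needed
  lib <- generate_library(lib_size, spec$seed,
                          tail_quota = stats::setNames(as.integer(quota),
                                                       names(quota)))
  seeds <- derive_seeds(spec$seed + 7L, nrow(tg) + 2L)
  rows <- list()
  truth <- list()
  for (i in seq_len(nrow(tg))) {
    n <- tg$n[i]; n_pos <- tg$n_pos[i]; motif <- tg$motif[i]
    pos_pool <- which(lib$tail == motif)
    neg_pool <- which(lib$tail != motif)
    if (length(pos_pool) < n_pos || length(neg_pool) < n - n_pos) {
      stop("hit rate ", tg$hit_rate[i], " unachievable for target ",
           tg$target_id[i], " with this library; increase library_size",
           call. = FALSE)
    }
    with_seed(seeds[i], {
      take_pos <- sample(pos_pool, n_pos)
      take_neg <- sample(neg_pool, n - n_pos)
      labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))
      idx <- c(take_pos, take_neg)
      k <- round(spec$noise * n_pos)
      k <- min(k, n_pos, n - n_pos)
      flip_pos <- if (k > 0) sample(seq_len(n_pos), k) else integer()
      flip_neg <- if (k > 0) n_pos + sample(seq_len(n - n_pos), k) else integer()
      labels[flip_pos] <- 0L
      labels[flip_neg] <- 1L
      ord <- sample.int(n)
      rows[[i]] <- data.frame(
        compound_id = lib$compound_id[idx][ord],
        smiles = lib$smiles[idx][ord],
        target_id = tg$target_id[i],
        activity = labels[ord],
        provenance = "synthetic",
        stringsAsFactors = FALSE
      )
      truth[[tg$target_id[i]]] <- list(
        motif = motif,
        n = n, n_active = n_pos,
        measured = lib$compound_id[idx],
        rule_active = lib$compound_id[take_pos],
        flipped = lib$compound_id[idx][c(flip_pos, flip_neg)]
      )
    })
  }
  out <- do.call(rbind, rows)
  if (spec$inject_invalid > 0) {
    out <- rbind(out, data.frame(
      compound_id = sprintf("BAD%03d", seq_len(spec$inject_invalid)),
      smiles = rep_len(c("C1CC", "c1ccccc", "X[Qq]"), spec$inject_invalid),
      target_id = tg$target_id[1],
      activity = 0L, provenance = "synthetic", stringsAsFactors = FALSE
    ))
  }
  if (spec$inject_duplicates > 0) {
    dup <- with_seed(seeds[nrow(tg) + 1L],
                     out[sample.int(nrow(out),
                                    min(spec$inject_duplicates, nrow(out))), ,
                         drop = FALSE])
    out <- rbind(out, dup)
  }
  rownames(out) <- NULL
  list(rows = out, library = lib, truth = truth)
}

#' Permute labels within each target
#'
#' Permutation-null fixture: per-target random permutation of the activity
#' labels, preserving each target's marginal hit rate exactly. A model
#' trained on a shuffled panel should score a held-out balanced accuracy
#' near 0.5.
#'
#' @param table a `panel_table` (or data.frame with `target_id`,
#'   `activity`).
#' @param seed integer seed.
#' @return the table with permuted labels (same class).
#' @export
shuffle_labels <- function(table, seed) {
  seeds <- derive_seeds(seed, length(unique(table$target_id)))
  targets <- sort(unique(table$target_id))
  for (i in seq_along(targets)) {
    sel <- which(table$target_id == targets[i])
    table$activity[sel] <- with_seed(seeds[i],
                                     sample(table$activity[sel]))
  }
  table
}
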