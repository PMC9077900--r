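#' @keywords internal
"_PACKAGE"

# package-local state: chemistry cache, backend probe result
.offpanel <- new.env(parent = emptyenv())

`%||%` <- function(x, y) if (is.null(x)) y else x

#' FNV-1a hash of a character string
#'
#' 32-bit Fowler-Noll-Vo hash, returned as an 8-character hexadecimal string.
#' Used as a lightweight integrity checksum on frozen splits and persisted
#' model bundles; it is not cryptographic.
#'
#' @param x a character scalar (multi-element inputs are collapsed with `\\n`).
#' @return an 8-character hex string.
#' @export
#' @examples
#' fnv1a_hash("T1:CCO,c1ccccc1")
fnv1a_hash <- function(x) {
  x <- paste(x, collapse = "\n")
  fnv1a_bytes(as.integer(charToRaw(enc2utf8(x))))
}

# FNV-1a over integer byte values. The 32-bit state is kept as two 16-bit
# halves so the xor can use R's integer bitwXor and the modular multiply
# stays within exact double precision.
fnv1a_bytes <- function(bytes) {
  hi <- 33052   # 0x811C
  lo <- 40389   # 0x9DC5
  for (b in bytes) {
    lo <- bitwXor(lo, b)
    tot <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
    hi <- tot %/% 65536
    lo <- tot %% 65536
  }
  sprintf("%04x%04x", hi, lo)
}

#' Derive reproducible child seeds from a master seed
#'
#' Fans one master seed out into `n` independent 31-bit seeds, so that
#' per-target stages (splitting, grid sampling, weight initialization) are
#' individually reproducible while being driven by a single configuration
#' value.
#'
#' @param seed master seed (integer).
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 1]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# evaluate expr with a local, seeded RNG stream; global stream untouched
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}

op_warning <- function(...) {
  msg <- paste0(...)
  warning(msg, call. = FALSE)
  msg
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
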