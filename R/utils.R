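#' @keywords internal
"_PACKAGE"

## Small internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Spawn a deterministic schedule of child seeds from one master seed
#'
#' Assays that interleave conditions (e.g. the two CRPs of the flexibility
#' protocol) reuse the same per-trial seed schedule across conditions so that
#' noise draws are matched trial-for-trial.
#'
#' @param master_seed single non-negative integer.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
spawn_seeds <- function(master_seed, n) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed), n >= 0)
  with_seed(as.integer(master_seed), sample.int(.Machine$integer.max - 1L, n))
}

# Polynomial hash (mod 2^31 - 1) of a character scalar, hex-formatted.
# Used for provenance stamps only.
str_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Canonical JSON text of a (config-like) list: sorted names, stable digits.
canonical_json <- function(x) {
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v)) && length(v) > 0) {
      v <- v[order(names(v))]
      lapply(v, sort_rec)
    } else if (is.list(v)) {
      lapply(v, sort_rec)
    } else {
      v
    }
  }
  as.character(jsonlite::toJSON(sort_rec(x), auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
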