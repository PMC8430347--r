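#' Canonicalize gene symbols
#'
#' Upper-cases and whitespace-strips identifiers. Exact-string matching only:
#' no alias resolution is attempted.
#'
#' @param x character vector of gene symbols.
#' @return character vector of canonical symbols.
#' @export
canonical_symbol <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Canonical key of an undirected edge
#'
#' Endpoints sorted lexicographically and tab-joined, so edge sets from
#' different networks are comparable as character vectors.
#'
#' @param a,b endpoint identifier vectors (recycled).
#' @return character vector of canonical keys.
#' @export
edge_key <- function(a, b) {
  swap <- b < a
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste(lo, hi, sep = "\t")
}

## Deterministic 32-bit sub-seed derived from a base seed and a stream name,
## so adding a generator never shifts the RNG stream of another.
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483629
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% m
  as.integer((h + (seed %% m) * 7919) %% m)
}

## Run `expr` under a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

## log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
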