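## Multi-source gene-list integration and convergent-evidence scoring.
##
## A curated gene panel is assembled from several independent evidence
## sources (association studies, phenotype databases, functional annotation,
## literature, expression signatures). Genes backed by at least `k` sources
## are retained and ranked by the convergent evidence score
## CES(g) = (number of sources listing g) / (number of sources).

#' Integrate per-source gene lists into a source-membership table
#'
#' Symbols are canonicalized ([canonical_symbol()]), duplicates within and
#' across sources are collapsed, and per-source presence is recorded as a
#' logical membership matrix (genes x sources).
#'
#' @param lists named list of character vectors, one per evidence source.
#' @return a `source_membership` object: a logical matrix with one row per
#'   unique gene (lexicographic order) and one column per source.
#' @export
integrate_sources <- function(lists) {
  if (!is.list(lists) || length(lists) == 0L) {
    stop("`lists` must be a non-empty named list of gene vectors")
  }
  if (is.null(names(lists)) || anyNA(names(lists)) || any(names(lists) == "")) {
    stop("every source must be named")
  }
  clean <- lapply(lists, function(x) {
    x <- canonical_symbol(x)
    unique(x[!is.na(x) & nzchar(x)])
  })
  genes <- sort(unique(unlist(clean, use.names = FALSE)))
  if (length(genes) == 0L) stop("empty input: no genes in any source")
  m <- vapply(clean, function(x) genes %in% x, logical(length(genes)))
  m <- matrix(m, nrow = length(genes), dimnames = list(genes, names(lists)))
  structure(m, class = c("source_membership", "matrix"))
}

#' @export
print.source_membership <- function(x, ...) {
  cat(sprintf("source_membership: %d genes x %d sources (%d entries)\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

n_sources_per_gene <- function(table) {
  stopifnot(inherits(table, "source_membership"))
  rowSums(unclass(table))
}

#' Filter a membership table to genes present in at least k sources
#'
#' @param table a `source_membership` object.
#' @param k minimum number of supporting sources (default 2, the panel
#'   selection rule).
#' @return a `source_membership` with the same source columns, restricted to
#'   genes with >= k set entries. `k` larger than the number of sources
#'   yields an empty table with a warning.
#' @export
filter_min_sources <- function(table, k = 2L) {
  stopifnot(inherits(table, "source_membership"), k >= 1)
  if (k > ncol(table)) {
    warning(sprintf("k = %d exceeds the number of sources (%d); empty table",
                    k, ncol(table)))
  }
  keep <- n_sources_per_gene(table) >= k
  structure(unclass(table)[keep, , drop = FALSE],
            class = c("source_membership", "matrix"))
}

#' Compute convergent evidence scores and rank a gene panel
#'
#' CES(g) = (sources listing g) / (total sources); genes are ranked by
#' descending CES with ties broken by ascending symbol, so ranking is
#' deterministic and invariant to source ordering.
#'
#' @param table a non-empty `source_membership` object.
#' @return a `gene_catalog` data frame with columns `gene`, `n_sources`,
#'   `ces`, `rank`, ordered by rank.
#' @export
compute_ces <- function(table) {
  stopifnot(inherits(table, "source_membership"))
  if (nrow(table) == 0L) stop("empty membership table")
  ns <- n_sources_per_gene(table)
  ces <- ns / ncol(table)
  ord <- order(-ces, names(ns))
  out <- data.frame(gene = names(ns)[ord],
                    n_sources = as.integer(ns[ord]),
                    ces = ces[ord],
                    rank = seq_along(ns),
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_catalog", "data.frame")
  out
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("gene_catalog: %d genes, CES in [%.4f, %.4f]\n",
              nrow(x), min(x$ces), max(x$ces)))
  print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}
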