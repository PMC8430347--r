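## Gene-set over-representation analysis: hypergeometric upper-tail
## p-values (computed in log space), Bonferroni correction, gene-ratio
## statistics, and cross-context intersection of significant terms.

#' Construct an annotation database of flat gene sets
#'
#' @param terms named list of character vectors (term members); every member
#'   must lie in `background` and no term may be empty.
#' @param background character vector: the annotation universe.
#' @param descriptions optional named character vector of term descriptions.
#' @return an `annotation_db` list with `terms`, `descriptions`, `background`.
#' @export
annotation_db <- function(terms, background, descriptions = NULL) {
  stopifnot(is.list(terms), !is.null(names(terms)))
  background <- unique(canonical_symbol(background))
  terms <- lapply(terms, function(g) unique(canonical_symbol(g)))
  if (any(lengths(terms) == 0L)) stop("empty annotation term")
  stray <- !vapply(terms, function(g) all(g %in% background), TRUE)
  if (any(stray)) {
    stop(sprintf("term(s) with members outside the background: %s",
                 paste(utils::head(names(terms)[stray], 5L), collapse = ", ")))
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(terms), names(terms))
  }
  structure(list(terms = terms,
                 descriptions = descriptions[names(terms)],
                 background = background),
            class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  cat(sprintf("annotation_db: %d terms over %d background genes (sizes %d-%d)\n",
              length(x$terms), length(x$background),
              min(lengths(x$terms)), max(lengths(x$terms))))
  invisible(x)
}

#' Restrict an annotation database to a smaller background
#'
#' Used when the effective universe of a context (e.g. the nodes of one
#' species' interactome) is a subset of the full annotation universe. Terms
#' that become empty are dropped.
#'
#' @param db an `annotation_db`.
#' @param background the restricted universe (intersected with the current
#'   one).
#' @return an `annotation_db`.
#' @export
restrict_background <- function(db, background) {
  stopifnot(inherits(db, "annotation_db"))
  bg <- intersect(db$background, unique(canonical_symbol(background)))
  terms <- lapply(db$terms, function(g) intersect(g, bg))
  keep <- lengths(terms) > 0L
  annotation_db(terms[keep], bg, db$descriptions[keep])
}

#' Hypergeometric upper-tail p-value for over-representation
#'
#' `P(X >= k)` where `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` containing `K` term members. Computed by log-space
#' summation of the tail probability mass for numerical stability. All
#' arguments are vectorized (recycled).
#'
#' @param k observed intersection size, `0 <= k <= min(n, K)`.
#' @param n query (draw) size.
#' @param K term size.
#' @param N background (universe) size.
#' @param log_p return log p-values instead.
#' @return numeric vector of p-values.
#' @export
hypergeom_pvalue <- function(k, n, K, N, log_p = FALSE) {
  args <- cbind(k = k, n = n, K = K, N = N)  # recycles
  k <- args[, "k"]; n <- args[, "n"]; K <- args[, "K"]; N <- args[, "N"]
  if (any(k < 0 | n < 0 | K < 0 | N < 0 | n > N | K > N | k > pmin(n, K))) {
    stop("impossible hypergeometric configuration: need 0 <= k <= min(n, K), n <= N, K <= N")
  }
  lp <- vapply(seq_along(k), function(i) {
    kk <- k[i]; nn <- n[i]; KK <- K[i]; NN <- N[i]
    if (kk == 0) return(0)  # P(X >= 0) = 1
    j <- seq.int(kk, min(nn, KK))
    logsumexp(lchoose(KK, j) + lchoose(NN - KK, nn - j) - lchoose(NN, nn))
  }, numeric(1))
  lp <- pmin(lp, 0)
  if (log_p) lp else exp(lp)
}

#' Over-representation analysis of a gene panel
#'
#' Tests each annotation term for over-representation in `query` with the
#' hypergeometric upper-tail test and applies Bonferroni correction over the
#' number of tested terms. Query genes outside the background are dropped
#' with a warning.
#'
#' @param query character vector of gene symbols.
#' @param db an `annotation_db`.
#' @param alpha significance level on the adjusted p-value (0 < alpha < 1).
#' @return an `enrichment_result` data frame (one row per term, sorted by
#'   `p_adj` then `term_id`) with columns `term_id`, `description`, `k`
#'   (intersection), `n` (effective query), `K` (term size), `N`
#'   (background), `p_raw`, `p_adj`, `gene_ratio` (= k/K), `significant`,
#'   `hits` (`;`-joined intersection). Attributes record `alpha`, the
#'   background size and the test direction (upper-tail over-representation).
#' @export
enrich <- function(query, db, alpha = 0.05) {
  stopifnot(inherits(db, "annotation_db"), alpha > 0, alpha < 1)
  query <- unique(canonical_symbol(query))
  outside <- setdiff(query, db$background)
  if (length(outside) > 0L) {
    warning(sprintf("%d query gene(s) outside the background were dropped",
                    length(outside)))
  }
  query <- intersect(query, db$background)
  if (length(query) == 0L) stop("no query genes remain within the background")
  m <- length(db$terms)
  N <- length(db$background)
  n <- length(query)
  hits <- lapply(db$terms, intersect, query)
  k <- lengths(hits)
  K <- lengths(db$terms)
  p_raw <- hypergeom_pvalue(k, n, K, N)
  p_adj <- pmin(1, p_raw * m)
  out <- data.frame(term_id = names(db$terms),
                    description = as.character(db$descriptions),
                    k = as.integer(k), n = n, K = as.integer(K), N = N,
                    p_raw = p_raw, p_adj = p_adj,
                    gene_ratio = k / K,
                    significant = p_adj < alpha,
                    hits = vapply(hits, function(h) paste(sort(h), collapse = ";"), ""),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "background_size") <- N
  attr(out, "test") <- "hypergeometric upper tail (over-representation), Bonferroni"
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Terms significant in every context, and per-context exclusive terms
#'
#' @param results_by_context named list (>= 2) of [enrich()] results.
#' @param alpha significance level applied to `p_adj` in every context.
#' @return list with `common` (character vector of term ids significant in
#'   all contexts), `exclusive` (named list: terms significant in exactly
#'   that one context), and `table` (logical significance matrix, terms x
#'   contexts).
#' @export
common_enriched <- function(results_by_context, alpha = 0.05) {
  stopifnot(is.list(results_by_context), length(results_by_context) >= 2L,
            !is.null(names(results_by_context)))
  sig_sets <- lapply(results_by_context, function(r) {
    r$term_id[r$p_adj < alpha]
  })
  all_terms <- sort(unique(unlist(lapply(results_by_context, `[[`, "term_id"))))
  tab <- vapply(sig_sets, function(s) all_terms %in% s, logical(length(all_terms)))
  tab <- matrix(tab, nrow = length(all_terms),
                dimnames = list(all_terms, names(results_by_context)))
  common <- all_terms[rowSums(tab) == ncol(tab)]
  exclusive <- lapply(seq_along(sig_sets), function(i) {
    all_terms[tab[, i] & rowSums(tab) == 1L]
  })
  names(exclusive) <- names(results_by_context)
  list(common = common, exclusive = exclusive, table = tab)
}
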