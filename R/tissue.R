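## Tissue-specific subnetworks: protein-expression-filtered induced
## subgraphs of a local PPI network, the conserved inter-tissue edge
## module, and expression/topology association with permutation p-values.

PROTEIN_LEVELS <- c(negative = 0L, weak = 1L, moderate = 2L, high = 3L)

#' Numeric codes of ordinal protein expression levels
#'
#' `negative = 0 < weak = 1 < moderate = 2 < high = 3`.
#'
#' @param level character vector of level names (or numeric codes, returned
#'   unchanged).
#' @return integer codes; NA for missing levels.
#' @export
protein_level_code <- function(level) {
  if (is.numeric(level)) return(as.integer(level))
  unname(PROTEIN_LEVELS[match(tolower(as.character(level)), names(PROTEIN_LEVELS))])
}

#' Construct an expression profile table
#'
#' @param df data frame with columns `gene`, `tissue`, `tpm` (finite,
#'   >= 0 transcript abundance) and `protein_level` (one of
#'   negative/weak/moderate/high, or NA for missing).
#' @return an `expression_profile` data frame.
#' @export
expression_profile <- function(df) {
  stopifnot(all(c("gene", "tissue", "tpm", "protein_level") %in% names(df)))
  df$gene <- canonical_symbol(df$gene)
  df$tissue <- as.character(df$tissue)
  df$tpm <- as.numeric(df$tpm)
  if (any(!is.finite(df$tpm)) || any(df$tpm < 0)) stop("tpm must be finite and >= 0")
  lv <- tolower(as.character(df$protein_level))
  bad <- !is.na(lv) & !(lv %in% names(PROTEIN_LEVELS))
  if (any(bad)) stop("unknown protein level(s): ", paste(unique(lv[bad]), collapse = ", "))
  df$protein_level <- lv
  if (anyDuplicated(paste(df$gene, df$tissue))) stop("duplicate (gene, tissue) rows")
  rownames(df) <- NULL
  structure(df[, c("gene", "tissue", "tpm", "protein_level")],
            class = c("expression_profile", "data.frame"))
}

expr_tissues <- function(expr) unique(expr$tissue)

tissue_slice <- function(expr, tissue) {
  if (!tissue %in% expr$tissue) {
    stop(sprintf("unknown tissue '%s' (available: %s)", tissue,
                 paste(expr_tissues(expr), collapse = ", ")))
  }
  expr[expr$tissue == tissue, , drop = FALSE]
}

#' Build a tissue-specific subnetwork by protein-expression filtering
#'
#' Keeps the nodes whose protein level in `tissue` is at least `min_level`
#' (default `"weak"`: any detected expression) and takes the induced
#' subgraph of the local PPI network on them.
#'
#' @param local_ppin an `interactome` (the gene panel's local PPI network).
#' @param expr an `expression_profile` covering `tissue`.
#' @param tissue tissue name.
#' @param min_level minimum ordinal level (name or code) for node inclusion.
#' @return a `tissue_network` list: `tissue`, `graph` (an `interactome`),
#'   `min_level` (integer code).
#' @export
build_tissue_network <- function(local_ppin, expr, tissue, min_level = "weak") {
  stopifnot(inherits(local_ppin, "interactome"), inherits(expr, "expression_profile"))
  min_code <- protein_level_code(min_level)
  stopifnot(length(min_code) == 1L, !is.na(min_code))
  sl <- tissue_slice(expr, tissue)
  code <- protein_level_code(sl$protein_level)
  keep <- sl$gene[!is.na(code) & code >= min_code]
  graph <- induced_subgraph(local_ppin, keep, name = paste0(local_ppin$name, "::", tissue))
  structure(list(tissue = tissue, graph = graph, min_level = min_code),
            class = "tissue_network")
}

#' @export
print.tissue_network <- function(x, ...) {
  cat(sprintf("tissue_network '%s' (min level %d): %d nodes, %d edges\n",
              x$tissue, x$min_level, length(x$graph$nodes), nrow(x$graph$edges)))
  invisible(x)
}

#' Conserved edge module across tissue (or other context) networks
#'
#' The module is defined on edges: its edge set is the intersection of all
#' input networks' edge sets, and its node set is the endpoints of the
#' surviving edges (a gene present in every network but without a conserved
#' interaction is excluded).
#'
#' @param nets list (>= 2) of `tissue_network`s or `interactome`s over a
#'   shared identifier namespace.
#' @param name name of the resulting module network.
#' @return an `interactome` containing only the conserved edges.
#' @export
conserved_module <- function(nets, name = "conserved_module") {
  stopifnot(is.list(nets), length(nets) >= 2L)
  graphs <- lapply(nets, function(x) {
    if (inherits(x, "tissue_network")) x$graph
    else if (inherits(x, "interactome")) x
    else stop("inputs must be tissue_network or interactome objects")
  })
  keys <- Reduce(intersect, lapply(graphs, edge_keys))
  e1 <- graphs[[1L]]$edges
  keep <- e1[edge_key(e1$a, e1$b) %in% keys, , drop = FALSE]
  new_interactome(unique(c(keep$a, keep$b)), keep, name)
}

## Average-rank Spearman correlation; NA (with reason) when either side is
## constant.
spearman_or_na <- function(x, y) {
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  stats::cor(rank(x), rank(y))
}

perm_pvalue <- function(obs, perm) {
  if (is.na(obs)) return(NA_real_)
  (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (length(perm) + 1)
}

#' Association between expression and network position
#'
#' Rank (Spearman, average-rank ties) correlations between a node's degree
#' and (a) its ordinal protein level, (b) its transcript abundance, in one
#' tissue network, with two-sided permutation p-values (expression labels
#' permuted across nodes).
#'
#' @param net a `tissue_network`.
#' @param expr an `expression_profile` covering the network's tissue.
#' @param metrics topology metrics of `net$graph` from [compute_topology()];
#'   computed if `NULL`.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @return data frame with one row per comparison (`protein_vs_degree`,
#'   `tpm_vs_degree`): `rho`, `p_perm`, `n`, `note` (NA correlations carry
#'   the reason, e.g. a constant expression column).
#' @export
expression_vs_topology <- function(net, expr, metrics = NULL, n_perm = 10000L,
                                   seed = 1L) {
  stopifnot(inherits(net, "tissue_network"), inherits(expr, "expression_profile"))
  if (is.null(metrics)) metrics <- compute_topology(net$graph)
  sl <- tissue_slice(expr, net$tissue)
  sl <- sl[match(metrics$node, sl$gene), , drop = FALSE]
  ok <- !is.na(sl$gene)
  metrics <- metrics[ok, , drop = FALSE]; sl <- sl[ok, , drop = FALSE]
  n <- nrow(metrics)
  if (n < 3L) stop("insufficient data: need >= 3 nodes with expression")
  deg_rank <- rank(metrics$degree)
  one <- function(x, label) {
    obs <- spearman_or_na(x, metrics$degree)
    if (is.na(obs)) {
      return(data.frame(comparison = label, rho = NA_real_, p_perm = NA_real_,
                        n = n, note = "constant input: correlation undefined",
                        stringsAsFactors = FALSE))
    }
    xr <- rank(x)
    perm <- with_seed(seed, {
      idx <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
      ## Spearman of permuted x-ranks against fixed degree ranks
      xc <- xr - mean(xr); dc <- deg_rank - mean(deg_rank)
      denom <- sqrt(sum(xc^2) * sum(dc^2))
      as.numeric(crossprod(matrix(xc[idx], nrow = n), dc)) / denom
    })
    data.frame(comparison = label, rho = obs, p_perm = perm_pvalue(obs, perm),
               n = n, note = NA_character_, stringsAsFactors = FALSE)
  }
  rbind(one(protein_level_code(sl$protein_level), "protein_vs_degree"),
        one(sl$tpm, "tpm_vs_degree"))
}

#' Rank correlation between transcript and protein level in a tissue
#'
#' Spearman correlation (average-rank ties) between transcript abundance
#' and the ordinal protein level over the genes measured on both scales.
#'
#' @param expr an `expression_profile`.
#' @param tissue tissue name.
#' @return a single correlation; NA with a `"note"` attribute when one side
#'   is constant. Fewer than 3 complete pairs is an error.
#' @export
mrna_protein_correlation <- function(expr, tissue) {
  stopifnot(inherits(expr, "expression_profile"))
  sl <- tissue_slice(expr, tissue)
  code <- protein_level_code(sl$protein_level)
  ok <- !is.na(code) & is.finite(sl$tpm)
  if (sum(ok) < 3L) stop("insufficient data: need >= 3 genes with both measurements")
  rho <- spearman_or_na(sl$tpm[ok], code[ok])
  if (is.na(rho)) attr(rho, "note") <- "constant input: correlation undefined"
  rho
}
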