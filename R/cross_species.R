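## Cross-species pathway conservation: presence/absence of a pathway's
## genes in each species' interactome, and "rewiring" of the
## pathway-induced subnetworks quantified by edge Jaccard after translating
## edges through the 1:1 ortholog map back to reference identifiers.

#' Presence matrix of a pathway's genes across species interactomes
#'
#' A gene is present in a species iff it has a 1:1 ortholog there AND that
#' ortholog is a node of the species' interactome.
#'
#' @param pathway_genes non-empty character vector of reference-species
#'   gene symbols.
#' @param map an `ortholog_map`.
#' @param species_nets named list of `interactome`s, one per species, in the
#'   species' own identifier namespace; names must be species in `map`.
#' @return logical matrix (pathway genes x species) with per-species totals
#'   in attribute `totals`.
#' @export
pathway_presence <- function(pathway_genes, map, species_nets) {
  stopifnot(length(pathway_genes) >= 1L, inherits(map, "ortholog_map"),
            is.list(species_nets), !is.null(names(species_nets)))
  if (!all(names(species_nets) %in% map_species(map))) {
    stop("species_nets names must be species of the ortholog map")
  }
  genes <- unique(canonical_symbol(pathway_genes))
  pres <- vapply(names(species_nets), function(sp) {
    lk <- species_lookup(map, sp)
    orth <- lk[genes]
    !is.na(orth) & orth %in% species_nets[[sp]]$nodes
  }, logical(length(genes)))
  pres <- matrix(pres, nrow = length(genes),
                 dimnames = list(genes, names(species_nets)))
  attr(pres, "totals") <- colSums(pres)
  pres
}

## Translate a species subgraph's edges back to reference-species gene
## pairs through the (1:1) ortholog map. Edges with an untranslatable
## endpoint are excluded and counted.
translate_edges <- function(net, map, species) {
  lk <- species_lookup(map, species)
  present <- !is.na(lk)
  rev_lk <- stats::setNames(names(lk)[present], lk[present])
  if (nrow(net$edges) == 0L) {
    return(list(keys = character(0), excluded = 0L))
  }
  a_ref <- rev_lk[net$edges$a]
  b_ref <- rev_lk[net$edges$b]
  ok <- !is.na(a_ref) & !is.na(b_ref)
  list(keys = unique(edge_key(a_ref[ok], b_ref[ok])), excluded = sum(!ok))
}

#' Compare pathway-induced subgraphs across species
#'
#' For each species, the subgraph of its interactome induced by the
#' ortholog-mapped pathway members is extracted; edges are translated back
#' to reference identifiers, and every species pair is compared by edge
#' Jaccard index. Low Jaccard between species whose pathway members largely
#' overlap indicates rewiring of the pathway's interactions.
#'
#' @inheritParams pathway_presence
#' @return a `rewiring_report` list: `jaccard` (symmetric matrix;
#'   self-comparison is 1 when the subgraph has >= 1 edge, NA otherwise),
#'   `shared_edges` (pairwise shared translated-edge counts), `edge_counts`
#'   (per species), `excluded_edges` (per species, edges lost to missing
#'   1:1 translation), `edge_sets` (translated canonical edge keys).
#' @export
compare_pathway_subgraphs <- function(pathway_genes, map, species_nets) {
  stopifnot(is.list(species_nets), length(species_nets) >= 2L)
  genes <- unique(canonical_symbol(pathway_genes))
  sets <- list(); excluded <- integer(length(species_nets))
  names(excluded) <- names(species_nets)
  for (sp in names(species_nets)) {
    lk <- species_lookup(map, sp)
    members <- lk[genes]
    members <- members[!is.na(members)]
    sub <- induced_subgraph(species_nets[[sp]], members,
                            name = paste0(sp, "::pathway"))
    tr <- translate_edges(sub, map, sp)
    sets[[sp]] <- tr$keys
    excluded[sp] <- tr$excluded
  }
  k <- length(sets)
  jac <- matrix(NA_real_, k, k, dimnames = list(names(sets), names(sets)))
  shared <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(union(sets[[i]], sets[[j]]))
      shared[i, j] <- inter
      jac[i, j] <- if (uni > 0L) inter / uni else NA_real_
    }
  }
  structure(list(jaccard = jac, shared_edges = shared,
                 edge_counts = lengths(sets), excluded_edges = excluded,
                 edge_sets = sets),
            class = "rewiring_report")
}

#' @export
print.rewiring_report <- function(x, ...) {
  cat("pathway rewiring report (edge Jaccard over ortholog-translated subgraphs)\n")
  print(round(x$jaccard, 3))
  invisible(x)
}
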