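## Cross-species 1:1 orthology: per-species gene sets, conserved-ortholog
## scoring over a species panel, and Venn partitioning of labeled sets.

#' Construct an ortholog map
#'
#' A long table of (gene, species, ortholog) rows; `NA` ortholog means the
#' gene has no detected 1:1 ortholog in that species. Genes whose mapping is
#' not 1:1 within a species (two genes sharing an ortholog identifier) are
#' excluded with a warning, mirroring a strict "gene to gene" mapping.
#'
#' @param df data frame with columns `gene`, `species`, `ortholog`.
#' @param species optional character vector fixing the species order
#'   (first species is the reference).
#' @return an `ortholog_map` data frame.
#' @export
ortholog_map <- function(df, species = NULL) {
  stopifnot(all(c("gene", "species", "ortholog") %in% names(df)))
  df$gene <- canonical_symbol(df$gene)
  df$species <- as.character(df$species)
  df$ortholog <- as.character(df$ortholog)
  df$ortholog[!is.na(df$ortholog) & df$ortholog == "NA"] <- NA_character_
  if (is.null(species)) species <- unique(df$species)
  if (!all(df$species %in% species)) stop("rows reference species not in `species`")
  ## enforce 1:1 within each species
  drop_genes <- character(0)
  for (sp in species) {
    sub <- df[df$species == sp & !is.na(df$ortholog), , drop = FALSE]
    dup_ids <- unique(sub$ortholog[duplicated(sub$ortholog)])
    dup_gene <- unique(sub$gene[duplicated(sub$gene)])
    bad <- unique(c(sub$gene[sub$ortholog %in% dup_ids], dup_gene))
    drop_genes <- union(drop_genes, bad)
  }
  if (length(drop_genes) > 0L) {
    warning(sprintf("excluded %d gene(s) with non-1:1 ortholog mappings",
                    length(drop_genes)))
    df <- df[!(df$gene %in% drop_genes), , drop = FALSE]
  }
  df <- df[order(match(df$species, species), df$gene), c("gene", "species", "ortholog")]
  rownames(df) <- NULL
  structure(df, species = species, class = c("ortholog_map", "data.frame"))
}

map_species <- function(map) attr(map, "species")

## Named character vector gene -> ortholog id (NA absent) for one species.
species_lookup <- function(map, species) {
  stopifnot(inherits(map, "ortholog_map"))
  if (!species %in% map_species(map)) {
    stop(sprintf("unknown species '%s' (available: %s)", species,
                 paste(map_species(map), collapse = ", ")))
  }
  sub <- map[map$species == species, , drop = FALSE]
  stats::setNames(sub$ortholog, sub$gene)
}

#' Per-species subsets of a gene panel with a detected ortholog
#'
#' @param genes character vector of reference-species gene symbols.
#' @param map an `ortholog_map`.
#' @return named list (one per species) of the subset of `genes` that has an
#'   ortholog in that species; genes absent from the map domain are reported
#'   in the `"skipped"` attribute rather than raising an error.
#' @export
species_gene_sets <- function(genes, map) {
  stopifnot(inherits(map, "ortholog_map"))
  genes <- unique(canonical_symbol(genes))
  domain <- unique(map$gene)
  skipped <- setdiff(genes, domain)
  genes <- intersect(genes, domain)
  out <- lapply(map_species(map), function(sp) {
    lk <- species_lookup(map, sp)
    genes[!is.na(lk[genes])]
  })
  names(out) <- map_species(map)
  attr(out, "skipped") <- skipped
  out
}

#' Conserved ortholog score
#'
#' Fraction of a species panel in which each gene has a detected ortholog
#' (unweighted presence fraction).
#'
#' @param genes gene symbols; must all be in the map domain.
#' @param map an `ortholog_map`.
#' @param panel species names to score over (non-empty, subset of the map's
#'   species).
#' @return named numeric vector of scores in `[0, 1]`.
#' @export
compute_cos <- function(genes, map, panel = map_species(map)) {
  stopifnot(inherits(map, "ortholog_map"), length(panel) >= 1L)
  if (!all(panel %in% map_species(map))) stop("panel species missing from map")
  genes <- canonical_symbol(genes)
  domain <- unique(map$gene)
  if (!all(genes %in% domain)) {
    stop(sprintf("gene(s) absent from ortholog map: %s",
                 paste(utils::head(setdiff(genes, domain), 5L), collapse = ", ")))
  }
  present <- vapply(panel, function(sp) {
    lk <- species_lookup(map, sp)
    !is.na(lk[genes])
  }, logical(length(genes)))
  present <- matrix(present, nrow = length(genes))
  stats::setNames(rowSums(present) / length(panel), genes)
}

#' Venn region counts for 2-6 labeled sets
#'
#' Elements of the union are partitioned by their exact membership pattern;
#' region names join member labels with `"&"`. All `2^k - 1` regions are
#' reported (zeros included); their sum equals the union cardinality.
#'
#' @param sets named list of 2-6 character vectors.
#' @return named integer vector of disjoint region counts.
#' @export
venn_counts <- function(sets) {
  if (!is.list(sets) || is.null(names(sets))) stop("`sets` must be a named list")
  k <- length(sets)
  if (k < 2L || k > 6L) stop("venn_counts supports 2-6 sets")
  labels <- names(sets)
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, nrow = length(universe))
  ## all non-empty label subsets, ordered by size then position
  combos <- unlist(lapply(seq_len(k), function(sz) {
    utils::combn(seq_len(k), sz, simplify = FALSE)
  }), recursive = FALSE)
  pattern <- apply(member, 1L, function(r) paste(labels[r], collapse = "&"))
  counts <- vapply(combos, function(idx) {
    sum(pattern == paste(labels[idx], collapse = "&"))
  }, integer(1))
  names(counts) <- vapply(combos, function(idx) paste(labels[idx], collapse = "&"),
                          character(1))
  counts
}
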