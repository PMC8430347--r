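## Drug-target conservation: confidence filtering of protein-chemical
## interactions, mapping surviving targets into species interactomes, and
## cross-species conservation of drugs.

#' Construct a drug-target table
#'
#' Confidence values on a 0-1000 integer scale (a common convention for
#' protein-chemical interaction scores) are auto-detected (any value > 1)
#' and divided by 1000; the rescaling is recorded in the `rescaled`
#' attribute. `(drug, species, target)` triples must be unique after
#' canonicalization.
#'
#' @param df data frame with columns `drug`, `species`, `target`,
#'   `confidence`.
#' @return a `drug_target_table` data frame with confidence in `[0, 1]`.
#' @export
drug_target_table <- function(df) {
  stopifnot(all(c("drug", "species", "target", "confidence") %in% names(df)))
  df$drug <- as.character(df$drug)
  df$species <- as.character(df$species)
  df$target <- canonical_symbol(df$target)
  df$confidence <- as.numeric(df$confidence)
  if (any(!is.finite(df$confidence)) || any(df$confidence < 0)) {
    stop("confidence must be finite and >= 0")
  }
  rescaled <- FALSE
  if (any(df$confidence > 1)) {
    df$confidence <- df$confidence / 1000
    rescaled <- TRUE
    if (any(df$confidence > 1)) stop("confidence exceeds 1 even after 0-1000 rescaling")
  }
  if (anyDuplicated(paste(df$drug, df$species, df$target, sep = "\r"))) {
    stop("duplicate (drug, species, target) rows")
  }
  rownames(df) <- NULL
  structure(df[, c("drug", "species", "target", "confidence")],
            rescaled = rescaled,
            class = c("drug_target_table", "data.frame"))
}

#' Filter drug-target interactions by confidence
#'
#' Retains rows with confidence strictly greater than `min_conf` (the
#' conventional high-confidence cut is 0.90).
#'
#' @param table a `drug_target_table`.
#' @param min_conf threshold in `[0, 1]`.
#' @return a filtered `drug_target_table`; attribute `n_removed` counts the
#'   dropped rows.
#' @export
filter_targets <- function(table, min_conf = 0.90) {
  stopifnot(inherits(table, "drug_target_table"), min_conf >= 0, min_conf <= 1)
  keep <- table$confidence > min_conf
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rescaled") <- attr(table, "rescaled")
  attr(out, "n_removed") <- sum(!keep)
  class(out) <- class(table)
  out
}

#' Map filtered drug targets into species interactomes
#'
#' A drug counts for a species iff at least one of its (already filtered)
#' targets in that species is a node of the species' interactome. Drugs are
#' then partitioned by their species-presence pattern (Venn regions); the
#' all-species region is the conserved drug set.
#'
#' @param table a (filtered) `drug_target_table` whose `target` identifiers
#'   are in each species' own namespace.
#' @param species_nets named list of `interactome`s (2-6 species).
#' @return a `drug_conservation_report` list: `presence` (logical drugs x
#'   species matrix), `venn` (region counts over drugs), `conserved`
#'   (drugs present in every species), `witnesses` (per drug, per species:
#'   mapped target genes), `unmapped` (per species, filtered targets not
#'   found in the net).
#' @export
map_drug_targets <- function(table, species_nets) {
  stopifnot(inherits(table, "drug_target_table"), is.list(species_nets),
            !is.null(names(species_nets)))
  species <- names(species_nets)
  drugs <- sort(unique(table$drug))
  presence <- matrix(FALSE, length(drugs), length(species),
                     dimnames = list(drugs, species))
  witnesses <- stats::setNames(vector("list", length(drugs)), drugs)
  unmapped <- stats::setNames(integer(length(species)), species)
  for (sp in species) {
    nodes <- species_nets[[sp]]$nodes
    sub <- table[table$species == sp, , drop = FALSE]
    unmapped[sp] <- sum(!(sub$target %in% nodes))
    hit <- sub[sub$target %in% nodes, , drop = FALSE]
    for (d in unique(hit$drug)) {
      presence[d, sp] <- TRUE
      witnesses[[d]][[sp]] <- sort(unique(hit$target[hit$drug == d]))
    }
  }
  sets <- lapply(species, function(sp) drugs[presence[, sp]])
  names(sets) <- species
  venn <- if (length(species) >= 2L) venn_counts(sets) else NULL
  structure(list(presence = presence, venn = venn,
                 conserved = drugs[rowSums(presence) == length(species)],
                 witnesses = witnesses, unmapped = unmapped),
            class = "drug_conservation_report")
}

#' @export
print.drug_conservation_report <- function(x, ...) {
  cat(sprintf("drug conservation: %d drugs x %d species; conserved in all: %s\n",
              nrow(x$presence), ncol(x$presence),
              if (length(x$conserved)) paste(x$conserved, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Targets shared by two drugs within a network
#'
#' Intersection of the two drugs' target sets (across species rows of the
#' table) restricted to the nodes of `net`. Symmetric in the drug
#' arguments.
#'
#' @param drug_a,drug_b drug identifiers present in `table`.
#' @param table a (filtered) `drug_target_table`.
#' @param net an `interactome` (e.g. the reference-species network).
#' @return character vector of shared target genes.
#' @export
shared_targets <- function(drug_a, drug_b, table, net) {
  stopifnot(inherits(table, "drug_target_table"), inherits(net, "interactome"))
  for (d in c(drug_a, drug_b)) {
    if (!d %in% table$drug) stop(sprintf("unknown drug '%s'", d))
  }
  ta <- table$target[table$drug == drug_a]
  tb <- table$target[table$drug == drug_b]
  sort(intersect(intersect(ta, tb), net$nodes))
}
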