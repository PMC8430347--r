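## End-to-end orchestration: curate -> orthology -> networks -> enrichment
## -> cross-species comparison -> tissue networks -> drugs, with every
## stage's declared output written to disk and a checksum manifest for
## reproducibility.

#' Pipeline configuration
#'
#' Inputs come either from a simulated study (`simulate`, a
#' [study_config()]) or from files (`paths`, a named list with elements
#' `sources` (directory of one-symbol-per-line lists), `networks` (named
#' vector of per-species edge-list TSVs), `reference_sources` (named vector
#' of edge-list TSVs for the reference interactome's provenance sources),
#' `orthologs`, `annotations` (GMT), `expression`, `drug_targets`).
#' Analysis parameter defaults follow the curated study: panel selection at
#' `min_sources = 2`, significance `alpha = 0.05`, `hub_k = 10` hubs,
#' drug-target confidence cut `min_conf = 0.90`.
#'
#' @param simulate a [study_config()], or `NULL` when `paths` is given.
#' @param paths named list of input paths, or `NULL`.
#' @param min_sources minimum evidence sources for panel inclusion.
#' @param alpha adjusted-p significance level.
#' @param hub_k number of hub genes reported per network.
#' @param min_conf drug-target confidence threshold (strict >).
#' @param min_level minimum ordinal protein level for tissue networks.
#' @param compare_term annotation term whose pathway subgraphs are compared
#'   across species; defaults to the first planted term (simulated runs) or
#'   the first term of the database.
#' @param n_perm permutations for expression/topology association.
#' @param seed base seed for all stage randomness.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = study_config(), paths = NULL,
                            min_sources = 2L, alpha = 0.05, hub_k = 10L,
                            min_conf = 0.90, min_level = "weak",
                            compare_term = NULL, n_perm = 10000L, seed = 1L) {
  if (is.null(simulate) && is.null(paths)) stop("either `simulate` or `paths` required")
  if (!is.null(paths)) {
    need <- c("sources", "networks", "orthologs", "annotations", "expression",
              "drug_targets")
    missing_k <- setdiff(need, names(paths))
    if (length(missing_k) > 0L) {
      stop("paths is missing: ", paste(missing_k, collapse = ", "))
    }
    all_paths <- c(list.files(paths$sources, full.names = TRUE),
                   unlist(paths[setdiff(names(paths), "sources")]))
    gone <- all_paths[!file.exists(all_paths)]
    if (length(gone) > 0L) stop("input path(s) do not exist: ",
                                paste(utils::head(gone, 5L), collapse = ", "))
  }
  structure(list(simulate = simulate, paths = paths,
                 min_sources = as.integer(min_sources), alpha = alpha,
                 hub_k = as.integer(hub_k), min_conf = min_conf,
                 min_level = min_level, compare_term = compare_term,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()] arguments; a `simulate:` block is
#' passed to [study_config()] (list-valued fields like `retention` become
#' named vectors).
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    s <- y$simulate
    for (f in c("source_sizes", "retention", "attachment", "planted_terms")) {
      if (!is.null(s[[f]])) s[[f]] <- unlist(s[[f]])
    }
    if (!is.null(s$confidence_mixture)) {
      s$confidence_mixture <- lapply(s$confidence_mixture, unlist)
    }
    sim <- do.call(study_config, s)
  }
  args <- y[setdiff(names(y), "simulate")]
  do.call(pipeline_config, c(list(simulate = sim), args))
}

load_study_inputs <- function(config) {
  if (!is.null(config$paths)) {
    p <- config$paths
    src_files <- sort(list.files(p$sources, pattern = "\\.txt$", full.names = TRUE))
    source_lists <- lapply(src_files, read_gene_list)
    names(source_lists) <- sub("\\.txt$", "", basename(src_files))
    nets <- lapply(p$networks, read_edge_list)
    names(nets) <- names(p$networks)
    ref_sources <- if (!is.null(p$reference_sources)) {
      rs <- lapply(p$reference_sources, read_edge_list)
      names(rs) <- names(p$reference_sources)
      rs
    } else NULL
    omap <- read_ortholog_map(p$orthologs)
    ## the annotation universe is the reference gene universe of the map
    ## (GMT files carry members only, not the background)
    list(source_lists = source_lists, species_nets = nets,
         reference_sources = ref_sources, ortholog_map = omap,
         annotations = read_gmt(p$annotations, background = unique(omap$gene)),
         expression = read_expression(p$expression),
         drug_table = read_drug_targets(p$drug_targets),
         truth = NULL)
  } else {
    sim <- config$simulate
    sim$seed <- config$seed          # pipeline seed governs the simulation
    sim$min_sources <- config$min_sources  # plant structure in the same panel
    generate_study(do.call(study_config, unclass(sim)))
  }
}

stage_path <- function(dir, ...) file.path(dir, paste0(...))

#' Run the full analysis pipeline
#'
#' Executes, in order: evidence curation and CES ranking; cross-species
#' orthology (per-species panels, Venn partition, conserved-ortholog
#' scores); species interactome subgraphs with topology, hubs, the combined
#' reference local network (union of provenance sources) and its degree
#' power-law fit; per-species pathway over-representation with
#' common/exclusive terms; pathway-subgraph rewiring comparison;
#' tissue-specific networks, the conserved inter-tissue edge module,
#' module-gene enrichment and expression/topology association; drug-target
#' filtering and cross-species conservation. All declared outputs are
#' written under `out_dir` and fingerprinted in `manifest.json`
#' (parameters + MD5 checksums), which is byte-identical across runs with
#' identical inputs and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return a `pipeline_report` list with the in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- load_study_inputs(config)
  species <- map_species(inputs$ortholog_map)
  reference <- species[1L]
  written <- character(0)
  emit <- function(path) { written <<- c(written, path); path }

  ## -- stage 1: curation -----------------------------------------------
  membership <- integrate_sources(inputs$source_lists)
  filtered <- filter_min_sources(membership, config$min_sources)
  catalog <- compute_ces(filtered)
  panel <- catalog$gene
  write_gene_catalog(catalog, emit(stage_path(out_dir, "catalog.tsv")))

  ## -- stage 2: orthology ----------------------------------------------
  sets <- species_gene_sets(panel, inputs$ortholog_map)
  venn <- venn_counts(sets)
  cos <- compute_cos(panel, inputs$ortholog_map)
  jsonlite::write_json(list(set_sizes = lengths(sets), venn = as.list(venn)),
                       emit(stage_path(out_dir, "ortholog_venn.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  write_tsv_plain(data.frame(gene = names(cos), cos = sprintf("%.17g", cos)),
                  emit(stage_path(out_dir, "cos.tsv")))

  ## -- stage 3: networks -----------------------------------------------
  panel_nets <- list(); panel_metrics <- list(); hubs <- list()
  for (sp in species) {
    lk <- species_lookup(inputs$ortholog_map, sp)
    ids <- unname(lk[sets[[sp]]])
    sub <- induced_subgraph(inputs$species_nets[[sp]], ids,
                            name = paste0(sp, "_panel"))
    panel_nets[[sp]] <- sub
    m <- compute_topology(sub)
    panel_metrics[[sp]] <- m
    hubs[[sp]] <- top_hubs(m, min(config$hub_k, nrow(m)))
    write_edge_list(sub, emit(stage_path(out_dir, "panel_", sp, ".tsv")))
    write_tsv_plain(m, emit(stage_path(out_dir, "metrics_", sp, ".tsv")))
  }
  ppin_sets <- lapply(species, function(sp) {
    sets[[sp]][unname(species_lookup(inputs$ortholog_map, sp)[sets[[sp]]]) %in%
                 inputs$species_nets[[sp]]$nodes]
  })
  names(ppin_sets) <- species
  ppin_venn <- venn_counts(ppin_sets)
  jsonlite::write_json(list(in_ppin = lengths(ppin_sets), venn = as.list(ppin_venn)),
                       emit(stage_path(out_dir, "ppin_venn.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  ## reference local network: union of provenance sources induced on panel
  if (!is.null(inputs$reference_sources)) {
    local_sources <- lapply(inputs$reference_sources, induced_subgraph, panel = panel)
    local_ppin <- union_interactomes(local_sources, name = "local_ppin")
  } else {
    local_ppin <- induced_subgraph(inputs$species_nets[[reference]], panel,
                                   name = "local_ppin")
  }
  local_metrics <- compute_topology(local_ppin)
  connected <- local_metrics$node[local_metrics$degree > 0L]
  degs <- local_metrics$degree[local_metrics$degree > 0L]
  pl_fit <- if (length(degs) >= 10L) {
    fit_power_law(degs)
  } else {
    list(exponent = NA_real_, xmin = NA_integer_, n_tail = length(degs),
         ks_distance = NA_real_, fit_method = "insufficient_data")
  }
  write_edge_list(local_ppin, emit(stage_path(out_dir, "local_ppin.tsv")))
  write_tsv_plain(local_metrics, emit(stage_path(out_dir, "local_ppin_metrics.tsv")))
  overlap <- attr(local_ppin, "source_overlap")
  jsonlite::write_json(
    list(n_nodes = length(local_ppin$nodes), n_interacting = length(connected),
         n_edges = n_edges(local_ppin),
         source_overlap = as.list(stats::setNames(as.integer(overlap),
                                                  names(overlap))),
         hubs = hubs,
         powerlaw = list(exponent = pl_fit$exponent, xmin = pl_fit$xmin,
                         n_tail = pl_fit$n_tail, method = pl_fit$fit_method)),
    emit(stage_path(out_dir, "network_summary.json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)

  ## -- stage 4: enrichment ---------------------------------------------
  enr <- list()
  for (sp in species) {
    lk <- species_lookup(inputs$ortholog_map, sp)
    bg_ids <- inputs$species_nets[[sp]]$nodes
    bg_ref <- names(lk)[!is.na(lk) & lk %in% bg_ids]
    db_sp <- restrict_background(inputs$annotations, bg_ref)
    enr[[sp]] <- enrich(intersect(ppin_sets[[sp]], db_sp$background), db_sp,
                        alpha = config$alpha)
    write_tsv_plain(as.data.frame(enr[[sp]]),
                    emit(stage_path(out_dir, "enrichment_", sp, ".tsv")))
  }
  common <- common_enriched(enr, alpha = config$alpha)
  jsonlite::write_json(list(common = common$common, exclusive = common$exclusive),
                       emit(stage_path(out_dir, "common_terms.json")),
                       auto_unbox = TRUE, pretty = TRUE)

  ## -- stage 5: cross-species pathway comparison ------------------------
  term <- config$compare_term %||%
    (if (length(common$common) > 0L) common$common[1L] else names(inputs$annotations$terms)[1L])
  path_genes <- inputs$annotations$terms[[term]]
  if (is.null(path_genes)) stop(sprintf("compare_term '%s' not in annotations", term))
  presence <- pathway_presence(path_genes, inputs$ortholog_map, inputs$species_nets)
  rewiring <- compare_pathway_subgraphs(path_genes, inputs$ortholog_map,
                                        inputs$species_nets)
  write_tsv_plain(data.frame(gene = rownames(presence), presence + 0L),
                  emit(stage_path(out_dir, "pathway_presence.tsv")))
  jsonlite::write_json(
    list(term = term, jaccard = as.data.frame(rewiring$jaccard),
         edge_counts = as.list(rewiring$edge_counts),
         excluded_edges = as.list(rewiring$excluded_edges)),
    emit(stage_path(out_dir, "rewiring.json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)

  ## -- stage 6: tissue networks ----------------------------------------
  tissues <- expr_tissues(inputs$expression)
  tissue_nets <- list(); assoc <- list(); mrna_cor <- list()
  for (ti in tissues) {
    tn <- build_tissue_network(local_ppin, inputs$expression, ti,
                               min_level = config$min_level)
    tissue_nets[[ti]] <- tn
    write_edge_list(tn$graph, emit(stage_path(out_dir, "tissue_", ti, ".tsv")))
    tm <- compute_topology(tn$graph)
    assoc[[ti]] <- cbind(tissue = ti,
                         expression_vs_topology(tn, inputs$expression, tm,
                                                n_perm = config$n_perm,
                                                seed = derive_seed(config$seed,
                                                                   paste0("perm_", ti))))
    rho <- mrna_protein_correlation(inputs$expression, ti)
    mrna_cor[[ti]] <- as.numeric(rho)
  }
  module <- conserved_module(tissue_nets)
  write_edge_list(module, emit(stage_path(out_dir, "conserved_module.tsv")))
  assoc_df <- do.call(rbind, assoc)
  write_tsv_plain(assoc_df, emit(stage_path(out_dir, "expression_topology.tsv")))
  ## inter-tissue enrichment consumes exactly the conserved-module node set
  db_mod <- restrict_background(inputs$annotations, local_ppin$nodes)
  inter_enr <- enrich(intersect(module$nodes, db_mod$background), db_mod,
                      alpha = config$alpha)
  write_tsv_plain(as.data.frame(inter_enr),
                  emit(stage_path(out_dir, "intertissue_enrichment.tsv")))
  jsonlite::write_json(
    list(min_level = protein_level_code(config$min_level),
         tissue_nodes = vapply(tissue_nets, function(t) length(t$graph$nodes), 0L),
         module_edges = n_edges(module), module_genes = length(module$nodes),
         module_background = length(db_mod$background),
         mrna_protein_spearman = mrna_cor),
    emit(stage_path(out_dir, "tissue_summary.json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)

  ## -- stage 7: drugs ----------------------------------------------------
  filt <- filter_targets(inputs$drug_table, config$min_conf)
  write_drug_targets(filt, emit(stage_path(out_dir, "drug_targets_filtered.tsv")))
  drug_report <- map_drug_targets(filt, inputs$species_nets)
  jsonlite::write_json(
    list(min_conf = config$min_conf, conserved = drug_report$conserved,
         venn = as.list(drug_report$venn),
         unmapped = as.list(drug_report$unmapped)),
    emit(stage_path(out_dir, "drug_conservation.json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)

  ## -- stage 8: manifest -------------------------------------------------
  written <- sort(unique(written))
  checksums <- as.list(stats::setNames(unname(tools::md5sum(written)),
                                       basename(written)))
  manifest <- list(
    package = "longnet",
    parameters = list(min_sources = config$min_sources, alpha = config$alpha,
                      hub_k = config$hub_k, min_conf = config$min_conf,
                      min_level = config$min_level, n_perm = config$n_perm,
                      seed = config$seed),
    species = species, reference = reference,
    stages = list(curation = "catalog.tsv",
                  orthology = c("ortholog_venn.json", "cos.tsv"),
                  networks = c("local_ppin.tsv", "network_summary.json"),
                  enrichment = "common_terms.json",
                  cross_species = "rewiring.json",
                  tissue = c("conserved_module.tsv", "tissue_summary.json"),
                  drugs = "drug_conservation.json",
                  manifest = "manifest.json"),
    checksums = checksums)
  manifest_path <- stage_path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  structure(list(catalog = catalog, species_sets = sets, venn = venn,
                 ppin_sets = ppin_sets, ppin_venn = ppin_venn, cos = cos,
                 panel_nets = panel_nets, panel_metrics = panel_metrics,
                 hubs = hubs, local_ppin = local_ppin,
                 local_metrics = local_metrics, powerlaw = pl_fit,
                 enrichment = enr, common_terms = common,
                 pathway_presence = presence, rewiring = rewiring,
                 tissue_nets = tissue_nets, conserved_module = module,
                 intertissue_enrichment = inter_enr,
                 expression_topology = assoc_df,
                 mrna_protein = unlist(mrna_cor),
                 drug_filtered = filt, drug_report = drug_report,
                 truth = inputs$truth, manifest = manifest,
                 manifest_path = manifest_path),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat(sprintf("  panel genes:        %d\n", nrow(x$catalog)))
  cat(sprintf("  local network:      %d nodes / %d edges (interacting: %d)\n",
              length(x$local_ppin$nodes), n_edges(x$local_ppin),
              sum(x$local_metrics$degree > 0)))
  cat(sprintf("  common pathways:    %s\n",
              if (length(x$common_terms$common)) paste(x$common_terms$common, collapse = ", ") else "(none)"))
  cat(sprintf("  conserved module:   %d edges / %d genes\n",
              n_edges(x$conserved_module), length(x$conserved_module$nodes)))
  cat(sprintf("  conserved drugs:    %s\n",
              if (length(x$drug_report$conserved)) paste(x$drug_report$conserved, collapse = ", ") else "(none)"))
  invisible(x)
}
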