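## Synthetic-study generator.
##
## Every input the pipeline consumes can be generated parametrically with
## the statistical structure the analysis assumes: sparse multi-source gene
## membership, approximately scale-free interactomes (preferential
## attachment), nested cross-species ortholog retention, planted
## over-represented gene sets, planted tissue-conserved edge modules, and
## mixed-confidence drug-target tables. All randomness flows from a single
## base seed through named substreams, so adding one generator never shifts
## the draws of another.

TABLE1_SOURCE_SIZES <- c(
  gwas_catalog = 230, dbgap = 32, gad = 102, ghmd = 33, hpo = 283,
  disgenet = 89, open_targets = 306, kegg = 385, amigo = 310,
  morbid_map = 358, geneage = 1780, longevitymap = 863, ncbi_mesh = 536,
  dna_methylation = 200, gene_expression = 308)

#' Configuration of a synthetic study
#'
#' Defaults emulate the study conditions of the curated analysis at a
#' quarter-scale universe: 15 evidence sources with the curated source
#' sizes divided by 4 over 1000 genes, a four-species panel
#' (reference human plus mouse/fly/worm with retention 0.96/0.45/0.41),
#' preferential-attachment interactomes, 200 annotation terms with 3
#' planted over-represented pathways, four tissues with a 50-edge planted
#' conserved module, and 40 drugs of which one is a planted pan-species
#' longevity compound.
#'
#' @param n_genes size of the gene universe.
#' @param source_sizes named integer vector of per-source list sizes
#'   (each in `1..n_genes`).
#' @param retention named numeric vector of per-species ortholog retention
#'   probabilities in `[0, 1]`; the first species is the reference and must
#'   have retention 1.
#' @param attachment named integer vector (same species) of
#'   preferential-attachment edges added per node.
#' @param n_terms number of annotation terms.
#' @param term_size_range integer `(min, max)` term sizes.
#' @param planted_terms named numeric vector: term id -> enrichment odds
#'   multiplier applied to panel genes when sampling members.
#' @param tissues tissue names (>= 1).
#' @param planted_conserved_edges number of planted inter-tissue conserved
#'   edges (>= 0).
#' @param n_drugs number of drugs (>= 1, including the planted pan-species
#'   drug when `pan_drug` is TRUE).
#' @param confidence_mixture two-component confidence distribution: list
#'   with `p_high` (mass of the high component) and uniform component
#'   ranges `high` and `low` within `[0, 1]`.
#' @param pan_drug plant one drug with high-confidence targets in every
#'   species?
#' @param min_sources evidence-source filter used when the generator needs
#'   the curated panel (to plant structure in it).
#' @param level_noise probability that a detected gene's ordinal protein
#'   level is jittered one grade up or down.
#' @param seed base RNG seed.
#' @return a validated `study_config` list.
#' @export
study_config <- function(n_genes = 1000L,
                         source_sizes = pmax(round(TABLE1_SOURCE_SIZES / 4), 1L),
                         retention = c(human = 1, mouse = 0.96, fly = 0.45, worm = 0.41),
                         attachment = c(human = 2L, mouse = 2L, fly = 2L, worm = 2L),
                         n_terms = 200L,
                         term_size_range = c(30L, 80L),
                         planted_terms = c(PW_PLANTED_01 = 10, PW_PLANTED_02 = 10,
                                           PW_PLANTED_03 = 10),
                         tissues = c("liver", "heart", "skeletal_muscle", "adipose"),
                         planted_conserved_edges = 50L,
                         n_drugs = 40L,
                         confidence_mixture = list(p_high = 0.3, high = c(0.90, 1),
                                                   low = c(0.10, 0.85)),
                         pan_drug = TRUE,
                         min_sources = 2L,
                         level_noise = 0.1,
                         seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), source_sizes = source_sizes,
              retention = retention, attachment = attachment,
              n_terms = as.integer(n_terms),
              term_size_range = as.integer(term_size_range),
              planted_terms = planted_terms, tissues = as.character(tissues),
              planted_conserved_edges = as.integer(planted_conserved_edges),
              n_drugs = as.integer(n_drugs),
              confidence_mixture = confidence_mixture,
              pan_drug = isTRUE(pan_drug), min_sources = as.integer(min_sources),
              level_noise = level_noise, seed = as.integer(seed))
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1L) stop("invalid config: n_genes must be >= 1")
    if (length(source_sizes) < 1L || any(source_sizes < 1L)) {
      stop("invalid config: every source size must be >= 1")
    }
    if (any(source_sizes > n_genes)) {
      stop("invalid config: source size exceeds n_genes")
    }
    if (is.null(names(retention)) || length(retention) < 1L) {
      stop("invalid config: retention must be a named vector")
    }
    if (any(retention < 0) || any(retention > 1)) {
      stop("invalid config: retention probabilities must lie in [0, 1]")
    }
    if (retention[[1L]] != 1) {
      stop("invalid config: the first (reference) species must have retention 1")
    }
    if (!all(names(retention) %in% names(attachment))) {
      stop("invalid config: attachment needed for every species")
    }
    if (any(attachment < 1L)) stop("invalid config: attachment must be >= 1")
    if (length(term_size_range) != 2L || term_size_range[1L] > term_size_range[2L]) {
      stop("invalid config: term_size_range must be (min <= max)")
    }
    if (term_size_range[1L] < 1L || term_size_range[2L] > n_genes) {
      stop("invalid config: term sizes must lie in 1..n_genes")
    }
    if (length(tissues) < 1L) stop("invalid config: at least one tissue required")
    if (planted_conserved_edges < 0L) stop("invalid config: planted_conserved_edges < 0")
    if (n_drugs < 1L) stop("invalid config: n_drugs must be >= 1")
    cm <- confidence_mixture
    if (!all(c("p_high", "high", "low") %in% names(cm)) ||
        cm$p_high < 0 || cm$p_high > 1 ||
        any(unlist(cm[c("high", "low")]) < 0) || any(unlist(cm[c("high", "low")]) > 1)) {
      stop("invalid config: confidence_mixture must have p_high in [0,1] and ranges within [0,1]")
    }
    if (level_noise < 0 || level_noise > 1) stop("invalid config: level_noise in [0,1]")
  })
  invisible(cfg)
}

universe_genes <- function(n) sprintf("GENE%04d", seq_len(n))

#' Generate per-source gene membership lists
#'
#' Each source samples its configured number of genes uniformly without
#' replacement from the shared universe, independently of the other sources
#' (the simplest null for multi-source membership); the per-gene source
#' count is then right-skewed with most genes in 0-2 sources.
#'
#' @param config a [study_config()].
#' @return a `source_membership` table (see [integrate_sources()]); the raw
#'   per-source lists are in attribute `source_lists`.
#' @export
generate_source_tables <- function(config) {
  validate_study_config(config)
  genes <- universe_genes(config$n_genes)
  lists <- with_seed(derive_seed(config$seed, "sources"), {
    lapply(config$source_sizes, function(sz) sample(genes, sz))
  })
  names(lists) <- names(config$source_sizes) %||%
    sprintf("source_%02d", seq_along(config$source_sizes))
  tab <- integrate_sources(lists)
  attr(tab, "source_lists") <- lists
  tab
}

#' Generate a preferential-attachment interactome
#'
#' Grows a connected simple undirected graph by preferential attachment
#' (each new node attaches to `attachment` existing nodes with probability
#' proportional to degree), yielding an approximately scale-free degree
#' distribution, then unions in any planted edges.
#'
#' @param n_nodes number of nodes (> attachment).
#' @param attachment edges added per new node (>= 1).
#' @param planted_edges optional 2-column matrix/data frame of node-name
#'   pairs to union in; endpoints must be existing nodes and distinct.
#' @param seed RNG seed.
#' @param node_names optional node names (length `n_nodes`); defaults to
#'   `N0001...`.
#' @param name network name.
#' @return an `interactome`.
#' @export
generate_interactome <- function(n_nodes, attachment = 2L, planted_edges = NULL,
                                 seed = 1L, node_names = NULL, name = "synthetic") {
  stopifnot(n_nodes > attachment, attachment >= 1L)
  if (is.null(node_names)) node_names <- sprintf("N%04d", seq_len(n_nodes))
  stopifnot(length(node_names) == n_nodes, !anyDuplicated(node_names))
  g <- with_seed(seed, igraph::sample_pa(n_nodes, power = 1, m = attachment,
                                         directed = FALSE))
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(a = node_names[el[, 1L]], b = node_names[el[, 2L]],
                      source = name, stringsAsFactors = FALSE)
  if (!is.null(planted_edges)) {
    pe <- as.data.frame(planted_edges, stringsAsFactors = FALSE)
    if (ncol(pe) < 2L) stop("planted_edges must have two columns")
    pa <- as.character(pe[[1L]]); pb <- as.character(pe[[2L]])
    if (any(pa == pb)) stop("planted edge is a self-loop")
    unknown <- setdiff(c(pa, pb), node_names)
    if (length(unknown) > 0L) {
      stop(sprintf("planted edge references unknown node(s): %s",
                   paste(utils::head(unknown, 5L), collapse = ", ")))
    }
    edges <- rbind(edges, data.frame(a = pa, b = pb, source = "planted",
                                     stringsAsFactors = FALSE))
  }
  net <- build_interactome(edges, name = name)
  ## keep isolated names (possible if planted edges duplicate backbone ones)
  net$nodes <- sort(node_names)
  net
}

#' Generate a cross-species 1:1 ortholog map
#'
#' Each gene is independently retained in each non-reference species with
#' that species' retention probability; retained genes receive a
#' species-prefixed ortholog identifier. The reference (first) species maps
#' every gene to itself.
#'
#' @param genes reference-species gene symbols.
#' @param retention named per-species retention probabilities (first species
#'   is the reference with retention 1).
#' @param seed RNG seed.
#' @return an `ortholog_map`.
#' @export
generate_ortholog_map <- function(genes, retention, seed = 1L) {
  stopifnot(!is.null(names(retention)), retention[[1L]] == 1,
            all(retention >= 0), all(retention <= 1))
  genes <- unique(canonical_symbol(genes))
  species <- names(retention)
  rows <- with_seed(seed, {
    lapply(species, function(sp) {
      if (sp == species[1L]) {
        orth <- genes
      } else {
        kept <- stats::runif(length(genes)) < retention[[sp]]
        orth <- ifelse(kept, paste0(toupper(sp), "_", genes), NA_character_)
      }
      data.frame(gene = genes, species = sp, ortholog = orth,
                 stringsAsFactors = FALSE)
    })
  })
  ortholog_map(do.call(rbind, rows), species = species)
}

#' Generate flat gene-set annotations with planted enrichment
#'
#' Term sizes are uniform on `term_size_range`; planted terms take the top
#' of the range (large-pathway analogue) and sample their members with the
#' configured odds multiplier on `query_set` genes, so downstream
#' over-representation of the planted terms in the panel is recoverable.
#' Unplanted terms sample members uniformly, independent of `query_set`.
#'
#' @param genes annotation universe.
#' @param query_set gene panel to enrich planted terms for (subset of
#'   `genes`).
#' @param n_terms number of terms (planted included).
#' @param term_size_range integer `(min, max)`.
#' @param planted_terms named numeric vector term id -> odds multiplier
#'   (may be empty).
#' @param seed RNG seed.
#' @return an `annotation_db` over `genes`.
#' @export
generate_annotations <- function(genes, query_set = character(0), n_terms = 200L,
                                 term_size_range = c(30L, 80L),
                                 planted_terms = numeric(0), seed = 1L) {
  genes <- unique(canonical_symbol(genes))
  query_set <- unique(canonical_symbol(query_set))
  if (!all(query_set %in% genes)) stop("query_set must be a subset of genes")
  if (term_size_range[2L] > length(genes)) {
    stop("invalid config: term size exceeds the universe size")
  }
  if (length(planted_terms) > n_terms) stop("more planted terms than terms")
  n_null <- n_terms - length(planted_terms)
  is_query <- genes %in% query_set
  with_seed(seed, {
    terms <- list()
    for (i in seq_along(planted_terms)) {
      odds <- planted_terms[[i]]
      w <- ifelse(is_query, odds, 1)
      terms[[names(planted_terms)[i]]] <- sample(genes, term_size_range[2L], prob = w)
    }
    sizes <- sample(seq.int(term_size_range[1L], term_size_range[2L]),
                    n_null, replace = TRUE)
    for (i in seq_len(n_null)) {
      terms[[sprintf("TERM_%04d", i)]] <- sample(genes, sizes[i])
    }
    desc <- stats::setNames(
      c(rep("planted synthetic pathway", length(planted_terms)),
        rep("synthetic gene set", n_null)), names(terms))
    annotation_db(terms, genes, desc)
  })
}

#' Generate tissue expression profiles
#'
#' Emulates tissue-restricted expression: each background gene is detected
#' in a random proper, non-empty subset of the tissues, while
#' `always_detected` genes (housekeeping-like, e.g. a planted conserved
#' module) are detected everywhere. Transcript values are log-normal (high
#' mode when detected, low mode otherwise); the ordinal protein level of a
#' detected gene is the tertile of its transcript value among detected
#' genes in that tissue (weak/moderate/high), jittered one grade with
#' probability `level_noise`; undetected genes are `negative`. Detection
#' calls are never jittered, mirroring the greater reliability of
#' presence/absence annotation over level gradation.
#'
#' @param genes gene symbols.
#' @param tissues tissue names (>= 1).
#' @param seed RNG seed.
#' @param always_detected genes detected in every tissue.
#' @param level_noise grade-jitter probability for detected genes.
#' @param meanlog_expr,meanlog_bg,sdlog log-normal transcript parameters for
#'   the detected and undetected modes.
#' @return an `expression_profile` with one row per gene x tissue.
#' @export
generate_expression <- function(genes, tissues, seed = 1L,
                                always_detected = character(0),
                                level_noise = 0.1,
                                meanlog_expr = 3, meanlog_bg = -2, sdlog = 0.8) {
  genes <- unique(canonical_symbol(genes))
  tissues <- as.character(tissues)
  if (length(tissues) < 1L) stop("invalid config: empty tissue list")
  always_detected <- intersect(unique(canonical_symbol(always_detected)), genes)
  nT <- length(tissues)
  with_seed(seed, {
    detected <- matrix(FALSE, length(genes), nT, dimnames = list(genes, tissues))
    detected[always_detected, ] <- TRUE
    bg <- setdiff(genes, always_detected)
    max_k <- max(1L, nT - 1L)
    for (g in bg) {
      k <- sample.int(max_k, 1L)
      detected[g, sample.int(nT, k)] <- TRUE
    }
    rows <- vector("list", nT)
    for (j in seq_len(nT)) {
      det <- detected[, j]
      tpm <- stats::rlnorm(length(genes),
                           meanlog = ifelse(det, meanlog_expr, meanlog_bg),
                           sdlog = sdlog)
      level <- rep("negative", length(genes))
      if (any(det)) {
        tert <- cut(rank(tpm[det], ties.method = "first"),
                    breaks = 3L, labels = FALSE)
        if (level_noise > 0) {
          jit <- stats::runif(length(tert)) < level_noise
          tert[jit] <- pmin(3L, pmax(1L, tert[jit] +
                                       sample(c(-1L, 1L), sum(jit), replace = TRUE)))
        }
        level[det] <- names(PROTEIN_LEVELS)[tert + 1L]
      }
      rows[[j]] <- data.frame(gene = genes, tissue = tissues[j], tpm = tpm,
                              protein_level = level, stringsAsFactors = FALSE)
    }
    expression_profile(do.call(rbind, rows))
  })
}

rconfidence <- function(n, mixture) {
  hi <- stats::runif(n) < mixture$p_high
  ifelse(hi,
         stats::runif(n, mixture$high[1L], mixture$high[2L]),
         stats::runif(n, mixture$low[1L], mixture$low[2L]))
}

#' Generate a mixed-confidence drug-target table
#'
#' Background drugs are assigned a random proper subset of the species and
#' draw targets from that species' pool with confidences from the
#' two-component mixture. The optional planted pan-species drug draws
#' targets from `pan_targets` in every species with confidence above 0.9,
#' so it is the unique drug whose filtered targets map into every species
#' network.
#'
#' @param n_drugs total number of drugs (pan drug included when planted).
#' @param target_pools named list (per species) of candidate target
#'   identifiers in the species' own namespace.
#' @param confidence_mixture see [study_config()].
#' @param pan_targets optional named list (per species, same names) of
#'   target identifiers for the planted pan-species drug `DRUG_PAN`.
#' @param max_targets maximum targets per background drug and species.
#' @param seed RNG seed.
#' @return a `drug_target_table`.
#' @export
generate_drug_targets <- function(n_drugs, target_pools, confidence_mixture,
                                  pan_targets = NULL, max_targets = 4L, seed = 1L) {
  stopifnot(n_drugs >= 1L, is.list(target_pools), !is.null(names(target_pools)))
  species <- names(target_pools)
  nS <- length(species)
  with_seed(seed, {
    rows <- list()
    if (!is.null(pan_targets)) {
      stopifnot(all(species %in% names(pan_targets)))
      for (sp in species) {
        tg <- unique(pan_targets[[sp]])
        rows[[length(rows) + 1L]] <-
          data.frame(drug = "DRUG_PAN", species = sp, target = tg,
                     confidence = stats::runif(length(tg), 0.905, 1),
                     stringsAsFactors = FALSE)
      }
    }
    n_bg <- n_drugs - as.integer(!is.null(pan_targets))
    for (d in seq_len(max(0L, n_bg))) {
      sub <- sample(species, sample.int(max(1L, nS - 1L), 1L))
      for (sp in sub) {
        pool <- target_pools[[sp]]
        tg <- sample(pool, min(length(pool), sample.int(max_targets, 1L)))
        rows[[length(rows) + 1L]] <-
          data.frame(drug = sprintf("DRUG_%03d", d), species = sp, target = tg,
                     confidence = rconfidence(length(tg), confidence_mixture),
                     stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    df <- df[!duplicated(paste(df$drug, df$species, df$target, sep = "\r")), ,
             drop = FALSE]
    drug_target_table(df)
  })
}

## Select the planted conserved-module genes and edges from the curated
## panel; module genes are panel genes, edges are random distinct pairs.
plant_conserved_edges <- function(panel_genes, n_edges, seed) {
  if (n_edges == 0L) {
    return(list(genes = character(0),
                edges = data.frame(a = character(0), b = character(0))))
  }
  with_seed(seed, {
    n_genes <- min(length(panel_genes), 2L * n_edges)
    if (n_genes < 2L) stop("panel too small to plant conserved edges")
    mod_genes <- sample(panel_genes, n_genes)
    keys <- character(0)
    edges <- list()
    while (length(edges) < n_edges) {
      pair <- sort(sample(mod_genes, 2L))
      k <- paste(pair, collapse = "\t")
      if (!k %in% keys) {
        keys <- c(keys, k)
        edges[[length(edges) + 1L]] <- pair
      }
    }
    e <- do.call(rbind, edges)
    list(genes = sort(unique(as.vector(e))),
         edges = data.frame(a = e[, 1L], b = e[, 2L], stringsAsFactors = FALSE))
  })
}

#' Generate a complete synthetic study
#'
#' Produces every input of the analysis pipeline with planted structure:
#' evidence-source lists, the 1:1 ortholog map, a reference-species
#' interactome split into three overlapping provenance sources (with the
#' planted conserved-module edges present in all three and backbone edges
#' internal to the module genes removed, so the module is exactly
#' recoverable), per-species interactomes, annotations with planted
#' over-represented pathways, tissue expression with housekeeping-like
#' module genes, and the drug-target table with a planted pan-species drug.
#'
#' @param config a [study_config()].
#' @return a `synthetic_study` list: `config`, `source_lists`, `membership`,
#'   `ortholog_map`, `species_nets` (reference net included),
#'   `reference_sources` (3 interactomes splitting the reference net),
#'   `annotations`, `expression`, `drug_table`, and `truth` (planted
#'   conserved edges/genes, planted term ids, pan drug id).
#' @export
generate_study <- function(config = study_config()) {
  validate_study_config(config)
  genes <- universe_genes(config$n_genes)
  species <- names(config$retention)
  reference <- species[1L]

  membership <- generate_source_tables(config)
  catalog <- compute_ces(filter_min_sources(membership, config$min_sources))
  panel <- catalog$gene

  omap <- generate_ortholog_map(genes, config$retention,
                                seed = derive_seed(config$seed, "orthologs"))

  planted <- plant_conserved_edges(panel, config$planted_conserved_edges,
                                   seed = derive_seed(config$seed, "conserved"))

  ## reference interactome over the whole universe, planted edges included
  ref_net <- generate_interactome(config$n_genes,
                                  attachment = config$attachment[[reference]],
                                  seed = derive_seed(config$seed, "net_reference"),
                                  node_names = genes, name = reference)
  ## drop backbone edges internal to the module so the planted edges are the
  ## only interactions among module genes
  if (nrow(planted$edges) > 0L) {
    internal <- ref_net$edges$a %in% planted$genes &
      ref_net$edges$b %in% planted$genes
    ref_net$edges <- ref_net$edges[!internal, , drop = FALSE]
    ref_net <- union_interactomes(list(
      ref_net,
      build_interactome(cbind(planted$edges, source = "planted"), name = reference)),
      name = reference)
    ref_net$nodes <- sort(genes)
  }

  ## split the reference net into three overlapping provenance sources;
  ## planted edges are well-replicated (all three sources)
  src_names <- c("ppidb_a", "ppidb_b", "ppidb_c")
  ref_sources <- with_seed(derive_seed(config$seed, "net_sources"), {
    ne <- nrow(ref_net$edges)
    memb <- matrix(stats::runif(ne * 3L) < 0.7, ne, 3L)
    empty <- rowSums(memb) == 0L
    while (any(empty)) {
      memb[empty, ] <- matrix(stats::runif(sum(empty) * 3L) < 0.7, sum(empty), 3L)
      empty <- rowSums(memb) == 0L
    }
    planted_row <- edge_keys(ref_net) %in% edge_key(planted$edges$a, planted$edges$b)
    memb[planted_row, ] <- TRUE
    lapply(seq_len(3L), function(i) {
      e <- ref_net$edges[memb[, i], c("a", "b"), drop = FALSE]
      build_interactome(cbind(e, source = src_names[i]), name = src_names[i])
    })
  })
  names(ref_sources) <- src_names

  ## per-species interactomes over the retained ortholog identifiers
  species_nets <- list()
  species_nets[[reference]] <- ref_net
  for (sp in setdiff(species, reference)) {
    lk <- species_lookup(omap, sp)
    ids <- sort(unname(lk[!is.na(lk)]))
    att <- config$attachment[[sp]]
    if (length(ids) > att) {
      sd_sp <- derive_seed(config$seed, paste0("net_", sp))
      nm <- with_seed(sd_sp, sample(ids))  # decouple age from identifier order
      species_nets[[sp]] <- generate_interactome(length(ids), attachment = att,
                                                 seed = sd_sp + 1L,
                                                 node_names = nm, name = sp)
    } else {
      species_nets[[sp]] <- build_interactome(
        data.frame(a = character(0), b = character(0), source = character(0)),
        name = sp)
      species_nets[[sp]]$nodes <- ids
    }
  }

  annotations <- generate_annotations(genes, query_set = panel,
                                      n_terms = config$n_terms,
                                      term_size_range = config$term_size_range,
                                      planted_terms = config$planted_terms,
                                      seed = derive_seed(config$seed, "annotations"))

  expression <- generate_expression(panel, config$tissues,
                                    seed = derive_seed(config$seed, "expression"),
                                    always_detected = planted$genes,
                                    level_noise = config$level_noise)

  ## drug-target table: pools are species net nodes; the pan drug targets
  ## orthologs of module genes retained in every species
  pools <- lapply(species_nets, function(n) n$nodes)
  pan_targets <- NULL
  if (config$pan_drug) {
    everywhere <- Reduce(intersect, lapply(species, function(sp) {
      lk <- species_lookup(omap, sp)
      names(lk)[!is.na(lk)]
    }))
    cand <- intersect(planted$genes, everywhere)
    if (length(cand) < 1L) cand <- intersect(panel, everywhere)
    if (length(cand) < 1L) cand <- everywhere
    if (length(cand) < 1L) stop("no gene retained in every species; cannot plant pan drug")
    picked <- with_seed(derive_seed(config$seed, "pan_drug"),
                        sample(cand, min(3L, length(cand))))
    pan_targets <- lapply(species, function(sp) {
      unname(species_lookup(omap, sp)[picked])
    })
    names(pan_targets) <- species
  }
  drug_table <- generate_drug_targets(config$n_drugs, pools,
                                      config$confidence_mixture,
                                      pan_targets = pan_targets,
                                      seed = derive_seed(config$seed, "drugs"))

  structure(list(config = config,
                 source_lists = attr(membership, "source_lists"),
                 membership = membership,
                 ortholog_map = omap,
                 species_nets = species_nets,
                 reference_sources = ref_sources,
                 annotations = annotations,
                 expression = expression,
                 drug_table = drug_table,
                 truth = list(conserved_edges = planted$edges,
                              conserved_genes = planted$genes,
                              planted_terms = names(config$planted_terms),
                              pan_drug = if (config$pan_drug) "DRUG_PAN" else NULL)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic_study: %d genes, %d sources, %d species, ",
                     "%d terms, %d tissues, %d drugs (seed %d)\n"),
              x$config$n_genes, length(x$source_lists),
              length(x$species_nets), length(x$annotations$terms),
              length(x$config$tissues), length(unique(x$drug_table$drug)),
              x$config$seed))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes every input table in its interchange format: per-source gene
#' lists (`sources/*.txt`), edge lists (`networks/*.tsv`),
#' `orthologs.tsv`, `annotations.gmt`, `expression.tsv`,
#' `drug_targets.tsv`. Output is byte-identical for identical
#' (config, seed).
#'
#' @param study a `synthetic_study` from [generate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(file.path(dir, "sources"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "networks"), showWarnings = FALSE)
  for (nm in names(study$source_lists)) {
    write_gene_list(study$source_lists[[nm]], file.path(dir, "sources", paste0(nm, ".txt")))
  }
  for (sp in names(study$species_nets)) {
    write_edge_list(study$species_nets[[sp]],
                    file.path(dir, "networks", paste0(sp, ".tsv")))
  }
  for (nm in names(study$reference_sources)) {
    write_edge_list(study$reference_sources[[nm]],
                    file.path(dir, "networks", paste0("reference_", nm, ".tsv")))
  }
  write_ortholog_map(study$ortholog_map, file.path(dir, "orthologs.tsv"))
  write_gmt(study$annotations, file.path(dir, "annotations.gmt"))
  write_expression(study$expression, file.path(dir, "expression.tsv"))
  write_drug_targets(study$drug_table, file.path(dir, "drug_targets.tsv"))
  invisible(dir)
}
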