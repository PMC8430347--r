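test_that("invalid study configurations are rejected with clear errors", {
  expect_error(study_config(n_genes = 0), "n_genes")
  expect_error(study_config(source_sizes = c(a = 0)), "source size")
  expect_error(study_config(source_sizes = c(a = 2000)), "exceeds n_genes")
  expect_error(study_config(retention = c(human = 0.5)), "reference")
  expect_error(study_config(retention = c(human = 1, mouse = 1.2)), "\\[0, 1\\]")
  expect_error(study_config(retention = c(human = 1, yeti = 0.5)), "attachment")
  expect_error(study_config(term_size_range = c(50, 10)), "term_size_range")
  expect_error(study_config(tissues = character(0)), "tissue")
  expect_error(study_config(n_drugs = 0), "n_drugs")
  expect_error(study_config(confidence_mixture = list(p_high = 1.5,
                                                      high = c(0.9, 1),
                                                      low = c(0.1, 0.8))),
               "confidence_mixture")
  expect_error(study_config(level_noise = 2), "level_noise")
})

test_that("identical configurations regenerate byte-identical studies", {
  cfg <- study_config(n_genes = 200,
                      source_sizes = pmax(round(TABLE1_SOURCE_SIZES / 20), 1L),
                      n_terms = 20, term_size_range = c(10L, 30L),
                      planted_conserved_edges = 10, n_drugs = 8, seed = 42)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(generate_study(cfg), d1)
  write_study(generate_study(cfg), d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f1))))
  ## a different seed changes at least the source lists
  d3 <- withr::local_tempdir()
  cfg3 <- cfg; cfg3$seed <- 43L
  write_study(generate_study(cfg3), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, f1))),
                         unname(tools::md5sum(file.path(d3, f1)))))
})

test_that("source generation matches its configuration and the CES bound", {
  cfg <- study_config(seed = 7)
  memb <- generate_source_tables(cfg)
  lists <- attr(memb, "source_lists")
  expect_identical(names(lists), names(cfg$source_sizes))
  expect_identical(lengths(lists), vapply(cfg$source_sizes, as.integer, 1L))
  expect_identical(as.integer(unname(colSums(memb))),
                   unname(vapply(cfg$source_sizes, as.integer, 1L)))
  ## saturated membership: every gene in every source, all CES equal 1
  sat <- integrate_sources(list(s1 = c("A", "B"), s2 = c("A", "B")))
  cat <- compute_ces(sat)
  expect_true(all(cat$ces == 1))
})

test_that("the two-or-more-source fraction matches the independence closed form", {
  ## sources sample independently; P(gene in >= 2 sources) =
  ## 1 - prod(1-p_i) - sum_i p_i prod_{j != i}(1-p_j), p_i = size_i / n
  cfg <- study_config()
  p <- cfg$source_sizes / cfg$n_genes
  p0 <- prod(1 - p)
  p1 <- sum(vapply(seq_along(p), function(i) p[i] * prod(1 - p[-i]), 0))
  expected <- 1 - p0 - p1
  frac <- vapply(1:50, function(s) {
    c2 <- cfg; c2$seed <- s
    memb <- generate_source_tables(c2)
    nrow(filter_min_sources(memb, 2L)) / cfg$n_genes
  }, 0)
  expect_lt(abs(mean(frac) - expected), 0.05 * expected)
})

test_that("preferential attachment yields heavy-tailed degree distributions", {
  tails <- vapply(1:20, function(s) {
    net <- generate_interactome(1000, attachment = 2, seed = s)
    fit_degree_distribution(net)$exponent
  }, 0)
  expect_true(all(tails > 2.2 & tails < 3.8))
})

test_that("ortholog retention is binomial at the configured rates", {
  ret <- c(human = 1, mouse = 0.96, fly = 0.45, worm = 0.41)
  genes <- sprintf("G%04d", 1:1007)
  counts <- t(vapply(1:30, function(s) {
    map <- generate_ortholog_map(genes, ret, seed = s)
    vapply(names(ret), function(sp) sum(!is.na(map$ortholog[map$species == sp])), 0)
  }, stats::setNames(numeric(4), names(ret))))
  expect_true(all(counts[, "human"] == 1007))
  for (sp in c("mouse", "fly", "worm")) {
    se <- sqrt(ret[[sp]] * (1 - ret[[sp]]) * 1007 / 30)
    expect_lt(abs(mean(counts[, sp]) - ret[[sp]] * 1007), 3 * se)
  }
})

test_that("planted annotation terms contain the query at elevated rates", {
  genes <- sprintf("G%04d", 1:1000)
  query <- genes[1:100]
  db <- generate_annotations(genes, query, n_terms = 50,
                             term_size_range = c(30, 80),
                             planted_terms = c(PL1 = 10, PL2 = 10), seed = 3)
  expect_length(db$terms, 50L)
  expect_true(all(c("PL1", "PL2") %in% names(db$terms)))
  ## planted terms take the maximal size
  expect_equal(lengths(db$terms[c("PL1", "PL2")]), c(PL1 = 80L, PL2 = 80L))
  planted_hits <- mean(vapply(db$terms[c("PL1", "PL2")],
                              function(t) sum(t %in% query), 0L))
  null_hits <- mean(vapply(db$terms[!names(db$terms) %in% c("PL1", "PL2")],
                           function(t) sum(t %in% query), 0L))
  expect_gt(planted_hits, 2 * null_hits)
})

test_that("noise-free expression reproduces the tertile grading exactly", {
  genes <- sprintf("G%03d", 1:90)
  expr <- generate_expression(genes, c("t1", "t2"), seed = 4,
                              always_detected = genes, level_noise = 0)
  for (ts in c("t1", "t2")) {
    sl <- expr[expr$tissue == ts, ]
    code <- protein_level_code(sl$protein_level)
    expect_true(all(code >= 1L))  # housekeeping genes always detected
    tert <- cut(rank(sl$tpm, ties.method = "first"), breaks = 3, labels = FALSE)
    expect_identical(code, as.integer(tert))
    ## grading is a deterministic function of tpm: rank correlation ~1
    expect_gt(mrna_protein_correlation(expr, ts), 0.9)
  }
  ## background genes are detected in a proper, non-empty tissue subset
  bg <- generate_expression(genes, c("a", "b", "c"), seed = 5)
  det <- tapply(protein_level_code(bg$protein_level) >= 1L, bg$gene, sum)
  expect_true(all(det >= 1L & det <= 2L))
})

test_that("the confidence mixture puts the configured mass above 0.90", {
  mix <- list(p_high = 0.3, high = c(0.90, 1), low = c(0.10, 0.85))
  frac <- vapply(1:20, function(s) {
    set.seed(s)
    mean(longnet:::rconfidence(1000, mix) > 0.90)
  }, 0)
  se <- sqrt(0.3 * 0.7 / (1000 * 20))
  expect_lt(abs(mean(frac) - 0.3), 3 * se)
  ## all mass below the cut leaves nothing after filtering
  set.seed(1)
  low <- drug_target_table(data.frame(drug = "D", species = "h",
                                      target = sprintf("T%02d", 1:50),
                                      confidence = runif(50, 0.1, 0.85)))
  expect_equal(nrow(filter_targets(low, 0.90)), 0L)
})

test_that("planted interactome edges are validated and unioned in", {
  expect_error(generate_interactome(10, planted_edges = cbind("N0001", "N0001")),
               "self-loop")
  expect_error(generate_interactome(10, planted_edges = cbind("N0001", "ZZZZ")),
               "unknown node")
  net <- generate_interactome(20, attachment = 1, seed = 2,
                              planted_edges = cbind("N0001", "N0020"))
  expect_true(edge_key("N0001", "N0020") %in% edge_keys(net))
})

test_that("the generated study carries recoverable planted truth", {
  study <- generate_study(study_config(seed = 11))
  truth <- study$truth
  expect_equal(nrow(truth$conserved_edges), 50L)
  expect_setequal(truth$conserved_genes,
                  unique(c(truth$conserved_edges$a, truth$conserved_edges$b)))
  ## planted edges exist in the reference net and in all three provenance
  ## sources; no other reference edge joins two module genes
  ref <- study$species_nets[[1]]
  pk <- edge_key(truth$conserved_edges$a, truth$conserved_edges$b)
  expect_true(all(pk %in% edge_keys(ref)))
  for (src in study$reference_sources) expect_true(all(pk %in% edge_keys(src)))
  internal <- ref$edges$a %in% truth$conserved_genes &
    ref$edges$b %in% truth$conserved_genes
  expect_setequal(edge_keys(ref)[internal], pk)
  ## module genes are housekeeping-like: detected in every tissue
  mod <- study$expression[study$expression$gene %in% truth$conserved_genes, ]
  expect_true(all(protein_level_code(mod$protein_level) >= 1L))
  ## pan drug targets map into every species network above the cut
  filt <- filter_targets(study$drug_table, 0.90)
  for (sp in names(study$species_nets)) {
    hit <- filt[filt$drug == "DRUG_PAN" & filt$species == sp, ]
    expect_gt(sum(hit$target %in% study$species_nets[[sp]]$nodes), 0L)
  }
})
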