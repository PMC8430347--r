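make_nets <- function(edge_lists) {
  lapply(edge_lists, function(e) {
    build_interactome(data.frame(a = e[, 1], b = e[, 2]))
  })
}

test_that("pathway presence requires both an ortholog and a network node", {
  genes <- c("A", "B", "C")
  map <- ortholog_map(rbind(
    data.frame(gene = genes, species = "h", ortholog = genes),
    data.frame(gene = genes, species = "m",
               ortholog = c("M_A", NA, "M_C"))), species = c("h", "m"))
  nets <- make_nets(list(h = cbind(c("A", "B"), c("B", "C")),
                         m = cbind("M_A", "M_X")))
  pres <- pathway_presence(genes, map, nets)
  expect_true(all(pres[, "h"]))
  ## B has no mouse ortholog; C's ortholog is not a mouse network node
  expect_equal(unname(pres[, "m"]), c(TRUE, FALSE, FALSE))
  expect_equal(unname(attr(pres, "totals")), c(3L, 1L))
  ## column sums agree with a direct table join
  for (sp in c("h", "m")) {
    lk <- species_lookup(map, sp)
    direct <- sum(!is.na(lk[genes]) & lk[genes] %in% nets[[sp]]$nodes)
    expect_equal(unname(attr(pres, "totals")[sp]), direct)
  }
  expect_error(pathway_presence(genes, map, list(zebra = nets$h)), "species")
})

test_that("identical networks under the identity map give edge Jaccard 1", {
  genes <- sprintf("G%02d", 1:12)
  map <- ortholog_map(rbind(
    data.frame(gene = genes, species = "s1", ortholog = genes),
    data.frame(gene = genes, species = "s2", ortholog = genes)),
    species = c("s1", "s2"))
  set.seed(21)
  net <- random_net(12, 0.4)
  net$nodes <- genes
  net$edges$a <- sub("^V", "G", net$edges$a)
  net$edges$b <- sub("^V", "G", net$edges$b)
  rep <- compare_pathway_subgraphs(genes, map, list(s1 = net, s2 = net))
  expect_equal(rep$jaccard["s1", "s2"], 1)
  expect_equal(rep$shared_edges["s1", "s2"], n_edges(net))
  expect_equal(unname(rep$excluded_edges), c(0L, 0L))
})

test_that("edge-disjoint subgraphs give Jaccard 0; planted overlap is exact", {
  genes <- c("A", "B", "C", "D")
  map <- ortholog_map(rbind(
    data.frame(gene = genes, species = "h", ortholog = genes),
    data.frame(gene = genes, species = "m", ortholog = paste0("M_", genes))),
    species = c("h", "m"))
  ## disjoint: h has A-B, m has M_C-M_D (translates to C-D)
  nets <- make_nets(list(h = cbind("A", "B"), m = cbind("M_C", "M_D")))
  rep0 <- compare_pathway_subgraphs(genes, map, nets)
  expect_equal(rep0$jaccard["h", "m"], 0)

  ## 3 shared + 2 private in h + 1 private in m -> Jaccard 3/6
  h_edges <- rbind(c("A", "B"), c("A", "C"), c("B", "C"), c("A", "D"), c("B", "D"))
  m_edges <- rbind(c("M_A", "M_B"), c("M_A", "M_C"), c("M_B", "M_C"), c("M_C", "M_D"))
  nets2 <- make_nets(list(h = h_edges, m = m_edges))
  rep1 <- compare_pathway_subgraphs(genes, map, nets2)
  expect_equal(rep1$shared_edges["h", "m"], 3L)
  expect_equal(rep1$jaccard["h", "m"], 3 / 6)
  ## diagonal is 1 where the subgraph has edges
  expect_equal(rep1$jaccard["h", "h"], 1)
})

test_that("edges with untranslatable endpoints are excluded and counted", {
  genes <- c("A", "B")
  map <- ortholog_map(rbind(
    data.frame(gene = genes, species = "h", ortholog = genes),
    data.frame(gene = genes, species = "m", ortholog = c("M_A", NA))),
    species = c("h", "m"))
  m_net <- build_interactome(data.frame(a = c("M_A", "M_A"), b = c("M_B", "M_C")))
  ## only M_A maps; induced subgraph on {M_A} keeps no edges at all
  rep <- compare_pathway_subgraphs(genes, map,
                                   list(h = make_nets(list(cbind("A", "B")))[[1]],
                                        m = m_net))
  expect_equal(unname(rep$edge_counts["m"]), 0L)
  expect_true(is.na(rep$jaccard["m", "m"]))
})

test_that("translation through the ortholog map is a bijection on retained genes", {
  genes <- sprintf("G%03d", 1:60)
  map <- generate_ortholog_map(genes, c(h = 1, m = 0.7), seed = 14)
  lk <- species_lookup(map, "m")
  kept <- names(lk)[!is.na(lk)]
  rev_lk <- stats::setNames(kept, lk[kept])
  expect_identical(unname(rev_lk[lk[kept]]), kept)
  expect_false(anyDuplicated(lk[kept]) > 0)
})

test_that("removing one species does not change the remaining comparisons", {
  study <- generate_study(study_config(
    n_genes = 150, source_sizes = pmax(round(TABLE1_SOURCE_SIZES / 20), 1L),
    n_terms = 10, term_size_range = c(10L, 30L),
    planted_conserved_edges = 5, n_drugs = 5, seed = 19))
  pw <- study$truth$conserved_genes
  full <- compare_pathway_subgraphs(pw, study$ortholog_map, study$species_nets)
  sub <- compare_pathway_subgraphs(pw, study$ortholog_map,
                                   study$species_nets[c("human", "mouse")])
  expect_equal(sub$jaccard["human", "mouse"], full$jaccard["human", "mouse"])
  expect_equal(sub$edge_counts[["mouse"]], full$edge_counts[["mouse"]])
})
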