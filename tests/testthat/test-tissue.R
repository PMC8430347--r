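test_that("protein level codes follow the ordinal scale", {
  expect_equal(protein_level_code(c("negative", "weak", "moderate", "high")),
               0:3)
  expect_true(is.na(protein_level_code("plaid")))
  expect_equal(protein_level_code(2L), 2L)
})

test_that("expression_profile validates its inputs", {
  ok <- data.frame(gene = c("a", "b"), tissue = "liver", tpm = c(1, 2),
                   protein_level = c("weak", "HIGH"))
  expr <- expression_profile(ok)
  expect_equal(expr$gene, c("A", "B"))
  expect_equal(expr$protein_level, c("weak", "high"))
  expect_error(expression_profile(transform(ok, tpm = c(-1, 2))), "tpm")
  expect_error(expression_profile(transform(ok, protein_level = "plaid")),
               "unknown protein level")
  expect_error(expression_profile(rbind(ok, ok)), "duplicate")
})

test_that("tissue networks keep exactly the nodes at or above the level cut", {
  set.seed(41)
  net <- random_net(25, 0.3)
  expr <- random_expression(net$nodes, "muscle")
  for (cut in c("weak", "moderate", "high")) {
    tn <- build_tissue_network(net, expr, "muscle", min_level = cut)
    expected <- expr$gene[protein_level_code(expr$protein_level) >=
                            protein_level_code(cut)]
    expect_setequal(tn$graph$nodes, intersect(net$nodes, expected))
    ## brute-force edge filter
    keep <- net$edges$a %in% expected & net$edges$b %in% expected
    expect_equal(n_edges(tn$graph), sum(keep))
  }
  ## raising the cut never adds nodes or edges
  sizes <- vapply(c("weak", "moderate", "high"), function(cut) {
    g <- build_tissue_network(net, expr, "muscle", cut)$graph
    c(length(g$nodes), n_edges(g))
  }, numeric(2))
  expect_true(all(diff(sizes[1, ]) <= 0))
  expect_true(all(diff(sizes[2, ]) <= 0))
  expect_error(build_tissue_network(net, expr, "spleen"), "unknown tissue")
})

test_that("a cut above every observed level empties the network", {
  net <- net_from_pairs(c("A", "B"))
  expr <- expression_profile(data.frame(gene = c("A", "B"), tissue = "t",
                                        tpm = 1, protein_level = "weak"))
  tn <- build_tissue_network(net, expr, "t", min_level = "high")
  expect_length(tn$graph$nodes, 0L)
  expect_equal(n_edges(tn$graph), 0L)
})

test_that("conserved_module is the exact edge-set intersection", {
  n1 <- net_from_pairs(c("A", "B"), c("B", "C"), c("C", "D"))
  n2 <- net_from_pairs(c("A", "B"), c("C", "D"), c("A", "D"))
  n3 <- net_from_pairs(c("A", "B"), c("C", "D"))
  mod <- conserved_module(list(n1, n2, n3))
  expect_setequal(edge_keys(mod), c(edge_key("A", "B"), edge_key("C", "D")))
  ## nodes are only the endpoints of surviving edges
  expect_setequal(mod$nodes, c("A", "B", "C", "D"))

  ## identity, disjointness, order-invariance, associativity
  expect_identical(conserved_module(list(n1, n1))$edges, n1$edges)
  disjoint <- net_from_pairs(c("X", "Y"))
  expect_equal(n_edges(conserved_module(list(n1, disjoint))), 0L)
  expect_identical(conserved_module(list(n3, n2, n1))$edges, mod$edges)
  nested <- conserved_module(list(conserved_module(list(n1, n2)), n3))
  expect_identical(nested$edges, mod$edges)
  ## the module's edges are a subset of every input's
  for (n in list(n1, n2, n3)) expect_true(all(edge_keys(mod) %in% edge_keys(n)))
  expect_error(conserved_module(list(n1)), ">= 2")
})

test_that("conserved modules shrink monotonically with the expression cut", {
  set.seed(43)
  net <- random_net(30, 0.25)
  exprs <- lapply(c("t1", "t2", "t3"), function(ts) random_expression(net$nodes, ts))
  expr <- expression_profile(do.call(rbind, exprs))
  mods <- lapply(c("weak", "moderate"), function(cut) {
    nets <- lapply(c("t1", "t2", "t3"), function(ts) {
      build_tissue_network(net, expr, ts, cut)
    })
    conserved_module(nets)
  })
  expect_true(all(edge_keys(mods[[2]]) %in% edge_keys(mods[[1]])))
})

test_that("expression~topology association handles signal, nulls and degeneracy", {
  ## strong association: transcript value increases with degree
  set.seed(61)
  net <- random_net(20, 0.3)
  m <- compute_topology(net)
  expr <- expression_profile(data.frame(
    gene = m$node, tissue = "t",
    tpm = m$degree + seq_len(nrow(m)) / 100,  # jitter only breaks ties
    protein_level = ifelse(m$degree > stats::median(m$degree), "high", "weak")))
  tn <- build_tissue_network(net, expr, "t")
  res <- expression_vs_topology(tn, expr, n_perm = 500, seed = 3)
  expect_equal(res$comparison, c("protein_vs_degree", "tpm_vs_degree"))
  rho_tpm <- res$rho[res$comparison == "tpm_vs_degree"]
  ## direct average-rank Spearman oracle
  expect_equal(rho_tpm, stats::cor(rank(expr$tpm), rank(m$degree)),
               tolerance = 1e-12)
  expect_gt(rho_tpm, 0.8)
  expect_lt(res$p_perm[res$comparison == "tpm_vs_degree"], 0.05)
  expect_true(all(res$p_perm <= 1 & res$p_perm >= 1 / 501, na.rm = TRUE))

  ## constant protein level: NA with a reason, tpm row still computed
  expr2 <- expression_profile(data.frame(
    gene = m$node, tissue = "t", tpm = seq_len(nrow(m)), protein_level = "weak"))
  tn2 <- build_tissue_network(net, expr2, "t")
  res2 <- expression_vs_topology(tn2, expr2, n_perm = 100, seed = 3)
  expect_true(is.na(res2$rho[res2$comparison == "protein_vs_degree"]))
  expect_match(res2$note[res2$comparison == "protein_vs_degree"], "constant")

  ## fewer than 3 expressed nodes is an error
  tiny <- net_from_pairs(c("A", "B"))
  expr3 <- expression_profile(data.frame(gene = c("A", "B"), tissue = "t",
                                         tpm = c(1, 2), protein_level = "weak"))
  expect_error(expression_vs_topology(build_tissue_network(tiny, expr3, "t"),
                                      expr3), "insufficient")
})

test_that("permuted expression shows no mRNA~protein association", {
  rhos <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 500
    expr <- expression_profile(data.frame(
      gene = sprintf("G%03d", 1:n), tissue = "t",
      tpm = stats::rlnorm(n, 2, 1),
      protein_level = sample(c("negative", "weak", "moderate", "high"), n,
                             replace = TRUE)))
    mrna_protein_correlation(expr, "t")
  }, 0)
  expect_lt(mean(abs(rhos)), 0.1)
  expect_lt(abs(mean(rhos)), 3 * stats::sd(rhos) / sqrt(50))
})

test_that("mrna_protein_correlation flags degenerate inputs", {
  expr <- expression_profile(data.frame(gene = c("A", "B", "C"), tissue = "t",
                                        tpm = c(1, 2, 3), protein_level = "weak"))
  rho <- mrna_protein_correlation(expr, "t")
  expect_true(is.na(rho))
  expect_match(attr(rho, "note"), "constant")
  small <- expression_profile(data.frame(gene = c("A", "B"), tissue = "t",
                                         tpm = c(1, 2),
                                         protein_level = c("weak", "high")))
  expect_error(mrna_protein_correlation(small, "t"), "insufficient")
})
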