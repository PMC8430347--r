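test_that("build_interactome canonicalizes pairs, drops loops and duplicates", {
  net <- build_interactome(data.frame(a = c("A", "B", "A"), b = c("B", "A", "A")))
  expect_equal(n_edges(net), 1L)
  expect_setequal(net$nodes, c("A", "B"))
  expect_equal(attr(net, "n_self_loops"), 1L)
  expect_equal(attr(net, "n_duplicates"), 1L)

  empty <- build_interactome(data.frame(a = character(0), b = character(0)))
  expect_equal(n_edges(empty), 0L)
  expect_length(empty$nodes, 0L)
})

test_that("edge count of noisy input equals the canonical-pair set oracle", {
  set.seed(23)
  ids <- sprintf("P%03d", 1:80)
  rows <- data.frame(a = sample(ids, 10000, replace = TRUE),
                     b = sample(ids, 10000, replace = TRUE))
  net <- build_interactome(rows)
  keep <- rows$a != rows$b
  oracle <- unique(paste(pmin(rows$a, rows$b), pmax(rows$a, rows$b))[keep])
  expect_equal(n_edges(net), length(oracle))
  ## handshake identity
  expect_equal(sum(compute_topology(net)$degree), 2L * n_edges(net))
})

test_that("induced_subgraph filters edges exactly, idempotently, monotonically", {
  set.seed(31)
  net <- random_net(30, 0.3)
  expect_identical(induced_subgraph(net, net$nodes)$edges, net$edges)
  expect_equal(n_edges(induced_subgraph(net, c("ZZ1", "ZZ2"))), 0L)

  panel <- sample(net$nodes, 15)
  sub <- induced_subgraph(net, panel)
  oracle <- net$edges[net$edges$a %in% panel & net$edges$b %in% panel, ]
  expect_equal(edge_key(sub$edges$a, sub$edges$b), edge_key(oracle$a, oracle$b))
  expect_identical(induced_subgraph(sub, panel)$edges, sub$edges)

  bigger <- union(panel, sample(net$nodes, 10))
  expect_gte(n_edges(induced_subgraph(net, bigger)), n_edges(sub))
})

test_that("union_interactomes merges provenance and counts per-source overlap", {
  n1 <- build_interactome(data.frame(a = c("A", "B"), b = c("B", "C"), s = "x"))
  n2 <- build_interactome(data.frame(a = c("A", "C"), b = c("B", "D"), s = "y"))
  u <- union_interactomes(list(n1, n2))
  expect_equal(n_edges(u), 3L)
  expect_equal(u$edges$sources[u$edges$a == "A" & u$edges$b == "B"], "x;y")
  ov <- attr(u, "source_overlap")
  expect_equal(as.integer(ov), c(2L, 1L))  # 2 single-source, 1 shared

  ## self-union is the identity (tags merge to themselves)
  expect_identical(union_interactomes(list(n1, n1))$edges, n1$edges)
  ## edge-disjoint nets add up
  n3 <- build_interactome(data.frame(a = "X", b = "Y", s = "z"))
  expect_equal(n_edges(union_interactomes(list(n1, n3))), n_edges(n1) + 1L)
})

test_that("union is commutative and associative up to provenance tags", {
  set.seed(17)
  nets <- lapply(1:3, function(i) {
    n <- random_net(20, 0.25, name = paste0("net", i))
    n$edges$sources <- paste0("net", i)
    n
  })
  u1 <- union_interactomes(nets)
  u2 <- union_interactomes(rev(nets))
  u3 <- union_interactomes(list(union_interactomes(nets[1:2]), nets[[3]]))
  expect_identical(u1$edges, u2$edges)
  expect_identical(u1$edges, u3$edges)
  ## per-source tag counts match brute-force counting over raw edge lists
  all_keys <- lapply(nets, edge_keys)
  k_count <- table(table(unlist(all_keys)))
  ov <- attr(u1, "source_overlap")
  expect_equal(as.integer(ov[names(k_count)]), as.integer(k_count))
})

test_that("topology closed forms hold on path and star graphs", {
  m <- compute_topology(path_net(c("A", "B", "C")))
  b <- m[m$node == "B", ]
  expect_equal(b$betweenness, 1.0)
  expect_equal(b$degree, 2L)
  expect_equal(b$closeness, 1.0)
  expect_equal(m$betweenness[m$node == "A"], 0)

  s <- compute_topology(star_net(5))
  expect_equal(s$betweenness[s$node == "CENTER"], 1.0)
  expect_true(all(s$betweenness[s$node != "CENTER"] == 0))
  expect_equal(s$closeness[s$node == "CENTER"], 1.0)
})

test_that("Brandes metrics match igraph and the path-enumeration oracle", {
  set.seed(47)
  for (i in 1:25) {
    net <- random_net(sample(4:8, 1), stats::runif(1, 0.2, 0.6))
    m <- compute_topology(net)
    o <- oracle_centrality(net)
    expect_equal(m$betweenness, o$betweenness, tolerance = 1e-12)
    expect_equal(m$closeness, o$closeness, tolerance = 1e-12)
    if (n_edges(net) > 0L) {
      ig <- as_igraph(net)
      expect_equal(m$betweenness_raw,
                   unname(igraph::betweenness(ig, directed = FALSE))[match(net$nodes, igraph::V(ig)$name)],
                   tolerance = 1e-10)
    }
  }
})

test_that("closeness of isolated nodes is 0 and degree sums obey the handshake", {
  net <- build_interactome(data.frame(a = "A", b = "B"))
  net$nodes <- c("A", "B", "LONER")
  m <- compute_topology(net)
  expect_equal(m$closeness[m$node == "LONER"], 0)
  expect_equal(sum(m$degree), 2L * n_edges(net))
  ## complete graph: all betweenness zero
  k4 <- build_interactome(t(utils::combn(c("A", "B", "C", "D"), 2)))
  expect_true(all(compute_topology(k4)$betweenness == 0))
})

test_that("top_hubs ranks by degree, betweenness, then name", {
  s <- compute_topology(star_net(4))
  expect_equal(top_hubs(s, 1), "CENTER")
  ## two nodes tied on degree and betweenness: lexicographic order decides
  sq <- build_interactome(data.frame(a = c("A", "B", "C", "D"),
                                     b = c("B", "C", "D", "A")))
  m <- compute_topology(sq)
  expect_equal(top_hubs(m, 2), c("A", "B"))
  expect_warning(all_nodes <- top_hubs(m, 99), "exceeds")
  expect_length(all_nodes, 4L)
})

test_that("power-law exponent recovery and BA degree-tail behaviour", {
  set.seed(99)
  x <- rpowerlaw(5000, alpha = 2.5, xmin = 2)
  fit <- fit_power_law(x)
  expect_lt(abs(fit$exponent - 2.5), 0.2)
  expect_gt(fit$exponent, 1)

  ## BA with attachment 1 yields a tree
  tree <- generate_interactome(5, attachment = 1, seed = 1)
  expect_equal(n_edges(tree), 4L)
})
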