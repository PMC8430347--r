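## Small graph and table builders used across tests.

net_from_pairs <- function(...) {
  pairs <- list(...)
  df <- data.frame(a = vapply(pairs, `[`, "", 1L),
                   b = vapply(pairs, `[`, "", 2L))
  build_interactome(df, name = "fixture")
}

path_net <- function(nodes = c("A", "B", "C")) {
  df <- data.frame(a = nodes[-length(nodes)], b = nodes[-1L])
  build_interactome(df, name = "path")
}

star_net <- function(n_leaves = 5L) {
  df <- data.frame(a = "CENTER", b = sprintf("LEAF%02d", seq_len(n_leaves)))
  build_interactome(df, name = "star")
}

## Erdos-Renyi-style random simple graph over `n` named nodes.
random_net <- function(n, p = 0.35, name = "random") {
  nodes <- sprintf("V%02d", seq_len(n))
  pairs <- t(utils::combn(n, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  df <- data.frame(a = nodes[pairs[keep, 1L]], b = nodes[pairs[keep, 2L]])
  net <- build_interactome(df, name = name)
  net$nodes <- nodes  # keep isolated nodes
  net
}

random_expression <- function(genes, tissue = "tissue1") {
  expression_profile(data.frame(
    gene = genes, tissue = tissue,
    tpm = stats::rlnorm(length(genes), 2, 1),
    protein_level = sample(c("negative", "weak", "moderate", "high"),
                           length(genes), replace = TRUE)))
}
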