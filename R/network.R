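## Physical protein-protein interaction networks: simple undirected graphs
## with per-edge provenance tags, induced subgraphs ("local" networks of a
## gene panel), interactome unions, and exact topology metrics.

new_interactome <- function(nodes, edges, name = "interactome") {
  nodes <- sort(unique(as.character(nodes)))
  stopifnot(is.data.frame(edges), all(c("a", "b", "sources") %in% names(edges)))
  if (nrow(edges) > 0L) {
    stopifnot(all(edges$a %in% nodes), all(edges$b %in% nodes), all(edges$a < edges$b))
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  }
  rownames(edges) <- NULL
  structure(list(name = name, nodes = nodes, edges = edges),
            class = "interactome")
}

#' Build an interactome from raw interaction rows
#'
#' Rows are canonicalized to unordered pairs; self-loops and duplicate pairs
#' are dropped (counts kept in attributes `n_self_loops` / `n_duplicates`),
#' provenance tags of duplicates are merged. Malformed rows (missing or
#' empty endpoint) are rejected per row with their line numbers.
#'
#' @param rows data frame (or 2-column matrix) whose first two columns are
#'   interactor identifiers; an optional third column carries a provenance
#'   tag per row.
#' @param name network name.
#' @param default_source provenance tag used when `rows` has no third column.
#' @return an `interactome`: list with `name`, sorted `nodes`, and an edge
#'   table `edges` (`a` < `b` lexicographically, `sources` =
#'   `;`-joined sorted tags).
#' @export
build_interactome <- function(rows, name = "interactome", default_source = name) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (nrow(rows) == 0L) {
    return(structure(new_interactome(character(0),
                                     data.frame(a = character(0), b = character(0),
                                                sources = character(0)),
                                     name),
                     n_self_loops = 0L, n_duplicates = 0L, class = "interactome"))
  }
  if (ncol(rows) < 2L) stop("interaction rows need two identifier columns")
  a <- canonical_symbol(rows[[1L]])
  b <- canonical_symbol(rows[[2L]])
  src <- if (ncol(rows) >= 3L) as.character(rows[[3L]]) else rep(default_source, length(a))
  src[is.na(src) | !nzchar(src)] <- default_source
  bad <- is.na(a) | is.na(b) | !nzchar(a) | !nzchar(b)
  if (any(bad)) {
    warning(sprintf("rejected %d malformed row(s) at line(s): %s", sum(bad),
                    paste(utils::head(which(bad), 10L), collapse = ", ")))
    a <- a[!bad]; b <- b[!bad]; src <- src[!bad]
  }
  loop <- a == b
  n_loops <- sum(loop)
  a <- a[!loop]; b <- b[!loop]; src <- src[!loop]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\t")
  n_dup <- sum(duplicated(key))
  merged <- tapply(src, key, function(s) paste(sort(unique(s)), collapse = ";"))
  keys <- sort(names(merged))
  parts <- strsplit(keys, "\t", fixed = TRUE)
  edges <- data.frame(a = vapply(parts, `[`, "", 1L),
                      b = vapply(parts, `[`, "", 2L),
                      sources = as.character(merged[keys]),
                      stringsAsFactors = FALSE)
  out <- new_interactome(unique(c(edges$a, edges$b)), edges, name)
  attr(out, "n_self_loops") <- n_loops
  attr(out, "n_duplicates") <- n_dup
  out
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("interactome '%s': %d nodes, %d edges\n",
              x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of edges of an interactome
#' @param net an `interactome`.
#' @return integer edge count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' Canonical edge keys of an interactome
#' @param net an `interactome`.
#' @return character vector of [edge_key()] values, one per edge.
#' @export
edge_keys <- function(net) {
  if (nrow(net$edges) == 0L) character(0) else edge_key(net$edges$a, net$edges$b)
}

#' Induced subgraph of an interactome on a gene panel
#'
#' Nodes are the intersection of the panel with the network's nodes; edges
#' are those with both endpoints retained. Panel genes absent from the
#' network are simply unmatched.
#'
#' @param net an `interactome`.
#' @param panel character vector of node identifiers.
#' @param name optional name of the result.
#' @return an `interactome`.
#' @export
induced_subgraph <- function(net, panel, name = paste0(net$name, "::subgraph")) {
  stopifnot(inherits(net, "interactome"))
  panel <- unique(as.character(panel))
  keep_nodes <- intersect(net$nodes, panel)
  e <- net$edges[net$edges$a %in% keep_nodes & net$edges$b %in% keep_nodes, ,
                 drop = FALSE]
  new_interactome(keep_nodes, e, name)
}

#' Union of interactomes with merged provenance
#'
#' Node and edge sets are unioned; provenance tags are merged per edge.
#' The attribute `source_overlap` counts, for each count k, the edges whose
#' merged provenance carries exactly k distinct tags (the per-source edge
#' overlap summary of a combined interactome).
#'
#' @param nets list of `interactome` objects sharing an identifier namespace.
#' @param name name of the union.
#' @return an `interactome` with a `source_overlap` attribute.
#' @export
union_interactomes <- function(nets, name = "union") {
  stopifnot(is.list(nets), length(nets) >= 1L,
            all(vapply(nets, inherits, TRUE, "interactome")))
  all_edges <- do.call(rbind, lapply(nets, function(n) n$edges))
  all_nodes <- unique(unlist(lapply(nets, function(n) n$nodes)))
  if (is.null(all_edges) || nrow(all_edges) == 0L) {
    out <- new_interactome(all_nodes,
                           data.frame(a = character(0), b = character(0),
                                      sources = character(0)), name)
    attr(out, "source_overlap") <- integer(0)
    return(out)
  }
  key <- paste(all_edges$a, all_edges$b, sep = "\t")
  tags <- tapply(all_edges$sources, key, function(s) {
    paste(sort(unique(unlist(strsplit(s, ";", fixed = TRUE)))), collapse = ";")
  })
  keys <- sort(names(tags))
  parts <- strsplit(keys, "\t", fixed = TRUE)
  edges <- data.frame(a = vapply(parts, `[`, "", 1L),
                      b = vapply(parts, `[`, "", 2L),
                      sources = as.character(tags[keys]),
                      stringsAsFactors = FALSE)
  out <- new_interactome(all_nodes, edges, name)
  ntags <- lengths(strsplit(edges$sources, ";", fixed = TRUE))
  attr(out, "source_overlap") <- table(factor(ntags, levels = seq_len(max(ntags))))
  out
}

#' Convert an interactome to an igraph graph
#' @param net an `interactome`.
#' @return an undirected [igraph::graph] with the same nodes and edges.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "interactome"))
  igraph::graph_from_data_frame(net$edges[, c("a", "b"), drop = FALSE],
                                directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

## Integer adjacency list of an interactome.
adjacency_list <- function(net) {
  n <- length(net$nodes)
  idx <- seq_len(n)
  names(idx) <- net$nodes
  adj <- vector("list", n)
  for (i in idx) adj[[i]] <- integer(0)
  if (nrow(net$edges) > 0L) {
    ia <- idx[net$edges$a]
    ib <- idx[net$edges$b]
    for (k in seq_along(ia)) {
      adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
      adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
    }
  }
  adj
}

#' Exact network topology metrics
#'
#' Degree, betweenness centrality and closeness centrality for every node of
#' an undirected unweighted graph. Betweenness uses Brandes' shortest-path
#' dependency accumulation; the normalized value divides by
#' `(n-1)(n-2)/2`, the number of node pairs excluding the focal node.
#' Closeness is computed within each node's connected component as
#' `(r-1)/sum(d)` over the `r-1` reachable nodes and scaled by
#' `(r-1)/(n-1)` (Wasserman-Faust), so isolated nodes score 0 and the
#' values stay comparable across components.
#'
#' @param net an `interactome`.
#' @return data frame with columns `node`, `degree`, `betweenness`
#'   (normalized), `betweenness_raw`, `closeness`.
#' @export
compute_topology <- function(net) {
  stopifnot(inherits(net, "interactome"))
  n <- length(net$nodes)
  if (n == 0L) {
    return(data.frame(node = character(0), degree = integer(0),
                      betweenness = numeric(0), betweenness_raw = numeric(0),
                      closeness = numeric(0)))
  }
  adj <- adjacency_list(net)
  deg <- lengths(adj)
  bc <- numeric(n)
  cc <- numeric(n)
  for (s in seq_len(n)) {
    ## BFS from s with shortest-path counts
    dist <- rep.int(-1L, n)
    sigma <- numeric(n)
    preds <- vector("list", n)
    dist[s] <- 0L
    sigma[s] <- 1
    queue <- integer(n)
    queue[1L] <- s
    qh <- 1L; qt <- 1L
    order_visited <- integer(n)
    nv <- 0L
    while (qh <= qt) {
      v <- queue[qh]; qh <- qh + 1L
      nv <- nv + 1L
      order_visited[nv] <- v
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          qt <- qt + 1L
          queue[qt] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    ## closeness of s from this BFS
    reach <- nv
    if (reach > 1L) {
      sumd <- sum(dist[order_visited[seq_len(nv)]])
      cc[s] <- ((reach - 1) / sumd) * ((reach - 1) / (n - 1))
    }
    ## dependency accumulation in reverse BFS order
    delta <- numeric(n)
    for (i in rev(seq_len(nv))) {
      w <- order_visited[i]
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + (sigma[v] / sigma[w]) * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc_raw <- bc / 2  # each undirected pair counted twice
  bc_norm <- if (n > 2L) bc_raw / ((n - 1) * (n - 2) / 2) else rep(0, n)
  data.frame(node = net$nodes, degree = as.integer(deg),
             betweenness = bc_norm, betweenness_raw = bc_raw,
             closeness = cc, stringsAsFactors = FALSE)
}

#' Top hub nodes of a network
#'
#' Ranks nodes by descending degree, then descending betweenness, then
#' ascending node name (a deterministic tie-break), and returns the top `k`.
#'
#' @param metrics output of [compute_topology()].
#' @param k number of hubs (>= 1); `k` beyond the node count returns all
#'   nodes with a warning.
#' @return character vector of hub node names, ranked.
#' @export
top_hubs <- function(metrics, k = 10L) {
  stopifnot(is.data.frame(metrics), k >= 1)
  if (k > nrow(metrics)) {
    warning(sprintf("k = %d exceeds node count (%d); returning all nodes",
                    k, nrow(metrics)))
    k <- nrow(metrics)
  }
  ord <- order(-metrics$degree, -metrics$betweenness, metrics$node)
  metrics$node[ord][seq_len(k)]
}
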