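## Independent oracles: exhaustive all-shortest-paths centrality (via
## igraph path enumeration, a code path disjoint from the package's Brandes
## implementation) and exact rational-arithmetic hypergeometric tail
## probabilities (big-integer arithmetic through the system python).

## Betweenness/closeness by explicit enumeration of every shortest path.
oracle_centrality <- function(net) {
  g <- as_igraph(net)
  nodes <- net$nodes
  n <- length(nodes)
  d <- igraph::distances(g)
  bc <- stats::setNames(numeric(n), nodes)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s >= t || !is.finite(d[s, t]) || d[s, t] == 0) next
      paths <- suppressWarnings(
        igraph::all_shortest_paths(g, from = s, to = t)$vpaths)
      w <- 1 / length(paths)
      for (p in paths) {
        inner <- as.integer(p)[-c(1L, length(p))]
        if (length(inner) > 0L) bc[inner] <- bc[inner] + w
      }
    }
  }
  bc_norm <- if (n > 2L) bc / ((n - 1) * (n - 2) / 2) else bc * 0
  cc <- vapply(seq_len(n), function(v) {
    dv <- d[v, ]
    reach <- sum(is.finite(dv))        # includes v itself
    if (reach <= 1L) return(0)
    ((reach - 1) / sum(dv[is.finite(dv) & dv > 0])) * ((reach - 1) / (n - 1))
  }, numeric(1))
  data.frame(node = nodes, betweenness = unname(bc_norm),
             closeness = cc, stringsAsFactors = FALSE)
}

## Exact hypergeometric upper-tail oracle: reads lines "N K n p_k0 p_k1 ..."
## and reports the maximum relative error of the given p-values against
## exact big-integer ratios.
exact_hypergeom_py <- '
import sys
from math import comb

worst = 0.0
with open(sys.argv[1]) as fh:
    for line in fh:
        parts = line.split()
        N, K, n = int(parts[0]), int(parts[1]), int(parts[2])
        vals = [float(x) for x in parts[3:]]
        den = comb(N, n)
        pmf = [comb(K, j) * comb(N - K, n - j) for j in range(min(n, K) + 1)]
        tail = [0] * (len(pmf) + 1)
        for j in range(len(pmf) - 1, -1, -1):
            tail[j] = tail[j + 1] + pmf[j]
        for k, v in enumerate(vals):
            exact = tail[k] / den
            err = abs(v - exact) / exact
            if err > worst:
                worst = err
print(repr(worst))
'

## Max relative error of hypergeom_pvalue() against the exact oracle over
## every configuration with N <= n_max.
hypergeom_max_rel_error <- function(n_max = 60L) {
  lines <- vector("list", sum((seq_len(n_max) + 1L)^2))
  i <- 0L
  for (N in seq_len(n_max)) {
    for (K in 0:N) {
      for (n in 0:N) {
        k <- 0:min(n, K)
        p <- hypergeom_pvalue(k, n, K, N)
        i <- i + 1L
        lines[[i]] <- paste(c(N, K, n, sprintf("%.17g", p)), collapse = " ")
      }
    }
  }
  lines <- unlist(lines[seq_len(i)])
  dat <- tempfile(fileext = ".txt")
  py <- tempfile(fileext = ".py")
  on.exit(unlink(c(dat, py)))
  writeLines(lines, dat)
  writeLines(exact_hypergeom_py, py)
  out <- system2("python", c(py, dat), stdout = TRUE)
  as.numeric(out[length(out)])
}
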