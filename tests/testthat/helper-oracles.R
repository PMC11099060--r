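# Independent oracles used across the suite. Deliberately written with
# plain-R loops (no igraph, no package internals) so they check the
# implementation rather than restate it.

# All-pairs shortest-path distances by breadth-first search on an
# undirected edge tibble. Returns a named matrix; Inf for unreachable.
bfs_all_pairs <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  d <- matrix(Inf, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (s in nodes) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    d[s, ] <- dist
  }
  d
}

# Mean distance between two sets under the package's pair convention
# (a != b; intra-group = unordered distinct pairs), from a BFS matrix.
oracle_set_distance <- function(d, A, B) {
  tot <- 0; np <- 0L
  for (a in A) for (b in B) {
    if (a == b) next
    tot <- tot + d[a, b]; np <- np + 1L
  }
  tot / np
}

# Random Erdos-Renyi edge tibble over given node names.
random_edges <- function(nodes, p) {
  cmb <- utils::combn(nodes, 2L)
  hit <- stats::runif(ncol(cmb)) < p
  tibble::tibble(from = cmb[1L, hit], to = cmb[2L, hit])
}

# Random multiplex with L independent G(n, p) layers; ensures at least one
# edge overall.
random_multiplex <- function(n, L, p) {
  nodes <- sprintf("N%02d", seq_len(n))
  repeat {
    layers <- lapply(seq_len(L), function(l) {
      layer_from_edges(random_edges(nodes, p), paste0("l", l))
    })
    if (sum(vapply(layers, nrow, integer(1))) > 0L) break
  }
  build_multiplex(layers)
}

# Dense linear-algebra RWR oracle. Builds the (node, layer) transition
# matrix entry by entry with explicit loops and solves the stationary
# system directly. Nodes isolated in a layer can only relocate; nodes
# isolated everywhere restart from the seed distribution.
dense_rwr_oracle <- function(mx, seeds, restart = 0.7, delta = 0.5) {
  nodes <- mx$nodes
  n <- length(nodes)
  L <- length(mx$layers)
  if (L == 1L) delta <- 0
  N <- n * L
  idx <- function(i, l) (l - 1L) * n + i
  neigh <- lapply(seq_len(L), function(l) {
    e <- mx$layers[[l]]
    out <- stats::setNames(vector("list", n), nodes)
    for (r in seq_len(nrow(e))) {
      out[[e$from[r]]] <- c(out[[e$from[r]]], e$to[r])
      out[[e$to[r]]] <- c(out[[e$to[r]]], e$from[r])
    }
    out
  })
  deg <- sapply(seq_len(L), function(l) {
    vapply(nodes, function(v) length(neigh[[l]][[v]]), integer(1))
  })
  deg <- matrix(deg, nrow = n)
  dangling <- rowSums(deg) == 0L
  s <- numeric(N)
  for (l in seq_len(L)) s[idx(match(seeds, nodes), l)] <- 1
  s <- s / sum(s)
  Tm <- matrix(0, N, N)
  for (i in seq_len(n)) for (l in seq_len(L)) {
    col <- idx(i, l)
    if (dangling[i]) { Tm[, col] <- s; next }
    di <- deg[i, l]
    walk_share <- if (di > 0) (if (L > 1L) 1 - delta else 1) else 0
    reloc_share <- 1 - walk_share
    if (di > 0) {
      for (nb in neigh[[l]][[nodes[i]]]) {
        Tm[idx(match(nb, nodes), l), col] <-
          Tm[idx(match(nb, nodes), l), col] + walk_share / di
      }
    }
    if (L > 1L && reloc_share > 0) {
      for (m in seq_len(L)) {
        if (m == l) next
        Tm[idx(i, m), col] <- Tm[idx(i, m), col] + reloc_share / (L - 1L)
      }
    }
  }
  p <- solve(diag(N) - (1 - restart) * Tm, restart * s)
  node_scores <- vapply(seq_len(n), function(i) {
    mean(p[idx(i, seq_len(L))])
  }, double(1))
  stats::setNames(node_scores / sum(node_scores), nodes)
}

# Exhaustive-enumeration upper tail of the hypergeometric distribution.
hyper_tail_enum <- function(k, n, K, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Ground-truth group labels of a bundle, restricted to a network.
truth_labels <- function(bundle, lcc) {
  tr <- truth_report(bundle)
  tr <- tr[tr$gene %in% lcc$nodes, ]
  tibble::tibble(gene = tr$gene, group = tr$group)
}

# Tiny convenience: aggregated network from an edge tibble.
toy_net <- function(edges, name = "l1") {
  aggregate_multiplex(build_multiplex(list(layer_from_edges(edges, name))))
}

path_edges <- function(nodes) {
  tibble::tibble(from = nodes[-length(nodes)], to = nodes[-1L])
}

complete_edges <- function(nodes) {
  cmb <- utils::combn(nodes, 2L)
  tibble::tibble(from = cmb[1L, ], to = cmb[2L, ])
}
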