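#' Random-walk-with-restart configuration
#'
#' @param restart Restart probability in (0, 1]; default 0.7.
#' @param interlayer_jump Probability that the walker relocates to another
#'   layer's copy of its current node instead of walking within its layer;
#'   default 0.5. Ignored for single-layer networks.
#' @param tol Convergence threshold on the L1 change between iterations.
#' @param max_iter Maximum number of power iterations.
#' @param aggregation How a node's layer-copy probabilities are combined
#'   into its score; the mean (rank-equivalent to the sum).
#' @return An `rwr_config` list.
#' @export
rwr_config <- function(restart = 0.7, interlayer_jump = 0.5, tol = 1e-10,
                       max_iter = 1000L,
                       aggregation = c("mean_over_layers")) {
  aggregation <- match.arg(aggregation)
  stopifnot(restart > 0, restart <= 1,
            interlayer_jump >= 0, interlayer_jump <= 1,
            tol > 0, max_iter >= 1L)
  structure(list(restart = restart, interlayer_jump = interlayer_jump,
                 tol = tol, max_iter = as.integer(max_iter),
                 aggregation = aggregation),
            class = "rwr_config")
}

# Supra-transition structure of a multiplex network. States are (node,
# layer) pairs indexed (l - 1) * n + i over the sorted node vector. The
# returned matrix is column-stochastic except for dangling states (nodes
# isolated in every layer), whose columns are zero; walkers there are
# redirected to the restart distribution by the solvers.
supra_transition <- function(mx, cfg = rwr_config()) {
  stopifnot(inherits(mx, "multiplex"))
  nodes <- mx$nodes
  n <- length(nodes)
  L <- length(mx$layers)
  delta <- if (L > 1L) cfg$interlayer_jump else 0
  deg <- matrix(0L, n, L, dimnames = list(nodes, names(mx$layers)))
  walk_blocks <- vector("list", L)
  for (l in seq_len(L)) {
    e <- mx$layers[[l]]
    i <- match(e$from, nodes); j <- match(e$to, nodes)
    A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(n, n))
    d <- Matrix::colSums(A)
    deg[, l] <- as.integer(d)
    inv <- ifelse(d > 0, 1 / d, 0)
    walk_blocks[[l]] <- A %*% Matrix::Diagonal(n, inv)  # column-stochastic where d > 0
  }
  dangling_node <- rowSums(deg) == 0L
  # assemble the nL x nL supra matrix
  blocks <- matrix(list(), L, L)
  zero <- Matrix::sparseMatrix(i = integer(), j = integer(), x = double(),
                               dims = c(n, n))
  for (l in seq_len(L)) {
    iso <- deg[, l] == 0L & !dangling_node
    # within-layer walk keeps (1 - delta); columns with no neighbours put
    # everything into relocation
    w <- Matrix::Diagonal(n, ifelse(deg[, l] > 0, 1 - delta, 0))
    if (L == 1L) w <- Matrix::Diagonal(n, ifelse(deg[, l] > 0, 1, 0))
    blocks[[l, l]] <- walk_blocks[[l]] %*% w
    if (L > 1L) {
      reloc <- ifelse(dangling_node, 0, ifelse(deg[, l] > 0, delta, 1)) / (L - 1)
      for (m in seq_len(L)) {
        if (m == l) next
        blocks[[m, l]] <- Matrix::Diagonal(n, reloc)
      }
    }
  }
  for (l in seq_len(L)) for (m in seq_len(L)) {
    if (is.null(blocks[[m, l]])) blocks[[m, l]] <- zero
  }
  rows <- lapply(seq_len(L), function(m) {
    do.call(cbind, lapply(seq_len(L), function(l) blocks[[m, l]]))
  })
  Tm <- do.call(rbind, rows)
  dangling_states <- rep(dangling_node, L)
  list(T = methods::as(Tm, "CsparseMatrix"), nodes = nodes, n = n, L = L,
       dangling = dangling_states)
}

# restart distribution: uniform over seed nodes x layers
restart_vector <- function(st, seeds) {
  idx <- match(seeds, st$nodes)
  s <- numeric(st$n * st$L)
  for (l in seq_len(st$L)) s[(l - 1L) * st$n + idx] <- 1
  s / sum(s)
}

aggregate_states <- function(st, p) {
  m <- matrix(p, nrow = st$n, ncol = st$L)
  sc <- rowMeans(m)
  sc / sum(sc)
}

#' Multiplex random walk with restart
#'
#' Computes the stationary visitation probabilities of a walker that, at
#' each step, restarts from the seed set with probability `restart` and
#' otherwise moves on the supra-graph of (node, layer) states: it either
#' walks to a uniformly chosen within-layer neighbour or, with probability
#' `interlayer_jump`, relocates to another layer's copy of its current node.
#' Nodes isolated in a layer can only relocate; nodes isolated in every
#' layer send the walker back to the seeds. A single-layer multiplex
#' reduces to standard random walk with restart on that graph. A node's
#' score is the mean of its layer-copy probabilities, renormalized to sum
#' to 1.
#'
#' @param mx A `multiplex` object (typically its largest connected
#'   component).
#' @param seeds Character vector of seed genes; seeds absent from the
#'   network are reported and dropped.
#' @param cfg An [rwr_config()].
#' @param engine `"power"` iterates to the fixed point (default);
#'   `"direct"` solves the linear system densely (practical up to a few
#'   thousand states).
#' @return An `rwr_scores` object: tibble with columns `gene`, `score`,
#'   `is_seed`, `rank`, and attributes `seeds`, `converged`, `iterations`,
#'   `config`.
#' @export
rwr_multiplex <- function(mx, seeds, cfg = rwr_config(),
                          engine = c("power", "direct")) {
  engine <- match.arg(engine)
  seeds <- as_gene_set(seeds, "seeds")
  dropped <- setdiff(seeds, mx$nodes)
  if (length(dropped) > 0L) {
    message("seeds not in network, dropped: ", paste(dropped, collapse = ", "))
  }
  seeds <- intersect(seeds, mx$nodes)
  if (length(seeds) == 0L) stop("no seed gene present in the network")
  st <- supra_transition(mx, cfg)
  s <- restart_vector(st, seeds)
  r <- cfg$restart
  if (engine == "direct") {
    p <- rwr_direct_solve(st, s, r)
    converged <- TRUE
    iterations <- 0L
  } else {
    p <- s
    converged <- FALSE
    iterations <- cfg$max_iter
    for (it in seq_len(cfg$max_iter)) {
      dangling_mass <- sum(p[st$dangling])
      p_new <- r * s + (1 - r) * (as.numeric(st$T %*% p) + dangling_mass * s)
      if (sum(abs(p_new - p)) < cfg$tol) {
        p <- p_new; converged <- TRUE; iterations <- it
        break
      }
      p <- p_new
    }
    if (!converged) {
      warning("random walk did not converge within ", cfg$max_iter,
              " iterations (returning last iterate)")
    }
  }
  scores <- aggregate_states(st, p)
  new_rwr_scores(st$nodes, scores, seeds, cfg, converged, iterations)
}

# dense solve of p = r s + (1 - r) (T p + (d' p) s)
rwr_direct_solve <- function(st, s, r) {
  N <- st$n * st$L
  M <- as.matrix(st$T)
  if (any(st$dangling)) {
    M <- M + s %*% t(as.numeric(st$dangling))
  }
  as.numeric(solve(diag(N) - (1 - r) * M, r * s))
}

new_rwr_scores <- function(nodes, scores, seeds, cfg, converged, iterations) {
  tab <- tibble::tibble(gene = nodes, score = scores,
                        is_seed = nodes %in% seeds) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(tab, class = c("rwr_scores", class(tab)),
            seeds = seeds, converged = converged,
            iterations = iterations, config = cfg)
}

#' @export
tidy.rwr_scores <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.rwr_scores <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    n_genes = nrow(x),
    n_seeds = length(attr(x, "seeds")),
    restart = cfg$restart,
    converged = attr(x, "converged"),
    iterations = attr(x, "iterations"),
    score_sum = sum(x$score)
  )
}

#' Top-k network neighborhood of a seed group
#'
#' Ranks non-seed genes by decreasing visitation score (ties broken
#' lexicographically by gene symbol) and returns the top `k`. The run's own
#' seed genes are excluded; other groups' genes may appear.
#'
#' @param sv An `rwr_scores` object.
#' @param k Neighborhood size (default 50).
#' @param seed_group Optional label for the seed group, carried in the
#'   result.
#' @return An `rwr_neighborhood`: tibble with `gene`, `score`, `rank`
#'   (rank among non-seed genes), attributes `k`, `seed_group`, `seeds`.
#' @export
extract_neighborhood <- function(sv, k = 50L, seed_group = NULL) {
  stopifnot(inherits(sv, "rwr_scores"), k >= 1L)
  nonseed <- tibble::as_tibble(sv)[!sv$is_seed, c("gene", "score")]
  nonseed <- dplyr::arrange(nonseed, dplyr::desc(.data$score), .data$gene)
  out <- utils::head(nonseed, k)
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("rwr_neighborhood", class(out)),
            k = as.integer(k), seed_group = seed_group,
            seeds = attr(sv, "seeds"))
}

#' @export
print.rwr_neighborhood <- function(x, ...) {
  cat("RWR neighborhood", if (!is.null(attr(x, "seed_group")))
    paste0("of ", attr(x, "seed_group")), "- top", nrow(x), "genes\n")
  print(tibble::as_tibble(x), n = 10)
  invisible(x)
}

#' Write a full score table as TSV
#'
#' @param sv An `rwr_scores` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rwr_scores <- function(sv, path) {
  readr::write_tsv(tibble::as_tibble(sv), path, progress = FALSE)
  invisible(path)
}
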