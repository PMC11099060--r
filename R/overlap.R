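#' Size of the intersection of two neighborhoods
#'
#' @param nA,nB `rwr_neighborhood` objects (or character vectors of genes).
#' @return Integer intersection size.
#' @export
neighborhood_overlap <- function(nA, nB) {
  ga <- if (is.character(nA)) nA else nA$gene
  gb <- if (is.character(nB)) nB else nB$gene
  length(intersect(ga, gb))
}

#' Precompute the RWR propagation kernel of a multiplex network
#'
#' Solves the fixed point once for all possible restart distributions: the
#' returned object maps any seed set to its node scores by a single
#' matrix-vector product. Used to make label-randomization tests (hundreds
#' of walks on the same network) affordable; the scores are identical to a
#' converged [rwr_multiplex()] run. Requires a network with no node
#' isolated in every layer (always true on a connected component).
#'
#' @param mx A `multiplex` object.
#' @param cfg An [rwr_config()].
#' @return An `rwr_kernel` object.
#' @export
rwr_kernel <- function(mx, cfg = rwr_config()) {
  st <- supra_transition(mx, cfg)
  if (any(st$dangling)) {
    stop("kernel requires a network without fully isolated nodes; ",
         "extract the largest connected component first")
  }
  N <- st$n * st$L
  K <- solve(diag(N) - (1 - cfg$restart) * as.matrix(st$T))
  # collapse layer copies: M[i, ] = sum over layers of K[(l-1)n + i, ]
  M <- matrix(0, st$n, N)
  for (l in seq_len(st$L)) {
    M <- M + K[(l - 1L) * st$n + seq_len(st$n), , drop = FALSE]
  }
  structure(list(M = M, nodes = st$nodes, n = st$n, L = st$L, config = cfg),
            class = "rwr_kernel")
}

# node scores (summing layer copies, normalized) for a seed set via kernel
kernel_scores <- function(kern, seeds) {
  idx <- match(seeds, kern$nodes)
  if (anyNA(idx)) stop("seed genes missing from kernel network")
  cols <- as.vector(outer(idx, (seq_len(kern$L) - 1L) * kern$n, `+`))
  sc <- rowSums(kern$M[, cols, drop = FALSE])
  stats::setNames(sc / sum(sc), kern$nodes)
}

# top-k non-seed genes by score, ties broken lexicographically
top_k_genes <- function(nodes, scores, seeds, k) {
  keep <- !(nodes %in% seeds)
  g <- nodes[keep]; s <- scores[keep]
  ord <- order(-s, g)
  g[ord][seq_len(min(k, length(g)))]
}

#' Label-randomization test of neighborhood overlap
#'
#' Computes the overlap between the top-`k` RWR neighborhoods seeded by two
#' gene groups, then permutes the group labels over the labeled,
#' network-present genes `n_rand` times (all labels permuted jointly, so
#' every group reshuffles), recomputing both neighborhoods and their
#' overlap each time. The reported `p_low` is the fraction of permutations
#' whose overlap is less than or equal to the observed one — small values
#' mean the real neighborhoods share fewer genes than expected for
#' arbitrary label assignments.
#'
#' @param mx A `multiplex` object (use the largest connected component).
#' @param labels A data frame with columns `gene`, `group`, or a named
#'   character vector of group labels. Genes absent from the network are
#'   dropped with a message.
#' @param group_a,group_b The two group labels whose neighborhoods are
#'   compared.
#' @param k Neighborhood size (default 50).
#' @param n_rand Number of label permutations (default 1000).
#' @param cfg An [rwr_config()].
#' @param rng_seed Integer seed for the permutations.
#' @return An `overlap_test` object: list with `real_overlap`, `p_low`,
#'   `n_randomizations`, `rng_seed`, `null_overlaps`, `k`, and the real
#'   neighborhoods.
#' @export
label_randomization_test <- function(mx, labels, group_a, group_b,
                                     k = 50L, n_rand = 1000L,
                                     cfg = rwr_config(), rng_seed = 42L) {
  lab <- normalize_labels(labels)
  absent <- setdiff(lab$gene, mx$nodes)
  if (length(absent) > 0L) {
    message("labeled genes not in network, dropped: ",
            paste(absent, collapse = ", "))
    lab <- lab[!lab$gene %in% absent, ]
  }
  stopifnot(group_a %in% lab$group, group_b %in% lab$group)
  kern <- rwr_kernel(mx, cfg)

  nb_for <- function(seeds) {
    top_k_genes(kern$nodes, kernel_scores(kern, seeds), seeds, k)
  }
  seeds_a <- lab$gene[lab$group == group_a]
  seeds_b <- lab$gene[lab$group == group_b]
  nb_a <- nb_for(seeds_a)
  nb_b <- nb_for(seeds_b)
  real <- length(intersect(nb_a, nb_b))

  redraws <- 0L
  nulls <- withr::with_seed(rng_seed, {
    vapply(seq_len(n_rand), function(i) {
      repeat {
        perm <- sample(lab$group)
        pa <- lab$gene[perm == group_a]
        pb <- lab$gene[perm == group_b]
        if (length(pa) > 0L && length(pb) > 0L) break
        redraws <<- redraws + 1L
      }
      length(intersect(nb_for(pa), nb_for(pb)))
    }, double(1))
  })
  if (redraws > 0L) message(redraws, " permutation(s) redrawn (empty group)")
  structure(list(real_overlap = real,
                 p_low = sum(nulls <= real) / n_rand,
                 n_randomizations = as.integer(n_rand),
                 rng_seed = as.integer(rng_seed),
                 null_overlaps = as.integer(nulls),
                 k = as.integer(k),
                 group_a = group_a, group_b = group_b,
                 neighborhood_a = nb_a, neighborhood_b = nb_b),
            class = "overlap_test")
}

normalize_labels <- function(labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("gene", "group") %in% names(labels)))
    out <- tibble::tibble(gene = canonicalize_symbols(labels$gene,
                                                      drop_empty = FALSE),
                          group = as.character(labels$group))
  } else {
    stopifnot(!is.null(names(labels)))
    out <- tibble::tibble(gene = canonicalize_symbols(names(labels),
                                                      drop_empty = FALSE),
                          group = as.character(labels))
  }
  if (anyDuplicated(out$gene)) stop("duplicate gene labels")
  out
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "Neighborhood overlap test (%s vs %s, k = %d)\n  real overlap: %d\n  p_low (null <= real): %.4g  [%d randomizations]\n",
    x$group_a, x$group_b, x$k, x$real_overlap, x$p_low, x$n_randomizations))
  invisible(x)
}

#' @export
tidy.overlap_test <- function(x, ...) {
  tibble::tibble(randomization = seq_along(x$null_overlaps),
                 null_overlap = x$null_overlaps)
}

#' @export
glance.overlap_test <- function(x, ...) {
  tibble::tibble(group_a = x$group_a, group_b = x$group_b, k = x$k,
                 real_overlap = x$real_overlap, p_low = x$p_low,
                 n_randomizations = x$n_randomizations,
                 null_mean = mean(x$null_overlaps))
}

#' Write an overlap test as JSON plus a null-distribution TSV
#'
#' @param x An `overlap_test`.
#' @param path Output JSON path; the null overlap distribution is written
#'   next to it with suffix `_null.tsv`.
#' @return `path`, invisibly.
#' @export
write_overlap_test <- function(x, path) {
  jsonlite::write_json(
    list(group_a = x$group_a, group_b = x$group_b, k = x$k,
         real_overlap = x$real_overlap, p_low = x$p_low,
         n_randomizations = x$n_randomizations, rng_seed = x$rng_seed),
    path, auto_unbox = TRUE, pretty = TRUE)
  readr::write_tsv(tidy.overlap_test(x),
                   sub("\\.json$", "_null.tsv", path), progress = FALSE)
  invisible(path)
}
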