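#' Null-model configuration for distance significance
#'
#' @param n_random Number of random gene sets per null (default 2000).
#' @param rng_seed Integer seed driving all draws (default 42).
#' @param comparison `"strict"` counts null distances strictly smaller than
#'   the observed one; `"lte"` counts smaller-or-equal.
#' @param exclude_group Exclude the reference group's own genes from the
#'   random draws? Default `FALSE`: random sets are drawn uniformly from all
#'   network nodes and may intersect the group.
#' @return A `null_config` list.
#' @export
null_config <- function(n_random = 2000L, rng_seed = 42L,
                        comparison = c("strict", "lte"),
                        exclude_group = FALSE) {
  comparison <- match.arg(comparison)
  stopifnot(n_random >= 1L)
  structure(list(n_random = as.integer(n_random),
                 rng_seed = as.integer(rng_seed),
                 comparison = comparison,
                 exclude_group = isTRUE(exclude_group)),
            class = "null_config")
}

# distance submatrix helpers -------------------------------------------------

# All-pairs shortest-path distances from A to all network nodes, as a
# |A| x n matrix with named columns. Errors on unreachable pairs: callers
# work on one connected component.
distance_rows <- function(net, A) {
  stopifnot(inherits(net, "aggregated_network"))
  A <- as_gene_set(A, "A")
  absent <- setdiff(A, net$nodes)
  if (length(absent) > 0L) {
    stop("genes not in network: ", paste(absent, collapse = ", "))
  }
  d <- igraph::distances(net$graph, v = A, to = net$nodes)
  colnames(d) <- net$nodes
  d
}

# mean distance over pairs (a in A, b in B) excluding a == b; D is the
# |A| x n row matrix from distance_rows
set_mean_distance <- function(D, A, B, on_empty = c("error", "na")) {
  on_empty <- match.arg(on_empty)
  sub <- D[, B, drop = FALSE]
  shared <- length(intersect(A, B))
  n_pairs <- length(A) * length(B) - shared
  if (setequal(A, B)) {
    # intra-group: unordered distinct pairs; the ordered off-diagonal mean
    # is identical by symmetry
    n_pairs <- length(A) * (length(A) - 1L)
  }
  if (n_pairs <= 0L) {
    if (on_empty == "na") return(NA_real_)
    stop("no valid gene pair between the two sets")
  }
  total <- sum(sub)  # d(a, a) = 0 contributes nothing
  if (any(is.infinite(sub))) stop("sets span disconnected components")
  total / n_pairs
}

#' Average shortest-path distance between two gene sets
#'
#' The mean of the shortest-path length `d(a, b)` over all pairs with `a` in
#' `A`, `b` in `B` and `a != b`; for the intra-group case (`A` equal to `B`)
#' this is the mean over unordered distinct pairs. The measure is symmetric
#' in its arguments. This is the plain all-pairs average, not the
#' minimum-based separation used elsewhere in network medicine.
#'
#' @param net An `aggregated_network` (typically the largest connected
#'   component).
#' @param A,B Character vectors of gene symbols present in `net`.
#' @return A single non-negative number (at least 1 on a simple graph).
#' @examples
#' mx <- build_multiplex(list(
#'   ppi = tibble::tibble(from = c("A", "B"), to = c("B", "C"))
#' ))
#' net <- aggregate_multiplex(mx)
#' avg_shortest_distance(net, "A", "C")
#' @export
avg_shortest_distance <- function(net, A, B) {
  A <- as_gene_set(A, "A")
  B <- as_gene_set(B, "B")
  absent <- setdiff(B, net$nodes)
  if (length(absent) > 0L) {
    stop("genes not in network: ", paste(absent, collapse = ", "))
  }
  set_mean_distance(distance_rows(net, A), A, B)
}

# draw a random node set of given size; optionally excluding some nodes
draw_random_set <- function(nodes, size, exclude = character()) {
  pool <- if (length(exclude) > 0L) setdiff(nodes, exclude) else nodes
  if (size > length(pool)) {
    stop("random set size ", size, " exceeds available nodes (", length(pool), ")")
  }
  sample(pool, size)
}

#' Empirical significance of a group-to-group distance
#'
#' Compares the observed average shortest distance from `A` to `B` against
#' distances from `A` to random node sets of size `|B|` drawn uniformly
#' (without replacement within a draw) from the network nodes. The p-value
#' is the fraction of random sets at a distance smaller than the observed
#' one — the chance of seeing a distance this small for a random gene set.
#' The assessment is directional: `B` is the randomized side, so
#' `empirical_p(net, A, B)` and `empirical_p(net, B, A)` answer different
#' questions even though the distance itself is symmetric.
#'
#' @param net An `aggregated_network`.
#' @param A,B Gene sets present in `net`.
#' @param cfg A [null_config()].
#' @return A list with `p`, `real_distance`, `null_distances`, `n_random`
#'   and `rng_seed`.
#' @export
empirical_p <- function(net, A, B, cfg = null_config()) {
  A <- as_gene_set(A, "A")
  B <- as_gene_set(B, "B")
  if (length(B) > length(net$nodes)) stop("|B| exceeds network size")
  D <- distance_rows(net, A)
  real <- set_mean_distance(D, A, B)
  exclude <- if (isTRUE(cfg$exclude_group)) A else character()
  nulls <- withr::with_seed(cfg$rng_seed, {
    vapply(seq_len(cfg$n_random), function(i) {
      # a draw identical to a singleton A has no valid pair: redraw
      repeat {
        R <- draw_random_set(net$nodes, length(B), exclude)
        val <- set_mean_distance(D, A, R, on_empty = "na")
        if (!is.na(val)) return(val)
      }
    }, double(1))
  })
  hits <- if (cfg$comparison == "strict") sum(nulls < real) else sum(nulls <= real)
  list(p = hits / cfg$n_random, real_distance = real,
       null_distances = nulls, n_random = cfg$n_random,
       rng_seed = cfg$rng_seed)
}

#' Mean distance from a gene set to random gene sets
#'
#' Averages `avg_shortest_distance(A, R)` over random node sets `R` of the
#' given size. With `randomize_A = TRUE` the reference side is redrawn each
#' iteration too (the random-versus-random baseline).
#'
#' @param net An `aggregated_network`.
#' @param A Gene set (ignored when `randomize_A = TRUE` except for its size
#'   default).
#' @param size Size of each random set; defaults to `|A|`.
#' @param cfg A [null_config()].
#' @param randomize_A Redraw `A` each iteration (same size as `A`)?
#' @return A single number: the mean over `cfg$n_random` draws.
#' @export
random_baseline <- function(net, A, size = NULL, cfg = null_config(),
                            randomize_A = FALSE) {
  A <- as_gene_set(A, "A")
  if (is.null(size)) size <- length(A)
  stopifnot(size >= 1L)
  if (size > length(net$nodes)) stop("random set size exceeds network size")
  D_full <- if (!randomize_A) distance_rows(net, A) else NULL
  vals <- withr::with_seed(cfg$rng_seed, {
    vapply(seq_len(cfg$n_random), function(i) {
      Ai <- if (randomize_A) sort(draw_random_set(net$nodes, length(A))) else A
      R <- draw_random_set(net$nodes, size)
      D <- if (randomize_A) distance_rows(net, Ai) else D_full
      # draws identical to the reference set carry no valid pair: skip
      set_mean_distance(D, Ai, R, on_empty = "na")
    }, double(1))
  })
  mean(vals, na.rm = TRUE)
}

#' Group-wise distance table with empirical significance
#'
#' Computes the full matrix of intra-group, inter-group, group-versus-random
#' and random-versus-random average shortest distances, with an empirical
#' p-value for each directed pair of real groups (the second group is the
#' randomized side). Groups of size one have no intra-group pair and get
#' `NA` in their diagonal cell.
#'
#' @param net An `aggregated_network`.
#' @param groups An `onset_groups` object or named list of gene sets; genes
#'   absent from the network are dropped with a message.
#' @param cfg A [null_config()].
#' @param random_size Size used for the random-versus-random cell; defaults
#'   to the rounded mean group size.
#' @return A `distance_table`: tibble with columns `group_a`, `group_b`,
#'   `mean_distance`, `p_empirical`, `n_random`, `rng_seed`; one row per
#'   ordered pair including the `random` pseudo-group.
#' @export
distance_table <- function(net, groups, cfg = null_config(),
                           random_size = NULL) {
  groups <- lapply(groups, as_gene_set)
  stopifnot(length(names(groups)) == length(groups))
  groups <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    absent <- setdiff(g, net$nodes)
    if (length(absent) > 0L) {
      message("group '", nm, "': not in network, dropped: ",
              paste(absent, collapse = ", "))
    }
    intersect(g, net$nodes)
  }) |> stats::setNames(names(groups))
  if (any(lengths(groups) == 0L)) stop("a group is empty after network intersection")
  if (is.null(random_size)) random_size <- max(1L, round(mean(lengths(groups))))

  nm <- names(groups)
  rows <- list()
  for (a in nm) {
    D <- distance_rows(net, groups[[a]])
    for (b in nm) {
      md <- if (a == b && length(groups[[a]]) < 2L) NA_real_
            else set_mean_distance(D, groups[[a]], groups[[b]])
      seed_ab <- derive_seed(cfg$rng_seed, paste0("dist:", a, ":", b))
      cfg_ab <- null_config(cfg$n_random, seed_ab, cfg$comparison,
                            cfg$exclude_group)
      p <- if (is.na(md)) NA_real_
           else empirical_p(net, groups[[a]], groups[[b]], cfg_ab)$p
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group_a = a, group_b = b, mean_distance = md, p_empirical = p,
        n_random = cfg$n_random, rng_seed = seed_ab)
    }
    # group-versus-random column
    seed_ar <- derive_seed(cfg$rng_seed, paste0("dist:", a, ":random"))
    rb <- random_baseline(net, groups[[a]], size = length(groups[[a]]),
                          cfg = null_config(cfg$n_random, seed_ar,
                                            cfg$comparison, cfg$exclude_group))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      group_a = a, group_b = "random", mean_distance = rb,
      p_empirical = NA_real_, n_random = cfg$n_random, rng_seed = seed_ar)
  }
  seed_rr <- derive_seed(cfg$rng_seed, "dist:random:random")
  rr <- random_baseline(net, sample_seed_set(net, random_size, seed_rr),
                        size = random_size,
                        cfg = null_config(cfg$n_random, seed_rr,
                                          cfg$comparison, cfg$exclude_group),
                        randomize_A = TRUE)
  rows[[length(rows) + 1L]] <- tibble::tibble(
    group_a = "random", group_b = "random", mean_distance = rr,
    p_empirical = NA_real_, n_random = cfg$n_random, rng_seed = seed_rr)
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("distance_table", class(out)),
            groups = groups, random_size = random_size)
}

sample_seed_set <- function(net, size, seed) {
  withr::with_seed(seed, sort(sample(net$nodes, size)))
}

#' Widen a distance table into a matrix shaped like a distance summary
#'
#' @param tab A `distance_table`.
#' @return A tibble, one row per group, columns per group plus `random`.
#' @export
distance_matrix <- function(tab) {
  stopifnot(inherits(tab, "distance_table"))
  tibble::as_tibble(tab)[, c("group_a", "group_b", "mean_distance")] |>
    tidyr::pivot_wider(names_from = "group_b", values_from = "mean_distance")
}

#' @export
tidy.distance_table <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.distance_table <- function(x, ...) {
  real <- x[x$group_a != "random" & x$group_b != "random", ]
  tibble::tibble(
    n_groups = length(attr(x, "groups")),
    n_random = x$n_random[1L],
    min_distance = min(real$mean_distance, na.rm = TRUE),
    max_p = max(real$p_empirical, na.rm = TRUE)
  )
}

#' Write a distance table as long and wide TSV
#'
#' @param tab A `distance_table`.
#' @param path Output TSV path for the long format; the wide matrix is
#'   written next to it with suffix `_matrix.tsv`.
#' @return `path`, invisibly.
#' @export
write_distance_table <- function(tab, path) {
  readr::write_tsv(tibble::as_tibble(tab), path, progress = FALSE)
  wide <- distance_matrix(tab)
  readr::write_tsv(wide, sub("\\.tsv$", "_matrix.tsv", path), progress = FALSE)
  invisible(path)
}
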