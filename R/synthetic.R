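#' Configuration for the planted-partition synthetic generator
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' each layer is an independent planted-partition (stochastic block) graph
#' with two functional communities over a shared gene universe; a
#' distal-like group lives inside community 1, a proximal-like group inside
#' community 2, and a bridging common-like group is wired into both
#' communities; a matching GMT annotates the two communities (bridge genes
#' carry both annotations).
#'
#' @param n_genes Total number of genes (default 300).
#' @param n_layers Number of layers (default 3).
#' @param community_sizes Sizes of the two planted communities (default
#'   c(60, 60)).
#' @param p_intra Within-community edge probability per layer (default
#'   0.15).
#' @param p_inter Background/cross-community edge probability per layer
#'   (default 0.01).
#' @param group_sizes Sizes of the distal-like, proximal-like and bridge
#'   groups (default c(11, 22, 7), mirroring the muscular dystrophy onset
#'   groups).
#' @param bridge_attachment Probability that a bridge gene links to any
#'   given member of each community, per layer (default 0.3).
#' @param n_terms Number of GMT terms: the two community terms plus noise
#'   terms (default 10).
#' @param rng_seed Integer seed; identical seeds give identical bundles.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 300L, n_layers = 3L,
                             community_sizes = c(60L, 60L),
                             p_intra = 0.15, p_inter = 0.01,
                             group_sizes = c(11L, 22L, 7L),
                             bridge_attachment = 0.3,
                             n_terms = 10L, rng_seed = 42L) {
  stopifnot(length(community_sizes) == 2L, length(group_sizes) == 3L,
            all(c(p_intra, p_inter, bridge_attachment) >= 0),
            all(c(p_intra, p_inter, bridge_attachment) <= 1),
            n_layers >= 1L, n_terms >= 2L)
  if (group_sizes[1L] > community_sizes[1L] ||
      group_sizes[2L] > community_sizes[2L]) {
    stop("group sizes must not exceed their community sizes")
  }
  if (n_genes < sum(community_sizes) + group_sizes[3L]) {
    stop("n_genes must cover both communities plus the bridge group")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_layers = as.integer(n_layers),
                 community_sizes = as.integer(community_sizes),
                 p_intra = p_intra, p_inter = p_inter,
                 group_sizes = as.integer(group_sizes),
                 bridge_attachment = bridge_attachment,
                 n_terms = as.integer(n_terms),
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

#' Generate a synthetic multiplex bundle
#'
#' Draws the layers, the three planted gene groups and the annotation
#' database described by [synthetic_config()]. Deterministic given
#' `cfg$rng_seed`.
#'
#' @param cfg A `synthetic_config`.
#' @return A `synthetic_bundle`: list with `multiplex`, `groups` (named
#'   list `distal_like`, `proximal_like`, `bridge`), `gmt`
#'   (`annotation_db`), `truth` (tibble gene/community/group) and `config`.
#' @export
generate_bundle <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_genes
  genes <- sprintf("G%04d", seq_len(n))
  c1 <- genes[seq_len(cfg$community_sizes[1L])]
  c2 <- genes[cfg$community_sizes[1L] + seq_len(cfg$community_sizes[2L])]
  rest <- setdiff(genes, c(c1, c2))

  withr::with_seed(cfg$rng_seed, {
    bridge <- sort(sample(rest, cfg$group_sizes[3L]))
    distal_like <- sort(sample(c1, cfg$group_sizes[1L]))
    proximal_like <- sort(sample(c2, cfg$group_sizes[2L]))

    community <- stats::setNames(rep("background", n), genes)
    community[c1] <- "community1"
    community[c2] <- "community2"
    community[bridge] <- "bridge"

    # per-pair edge probability matrix (upper triangle sampled per layer)
    pair_idx <- utils::combn(n, 2L)
    prob <- pair_probabilities(genes, community, pair_idx, cfg)
    layers <- lapply(seq_len(cfg$n_layers), function(l) {
      hit <- stats::runif(ncol(pair_idx)) < prob
      layer_from_edges(
        tibble::tibble(from = genes[pair_idx[1L, hit]],
                       to = genes[pair_idx[2L, hit]]),
        paste0("layer", l))
    })
    mx <- build_multiplex(layers)

    gmt <- synthetic_gmt(genes, c1, c2, bridge, cfg)
  })

  truth <- tibble::tibble(
    gene = genes,
    community = unname(community[genes]),
    group = dplyr::case_when(
      genes %in% distal_like ~ "distal_like",
      genes %in% proximal_like ~ "proximal_like",
      genes %in% bridge ~ "bridge",
      TRUE ~ NA_character_
    )
  )
  structure(list(multiplex = mx,
                 groups = list(distal_like = distal_like,
                               proximal_like = proximal_like,
                               bridge = bridge),
                 gmt = gmt, truth = truth, config = cfg),
            class = "synthetic_bundle")
}

pair_probabilities <- function(genes, community, pair_idx, cfg) {
  ca <- community[pair_idx[1L, ]]
  cb <- community[pair_idx[2L, ]]
  p <- rep(cfg$p_inter, ncol(pair_idx))
  same_comm <- ca == cb & ca %in% c("community1", "community2")
  p[same_comm] <- cfg$p_intra
  # bridge genes participate in both communities and form a cohesive
  # cluster of their own (common genes are multifunctional and mutually
  # close, which is what the group-distance analysis expects)
  bridge_pair <- (ca == "bridge" & cb %in% c("community1", "community2", "bridge")) |
    (cb == "bridge" & ca %in% c("community1", "community2", "bridge"))
  p[bridge_pair] <- cfg$bridge_attachment
  p
}

synthetic_gmt <- function(genes, c1, c2, bridge, cfg) {
  sets <- list(sarcomere_like = sort(c(c1, bridge)),
               sarcolemma_like = sort(c(c2, bridge)))
  n_noise <- cfg$n_terms - 2L
  if (n_noise > 0L) {
    for (i in seq_len(n_noise)) {
      size <- sample(10:40, 1L)
      sets[[paste0("noise_term_", i)]] <- sort(sample(genes, size))
    }
  }
  annotation_db(sets)
}

#' Ground-truth membership table of a synthetic bundle
#'
#' @param bundle A `synthetic_bundle`.
#' @return A tibble with columns `gene`, `community`, `group`, restricted
#'   to the planted group members.
#' @export
truth_report <- function(bundle) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  bundle$truth[!is.na(bundle$truth$group), ]
}

#' Write a synthetic bundle to disk in pipeline input formats
#'
#' Writes one TSV edge list per layer, one gene list per planted group, the
#' GMT, and the ground-truth table — exactly the formats the readers of
#' this package consume. Byte-identical across runs for a given config.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (nm in names(bundle$multiplex$layers)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(bundle$multiplex$layers[[nm]], p, col_names = FALSE,
                     progress = FALSE)
    paths[[nm]] <- p
  }
  for (g in names(bundle$groups)) {
    p <- file.path(dir, paste0(g, ".txt"))
    writeLines(bundle$groups[[g]], p)
    paths[[g]] <- p
  }
  gmt_path <- file.path(dir, "annotations.gmt")
  writeLines(vapply(names(bundle$gmt$terms), function(id) {
    t <- bundle$gmt$terms[[id]]
    paste(c(id, t$name, t$genes), collapse = "\t")
  }, character(1)), gmt_path)
  paths$gmt <- gmt_path
  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(bundle$truth, truth_path, progress = FALSE)
  paths$truth <- truth_path
  invisible(paths)
}
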