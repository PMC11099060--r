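#' Pipeline configuration
#'
#' Collects the file paths and parameters of a full run. All referenced
#' files must exist at validation time.
#'
#' @param layer_paths Named character vector of layer edge-list TSV paths.
#' @param distal_path,proximal_path Gene-list files for the two onset
#'   lists.
#' @param gmt_path GMT annotation file.
#' @param out_dir Output directory.
#' @param rng_seed Global seed; per-stage seeds are derived from it
#'   deterministically so stages are also reproducible standalone.
#' @param k Neighborhood sizes (default `c(50, 100)`).
#' @param n_random Random gene sets per distance null (default 2000).
#' @param n_rand_overlap Label randomizations per overlap test (default
#'   1000).
#' @param restart RWR restart probability (default 0.7).
#' @param interlayer_jump RWR layer-switch probability (default 0.5).
#' @param alpha Enrichment significance threshold (default 0.05).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(layer_paths, distal_path, proximal_path,
                            gmt_path = NULL, out_dir, rng_seed = 42L,
                            k = c(50L, 100L), n_random = 2000L,
                            n_rand_overlap = 1000L, restart = 0.7,
                            interlayer_jump = 0.5, alpha = 0.05) {
  stopifnot(length(layer_paths) >= 1L, all(k >= 1L))
  files <- c(layer_paths, distal_path, proximal_path, gmt_path)
  missing <- files[!file.exists(files)]
  if (length(missing) > 0L) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  if (is.null(names(layer_paths)) || any(!nzchar(names(layer_paths)))) {
    names(layer_paths) <- tools::file_path_sans_ext(basename(layer_paths))
  }
  structure(list(layer_paths = layer_paths, distal_path = distal_path,
                 proximal_path = proximal_path, gmt_path = gmt_path,
                 out_dir = out_dir, rng_seed = as.integer(rng_seed),
                 k = as.integer(k), n_random = as.integer(n_random),
                 n_rand_overlap = as.integer(n_rand_overlap),
                 restart = restart, interlayer_jump = interlayer_jump,
                 alpha = alpha),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full onset-group network analysis pipeline
#'
#' Chains curation, multiplex assembly, largest-connected-component
#' extraction, the induced subnetwork with closeness centralities, the
#' group-wise distance table, the RWR neighborhoods of each group, the
#' pairwise neighborhood overlap tests and (when a GMT is configured) the
#' per-group enrichment tables. All stage outputs plus a manifest of every
#' parameter and derived seed are written to `cfg$out_dir`. Re-running with
#' the same config reproduces identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return The output directory, invisibly; results are also returned in
#'   the `results` attribute.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  groups <- run_stage("curate", {
    g <- assign_onset_groups(read_gene_list(cfg$distal_path),
                             read_gene_list(cfg$proximal_path))
    write_onset_groups(g, file.path(cfg$out_dir, "onset_groups.tsv"))
    write_onset_groups(g, file.path(cfg$out_dir, "onset_groups.json"))
    g
  })
  res$groups <- groups

  lcc <- run_stage("build-net", {
    layers <- purrr::imap(cfg$layer_paths, function(p, nm) read_layer(p, nm))
    largest_connected_component(build_multiplex(unname(layers)))
  })
  res$multiplex <- lcc
  net <- aggregate_multiplex(lcc)

  res$subnetwork <- run_stage("subnet", {
    all_md <- unlist(unclass(groups), use.names = FALSE)
    sub <- suppressMessages(induced_subnetwork(net, all_md))
    export_network(sub, file.path(cfg$out_dir, "md_subnetwork.graphml"),
                   groups = groups)
    export_network(sub, file.path(cfg$out_dir, "md_subnetwork.sif"))
    if (length(sub$missing) > 0L) {
      writeLines(sub$missing, file.path(cfg$out_dir, "not_in_network.txt"))
    }
    readr::write_tsv(closeness_centrality(sub),
                     file.path(cfg$out_dir, "subnetwork_closeness.tsv"),
                     progress = FALSE)
    summ <- summarize_network(net)
    readr::write_tsv(summ$summary, file.path(cfg$out_dir, "network_metrics.tsv"),
                     progress = FALSE)
    sub
  })

  dist_tab <- run_stage("distances", {
    present <- lapply(unclass(groups), function(g) intersect(g, net$nodes))
    dcfg <- null_config(cfg$n_random,
                        derive_seed(cfg$rng_seed, "distances"))
    tab <- suppressMessages(distance_table(net, present, dcfg))
    write_distance_table(tab, file.path(cfg$out_dir, "distance_table.tsv"))
    tab
  })
  res$distances <- dist_tab

  rwr_cfg <- rwr_config(restart = cfg$restart,
                        interlayer_jump = cfg$interlayer_jump)
  neighborhoods <- run_stage("rwr", {
    out <- list()
    for (g in names(unclass(groups))) {
      seeds <- intersect(groups[[g]], lcc$nodes)
      if (length(seeds) == 0L) next
      sv <- suppressMessages(rwr_multiplex(lcc, seeds, rwr_cfg))
      write_rwr_scores(sv, file.path(cfg$out_dir, paste0("rwr_scores_", g, ".tsv")))
      for (kk in cfg$k) {
        nb <- extract_neighborhood(sv, kk, seed_group = g)
        readr::write_tsv(tibble::as_tibble(nb),
                         file.path(cfg$out_dir,
                                   sprintf("neighborhood_%s_k%d.tsv", g, kk)),
                         progress = FALSE)
        out[[paste0(g, "_k", kk)]] <- nb
      }
    }
    out
  })
  res$neighborhoods <- neighborhoods

  overlaps <- run_stage("overlap", {
    labels <- tidy.onset_groups(groups)
    labels <- labels[labels$gene %in% lcc$nodes, ]
    pairs <- utils::combn(names(unclass(groups)), 2L)
    out <- list()
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      ot <- suppressMessages(label_randomization_test(
        lcc, labels, a, b, k = cfg$k[1L], n_rand = cfg$n_rand_overlap,
        cfg = rwr_cfg,
        rng_seed = derive_seed(cfg$rng_seed, paste0("overlap:", a, ":", b))))
      write_overlap_test(ot, file.path(cfg$out_dir,
                                       sprintf("overlap_%s_%s.json", a, b)))
      out[[paste(a, b, sep = "_")]] <- ot
    }
    out
  })
  res$overlaps <- overlaps

  if (!is.null(cfg$gmt_path)) {
    res$enrichment <- run_stage("enrich", {
      db <- read_gmt(cfg$gmt_path)
      out <- list()
      for (g in names(unclass(groups))) {
        er <- suppressWarnings(enrich(groups[[g]], db, alpha = cfg$alpha))
        write_enrichment(er, file.path(cfg$out_dir,
                                       paste0("enrichment_", g, ".tsv")))
        out[[g]] <- er
      }
      out
    })
  }

  run_stage("manifest", {
    manifest <- list(
      package = "onsetnet",
      version = as.character(utils::packageVersion("onsetnet")),
      parameters = unclass(cfg)[c("rng_seed", "k", "n_random",
                                  "n_rand_overlap", "restart",
                                  "interlayer_jump", "alpha")],
      inputs = list(layers = as.list(cfg$layer_paths),
                    distal = cfg$distal_path, proximal = cfg$proximal_path,
                    gmt = cfg$gmt_path),
      derived_seeds = list(
        distances = derive_seed(cfg$rng_seed, "distances"))
    )
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })

  structure(invisible(cfg$out_dir), results = res)
}
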