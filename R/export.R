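#' Export an aggregated network for Cytoscape
#'
#' Writes GraphML (via igraph) with an edge attribute listing the
#' supporting layers and, optionally, a node attribute giving the onset
#' group; or a SIF file where the interaction type is the comma-joined
#' layer tag.
#'
#' @param net An `aggregated_network`.
#' @param path Output path; format chosen by extension (`.graphml` or
#'   `.sif`).
#' @param groups Optional `onset_groups` object (or tibble with `gene`,
#'   `group`) used to annotate nodes.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, groups = NULL) {
  stopifnot(inherits(net, "aggregated_network"))
  tags <- vapply(net$edges$layers, paste, character(1), collapse = ",")
  if (grepl("\\.sif$", path)) {
    lines <- if (nrow(net$edges) > 0L)
      paste(net$edges$from, tags, net$edges$to) else character()
    isolated <- setdiff(net$nodes, c(net$edges$from, net$edges$to))
    writeLines(c(lines, isolated), path)
    return(invisible(path))
  }
  g <- net$graph
  igraph::E(g)$layers <- tags
  if (!is.null(groups)) {
    tab <- if (inherits(groups, "onset_groups")) tidy.onset_groups(groups)
           else tibble::as_tibble(groups)
    grp <- tab$group[match(igraph::V(g)$name, tab$gene)]
    igraph::V(g)$group <- ifelse(is.na(grp), "none", grp)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
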