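# Internal edge canonicalisation: undirected simple edges as a tibble with
# from < to, no self-loops, no duplicates.
canonical_edges <- function(from, to) {
  from <- canonicalize_symbols(from, drop_empty = FALSE)
  to <- canonicalize_symbols(to, drop_empty = FALSE)
  keep <- from != to
  a <- pmin(from[keep], to[keep])
  b <- pmax(from[keep], to[keep])
  e <- tibble::tibble(from = a, to = b)
  dplyr::distinct(dplyr::arrange(e, .data$from, .data$to))
}

#' Read a network layer from a TSV edge list
#'
#' Each row is one undirected interaction given as two gene-symbol columns
#' (extra columns, e.g. weights, are ignored with a warning — the package
#' works on simple unweighted graphs). Self-loops are dropped and duplicate
#' edges collapsed; symbols are canonicalized to uppercase. Lines starting
#' with `#` are ignored.
#'
#' @param path Path to the edge-list file.
#' @param name Layer name (e.g. `"ppi"`, `"complexes"`, `"pathways"`).
#' @return A `network_layer`: a tibble with columns `from`, `to` and a
#'   `layer_name` attribute.
#' @export
read_layer <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("layer file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(new_layer(canonical_edges(character(), character()), name))
  parts <- strsplit(lines, "[\t ]+")
  short <- lengths(parts) < 2L
  if (any(short)) {
    stop("edge list ", path, ": fewer than 2 columns on line ",
         lineno[which(short)[1L]])
  }
  if (any(lengths(parts) > 2L)) {
    warning("layer '", name, "': extra columns (e.g. weights) ignored; ",
            "graphs are simple and unweighted")
  }
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), 2L)
  new_layer(canonical_edges(from, to), name)
}

new_layer <- function(edges, name) {
  structure(edges, layer_name = name, class = c("network_layer", class(edges)))
}

#' Create a network layer from an edge table
#'
#' @param edges A data frame whose first two columns are gene symbols.
#' @param name Layer name.
#' @return A `network_layer` tibble.
#' @export
layer_from_edges <- function(edges, name) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L && nrow(edges) > 0L) stop("edge table needs 2 columns")
  if (nrow(edges) == 0L) {
    return(new_layer(canonical_edges(character(), character()), name))
  }
  new_layer(canonical_edges(as.character(edges[[1L]]),
                            as.character(edges[[2L]])), name)
}

#' Assemble a multiplex network from layers
#'
#' A multiplex network is a set of layers sharing one node universe but
#' carrying different interactions. The shared node set is the union of all
#' edge endpoints across layers; a node may therefore be isolated within any
#' given layer.
#'
#' @param layers A list of `network_layer` objects (or plain edge tibbles;
#'   names are then taken from the list names).
#' @return A `multiplex` object with fields `nodes` (sorted character
#'   vector) and `layers` (named list of edge tibbles).
#' @export
build_multiplex <- function(layers) {
  if (inherits(layers, "network_layer")) layers <- list(layers)
  if (length(layers) == 0L) stop("at least one layer is required")
  nm <- vapply(seq_along(layers), function(i) {
    n <- attr(layers[[i]], "layer_name")
    if (is.null(n)) n <- names(layers)[i]
    if (is.null(n) || is.na(n) || !nzchar(n)) n <- paste0("layer", i)
    n
  }, character(1))
  if (anyDuplicated(nm)) stop("layer names must be unique")
  edges <- lapply(layers, function(l) {
    e <- tibble::as_tibble(l)[, c("from", "to")]
    canonical_edges(e$from, e$to)
  })
  names(edges) <- nm
  nodes <- sort(unique(unlist(lapply(edges, function(e) c(e$from, e$to)),
                              use.names = FALSE)))
  structure(list(nodes = nodes, layers = edges), class = "multiplex")
}

#' @export
print.multiplex <- function(x, ...) {
  cat("Multiplex network:", length(x$nodes), "nodes,",
      length(x$layers), "layer(s)\n")
  for (nm in names(x$layers)) {
    cat(sprintf("  %-12s %6d edges\n", nm, nrow(x$layers[[nm]])))
  }
  invisible(x)
}

# igraph of the union-of-layers graph over the multiplex node universe
aggregated_igraph <- function(mx) {
  e <- dplyr::distinct(dplyr::bind_rows(mx$layers)[, c("from", "to")])
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = data.frame(name = mx$nodes))
}

#' Extract the largest connected component of a multiplex network
#'
#' Connectivity is evaluated on the aggregated (union-of-layers) graph: a
#' walker can switch layers at any node, so any node reachable through any
#' layer belongs to the same component. Ties between equally sized
#' components are broken in favour of the component containing the
#' lexicographically smallest node.
#'
#' @param mx A `multiplex` object.
#' @return A `multiplex` restricted to the nodes of the largest component.
#' @export
largest_connected_component <- function(mx) {
  stopifnot(inherits(mx, "multiplex"))
  if (length(mx$nodes) == 0L) stop("empty multiplex")
  g <- aggregated_igraph(mx)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie-break: component whose smallest member node sorts first
    mins <- vapply(best, function(b) {
      min(igraph::V(g)$name[comp$membership == b])
    }, character(1))
    best <- best[order(mins)][1L]
  }
  keep <- igraph::V(g)$name[comp$membership == best]
  restrict_multiplex(mx, sort(keep))
}

restrict_multiplex <- function(mx, nodes) {
  layers <- lapply(mx$layers, function(e) {
    e[e$from %in% nodes & e$to %in% nodes, , drop = FALSE]
  })
  structure(list(nodes = sort(nodes), layers = layers), class = "multiplex")
}

#' Merge the layers of a multiplex network into one tagged graph
#'
#' The aggregated network has the union of all layer edge sets; each edge is
#' tagged with the layers supporting it, so the per-layer edge sets can be
#' recovered exactly and exports can colour edges by provenance.
#'
#' @param mx A `multiplex` object.
#' @return An `aggregated_network`: list with `nodes`, `edges` (tibble
#'   `from`, `to`, `layers` list-column) and `graph` (igraph).
#' @export
aggregate_multiplex <- function(mx) {
  stopifnot(inherits(mx, "multiplex"))
  tagged <- dplyr::bind_rows(mx$layers, .id = "layer")
  if (nrow(tagged) == 0L) {
    edges <- tibble::tibble(from = character(), to = character(),
                            layers = list())
  } else {
    edges <- tagged |>
      dplyr::group_by(.data$from, .data$to) |>
      dplyr::summarise(layers = list(unique(.data$layer)), .groups = "drop") |>
      dplyr::arrange(.data$from, .data$to)
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = mx$nodes)
  )
  structure(list(nodes = mx$nodes, edges = edges, graph = g),
            class = "aggregated_network")
}

#' @export
print.aggregated_network <- function(x, ...) {
  cat("Aggregated network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

# split an aggregated network back into per-layer edge tibbles (round-trip
# counterpart of aggregate_multiplex)
split_by_layer <- function(net) {
  stopifnot(inherits(net, "aggregated_network"))
  long <- tidyr::unnest(net$edges, "layers")
  lapply(split(long[, c("from", "to")], long$layers),
         function(e) dplyr::arrange(tibble::as_tibble(e), .data$from, .data$to))
}

#' Induce a subnetwork on a set of genes
#'
#' Returns the subgraph induced on `genes`. Members with no interaction
#' among themselves are retained as disconnected nodes. Genes absent from
#' the network are not silently dropped: they are reported with a message
#' and listed in the `missing` attribute of the result.
#'
#' @param net An `aggregated_network`.
#' @param genes Character vector of gene symbols.
#' @return An `aggregated_network` over `genes` present in `net`, with
#'   attribute `missing` listing absent symbols.
#' @export
induced_subnetwork <- function(net, genes) {
  stopifnot(inherits(net, "aggregated_network"))
  genes <- as_gene_set(genes)
  missing <- setdiff(genes, net$nodes)
  if (length(missing) > 0L) {
    message("not in network: ", paste(missing, collapse = ", "))
  }
  present <- intersect(genes, net$nodes)
  edges <- net$edges[net$edges$from %in% present & net$edges$to %in% present, ]
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = present))
  structure(list(nodes = present, edges = edges, graph = g,
                 missing = missing),
            class = "aggregated_network")
}

#' Closeness centrality per node
#'
#' For a node in a connected component of size at least two, closeness is
#' the reciprocal of its mean shortest-path distance to the other nodes of
#' its component (the NetworkAnalyzer convention). Isolated nodes get 0.
#'
#' @param net An `aggregated_network`.
#' @return A tibble with columns `gene` and `closeness`, sorted by
#'   decreasing closeness then gene symbol.
#' @export
closeness_centrality <- function(net) {
  stopifnot(inherits(net, "aggregated_network"))
  g <- net$graph
  n <- length(net$nodes)
  if (n == 0L) return(tibble::tibble(gene = character(), closeness = double()))
  comp <- igraph::components(g)
  d <- igraph::distances(g)
  cc <- vapply(seq_len(n), function(i) {
    members <- which(comp$membership == comp$membership[i])
    others <- setdiff(members, i)
    if (length(others) == 0L) return(0)
    1 / mean(d[i, others])
  }, double(1))
  tibble::tibble(gene = igraph::V(g)$name, closeness = cc) |>
    dplyr::arrange(dplyr::desc(.data$closeness), .data$gene)
}

#' Summary metrics of an aggregated network
#'
#' @param net An `aggregated_network`.
#' @return A list with `summary` (one-row tibble: node count, edge count,
#'   density, component count, diameter of the largest component, degree
#'   statistics) and `components` (per-component tibble with size and
#'   diameter).
#' @export
summarize_network <- function(net) {
  stopifnot(inherits(net, "aggregated_network"))
  g <- net$graph
  n <- length(net$nodes)
  m <- nrow(net$edges)
  if (n == 0L) {
    return(list(
      summary = tibble::tibble(n_nodes = 0L, n_edges = 0L, density = 0,
                               n_components = 0L, diameter_lcc = 0,
                               mean_degree = 0, max_degree = 0),
      components = tibble::tibble(component = integer(), n_nodes = integer(),
                                  diameter = double())
    ))
  }
  comp <- igraph::components(g)
  comps <- purrr::map_dfr(seq_len(comp$no), function(i) {
    sub <- igraph::induced_subgraph(g, which(comp$membership == i))
    tibble::tibble(component = i,
                   n_nodes = igraph::vcount(sub),
                   diameter = if (igraph::vcount(sub) > 1L)
                     igraph::diameter(sub) else 0)
  }) |> dplyr::arrange(dplyr::desc(.data$n_nodes))
  deg <- igraph::degree(g)
  list(
    summary = tibble::tibble(
      n_nodes = n, n_edges = m,
      density = if (n > 1L) m / choose(n, 2) else 0,
      n_components = comp$no,
      diameter_lcc = comps$diameter[1L],
      mean_degree = mean(deg), max_degree = max(deg)
    ),
    components = comps
  )
}
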