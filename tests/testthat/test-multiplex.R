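test_that("layer reading drops self-loops, dedupes and canonicalizes", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "C\tC"), f)
  l <- read_layer(f, "ppi")
  expect_equal(nrow(l), 1)
  expect_equal(l$from, "A")
  expect_equal(l$to, "B")

  writeLines(character(), f)
  expect_equal(nrow(read_layer(f, "empty")), 0)

  writeLines(c("a\tb", "b\tc", "A\tC"), f)
  expect_equal(nrow(read_layer(f, "toy")), 3)
})

test_that("rows with fewer than two columns fail naming the line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "LONELY"), f)
  expect_error(read_layer(f), "line 2")
})

test_that("multiplex assembly shares the node universe across layers", {
  mx <- build_multiplex(list(
    l1 = tibble::tibble(from = "A", to = "B"),
    l2 = tibble::tibble(from = "B", to = "C")
  ))
  expect_equal(mx$nodes, c("A", "B", "C"))
  # A is isolated in l2, C in l1, but both are part of the universe
  expect_false("C" %in% c(mx$layers$l1$from, mx$layers$l1$to))

  single <- build_multiplex(list(l1 = tibble::tibble(from = "A", to = "B")))
  expect_equal(single$nodes, c("A", "B"))
  expect_error(build_multiplex(list()), "at least one layer")

  disjoint <- build_multiplex(list(
    l1 = tibble::tibble(from = "A", to = "B"),
    l2 = tibble::tibble(from = "C", to = "D"),
    l3 = tibble::tibble(from = "E", to = "F")
  ))
  expect_equal(length(disjoint$nodes), 6)
})

test_that("largest connected component works on the aggregated graph", {
  mx <- build_multiplex(list(
    l1 = tibble::tibble(from = c("A", "B", "A"), to = c("B", "C", "C")),
    l2 = tibble::tibble(from = "D", to = "E")
  ))
  lcc <- largest_connected_component(mx)
  expect_equal(lcc$nodes, c("A", "B", "C"))

  # connectivity may come from different layers
  chain <- build_multiplex(list(
    l1 = tibble::tibble(from = "A", to = "B"),
    l2 = tibble::tibble(from = "B", to = "C")
  ))
  expect_equal(largest_connected_component(chain)$nodes, c("A", "B", "C"))

  # equal-size tie broken toward the lexicographically smallest member
  tie <- build_multiplex(list(
    l1 = tibble::tibble(from = c("C", "A"), to = c("D", "B"))
  ))
  expect_equal(largest_connected_component(tie)$nodes, c("A", "B"))

  # idempotent
  expect_equal(largest_connected_component(lcc)$nodes, lcc$nodes)
})

test_that("aggregation tags edges and round-trips the layers", {
  mx <- build_multiplex(list(
    l1 = tibble::tibble(from = c("A", "B"), to = c("B", "C")),
    l2 = tibble::tibble(from = "A", to = "B")
  ))
  net <- aggregate_multiplex(mx)
  ab <- net$edges[net$edges$from == "A" & net$edges$to == "B", ]
  expect_setequal(ab$layers[[1]], c("l1", "l2"))

  back <- onsetnet:::split_by_layer(net)
  expect_equal(back$l1, mx$layers$l1)
  expect_equal(back$l2, mx$layers$l2)

  # disjoint layers: edge count adds up; single layer: all tags singleton
  dj <- aggregate_multiplex(build_multiplex(list(
    l1 = tibble::tibble(from = "A", to = "B"),
    l2 = tibble::tibble(from = "C", to = "D")
  )))
  expect_equal(nrow(dj$edges), 2)
  expect_true(all(lengths(dj$layers) == 1))
})

test_that("induced subnetworks keep isolated members and report absentees", {
  net <- toy_net(path_edges(c("A", "B", "C")))
  sub <- induced_subnetwork(net, c("A", "C"))
  expect_equal(sub$nodes, c("A", "C"))
  expect_equal(nrow(sub$edges), 0)

  full <- induced_subnetwork(net, c("A", "B", "C"))
  expect_equal(nrow(full$edges), 2)

  expect_message(miss <- induced_subnetwork(net, c("A", "ANO5")),
                 "not in network: ANO5")
  expect_equal(miss$missing, "ANO5")
  expect_equal(miss$nodes, "A")
})

test_that("closeness centrality follows the per-component convention", {
  net <- toy_net(path_edges(c("A", "B", "C")))
  cc <- closeness_centrality(net)
  expect_equal(cc$closeness[cc$gene == "B"], 1.0)
  expect_equal(cc$closeness[cc$gene == "A"], 2 / 3)

  comp <- toy_net(complete_edges(c("A", "B", "C", "D")))
  expect_true(all(closeness_centrality(comp)$closeness == 1.0))

  # isolated node gets 0
  iso <- induced_subnetwork(toy_net(path_edges(c("A", "B", "C"))), c("A", "C"))
  expect_true(all(closeness_centrality(iso)$closeness == 0))
})

test_that("closeness matches a brute-force BFS oracle on random graphs", {
  withr::with_seed(31, {
    for (i in 1:10) {
      n <- sample(10:50, 1)
      nodes <- sprintf("N%02d", seq_len(n))
      edges <- random_edges(nodes, 0.08)
      net <- toy_net(edges)
      d <- bfs_all_pairs(net$nodes, edges[edges$from %in% net$nodes &
                                            edges$to %in% net$nodes, ])
      cc <- closeness_centrality(net)
      for (v in net$nodes) {
        others <- d[v, setdiff(net$nodes, v)]
        reach <- others[is.finite(others)]
        expected <- if (length(reach) == 0L) 0 else 1 / mean(reach)
        expect_equal(cc$closeness[cc$gene == v], expected)
      }
    }
  })
})

test_that("network summaries report counts, density and diameters", {
  tri <- summarize_network(toy_net(complete_edges(c("A", "B", "C"))))
  expect_equal(tri$summary$n_nodes, 3)
  expect_equal(tri$summary$n_edges, 3)
  expect_equal(tri$summary$diameter_lcc, 1)
  expect_equal(tri$summary$density, 1.0)

  p4 <- summarize_network(toy_net(path_edges(c("A", "B", "C", "D"))))
  expect_equal(p4$summary$diameter_lcc, 3)

  empty <- induced_subnetwork(toy_net(path_edges(c("A", "B"))), character())
  z <- summarize_network(empty)
  expect_equal(z$summary$n_nodes, 0)
  expect_equal(z$summary$n_edges, 0)
})

test_that("network export writes GraphML and SIF that preserve structure", {
  mx <- build_multiplex(list(
    ppi = tibble::tibble(from = c("A", "B"), to = c("B", "C")),
    complexes = tibble::tibble(from = "A", to = "B")
  ))
  net <- aggregate_multiplex(mx)
  og <- assign_onset_groups(c("A"), c("C"))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, groups = og)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), 3)
  expect_equal(igraph::ecount(g2), 2)
  expect_true("ppi,complexes" %in% igraph::E(g2)$layers ||
                "complexes,ppi" %in% igraph::E(g2)$layers)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif)
  lines <- readLines(sif)
  expect_length(lines, 2)
  expect_true(any(grepl("^A .* B$", lines)))
})
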