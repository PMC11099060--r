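star_net <- function() {
  toy_net(tibble::tibble(from = "C0", to = c("L1", "L2", "L3")))
}

test_that("average shortest distance handles intra, inter and edge cases", {
  # leaves of a star: every distinct pair at distance 2
  expect_equal(avg_shortest_distance(star_net(), c("L1", "L2", "L3"),
                                     c("L1", "L2", "L3")), 2.0)
  # a single edge
  net <- toy_net(tibble::tibble(from = "A", to = "B"))
  expect_equal(avg_shortest_distance(net, "A", "B"), 1.0)
  # complete graph: all pairs at distance 1
  comp <- toy_net(complete_edges(sprintf("K%d", 1:6)))
  expect_equal(avg_shortest_distance(comp, c("K1", "K2"), c("K3", "K4")), 1.0)
  # identical sets: intra equals inter by definition
  expect_equal(avg_shortest_distance(comp, c("K1", "K2"), c("K1", "K2")),
               avg_shortest_distance(comp, c("K1", "K2"), c("K2", "K1")))
  # a singleton has no intra-group pair
  expect_error(avg_shortest_distance(net, "A", "A"), "no valid")
  expect_error(avg_shortest_distance(net, "A", "ZZZ"), "not in network")
})

test_that("set distances match the BFS oracle and are symmetric", {
  withr::with_seed(101, {
    for (i in 1:8) {
      n <- sample(15:50, 1)
      nodes <- sprintf("N%02d", seq_len(n))
      net <- toy_net(random_edges(nodes, 0.15))
      net <- toy_net(igraph::as_data_frame(
        igraph::induced_subgraph(net$graph,
          which(igraph::components(net$graph)$membership == 1))))
      if (length(net$nodes) < 6) next
      d <- bfs_all_pairs(net$nodes,
                         tibble::as_tibble(net$edges[, c("from", "to")]))
      for (j in 1:5) {
        A <- sample(net$nodes, sample(2:4, 1))
        B <- sample(net$nodes, sample(2:4, 1))
        got <- avg_shortest_distance(net, A, B)
        expect_equal(got, oracle_set_distance(d, sort(unique(A)),
                                              sort(unique(B))))
        expect_equal(got, avg_shortest_distance(net, B, A))
        expect_gte(got, 1)
      }
    }
  })
})

test_that("empirical p-values behave at the extremes", {
  comp <- toy_net(complete_edges(sprintf("K%d", 1:8)))
  # the real distance is the minimum possible: nothing can beat it
  res <- empirical_p(comp, c("K1", "K2"), c("K3", "K4"),
                     null_config(n_random = 50, rng_seed = 1))
  expect_equal(res$p, 0)
  expect_equal(res$real_distance, 1)
  expect_length(res$null_distances, 50)

  # adjacent pair on a long path: random sets are almost always farther
  nodes <- sprintf("P%02d", 1:30)
  pnet <- toy_net(path_edges(nodes))
  res2 <- empirical_p(pnet, "P01", "P02",
                      null_config(n_random = 200, rng_seed = 2))
  expect_lt(res2$p, 0.1)
})

test_that("empirical p-values are reproducible and live on the n_random grid", {
  net <- toy_net(random_edges(sprintf("N%02d", 1:40), 0.15))
  cfg <- null_config(n_random = 37, rng_seed = 99)
  a <- empirical_p(net, net$nodes[1:3], net$nodes[4:6], cfg)
  b <- empirical_p(net, net$nodes[1:3], net$nodes[4:6], cfg)
  expect_identical(a$null_distances, b$null_distances)
  expect_true(a$p %in% ((0:37) / 37))
})

test_that("random baselines recover exact expectations", {
  # complete graph: every draw is at distance 1
  comp <- toy_net(complete_edges(sprintf("K%d", 1:6)))
  expect_equal(random_baseline(comp, c("K1", "K2"), size = 2,
                               cfg = null_config(30, 5)), 1.0)
  # star center: every leaf at distance 1 (a draw equal to the center
  # itself has no valid pair and is skipped)
  expect_equal(random_baseline(star_net(), "C0", size = 1,
                               cfg = null_config(200, 6)), 1.0)
  # end of a 10-node path: expected distance to a uniformly drawn other
  # node is mean(1:9) = 5 under the distinct-pair convention
  pnet <- toy_net(path_edges(sprintf("P%02d", 1:10)))
  rb <- random_baseline(pnet, "P01", size = 1,
                        cfg = null_config(4000, 7))
  expect_equal(rb, 5, tolerance = 0.05)
})

test_that("distance tables cover all cells with directional significance", {
  b <- generate_bundle(synthetic_config(rng_seed = 3))
  lcc <- largest_connected_component(b$multiplex)
  net <- aggregate_multiplex(lcc)
  groups <- lapply(b$groups, intersect, y = net$nodes)
  tab <- distance_table(net, groups, null_config(n_random = 100, rng_seed = 8))

  expect_s3_class(tab, "distance_table")
  # 3x3 ordered group pairs + 3 group-vs-random + random-vs-random
  expect_equal(nrow(tab), 13)
  wide <- distance_matrix(tab)
  expect_equal(dim(wide), c(4, 5))

  # mean distance is symmetric even though p is directional
  m <- tibble::as_tibble(tab)
  for (a in names(groups)) for (bb in names(groups)) {
    expect_equal(
      m$mean_distance[m$group_a == a & m$group_b == bb],
      m$mean_distance[m$group_a == bb & m$group_b == a])
  }
  expect_true(all(m$p_empirical >= 0 & m$p_empirical <= 1, na.rm = TRUE))

  # planted groups sit closer together than random baselines
  for (g in names(groups)) {
    intra <- m$mean_distance[m$group_a == g & m$group_b == g]
    rand <- m$mean_distance[m$group_a == g & m$group_b == "random"]
    expect_lt(intra, rand)
  }

  # triangle of singleton groups: all cells 1, intra NA
  tri <- toy_net(complete_edges(c("A", "B", "C")))
  tt <- distance_table(tri, list(g1 = "A", g2 = "B", g3 = "C"),
                       null_config(n_random = 10, rng_seed = 1))
  td <- tibble::as_tibble(tt)
  inter <- td[td$group_a != td$group_b & td$group_b != "random", ]
  expect_true(all(inter$mean_distance == 1))
  expect_true(is.na(td$mean_distance[td$group_a == "g1" & td$group_b == "g1"]))
})

test_that("distance table writer emits long and wide TSVs", {
  tri <- toy_net(complete_edges(c("A", "B", "C", "D")))
  tab <- distance_table(tri, list(g1 = c("A", "B"), g2 = c("C", "D")),
                        null_config(n_random = 10, rng_seed = 2))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_table(tab, f)
  expect_true(file.exists(f))
  expect_true(file.exists(sub("\\.tsv$", "_matrix.tsv", f)))
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(tab))
})
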