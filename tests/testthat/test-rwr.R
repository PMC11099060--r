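two_node_mx <- function() {
  build_multiplex(list(l1 = tibble::tibble(from = "A", to = "B")))
}

test_that("full restart keeps all mass on the seeds", {
  mx <- random_multiplex(12, 2, 0.3)
  seeds <- mx$nodes[1:3]
  sv <- rwr_multiplex(mx, seeds, rwr_config(restart = 1.0))
  tab <- tibble::as_tibble(sv)
  expect_equal(sum(tab$score[tab$is_seed]), 1, tolerance = 1e-12)
  expect_true(all(tab$score[!tab$is_seed] == 0))
})

test_that("the two-node chain matches its closed-form solution", {
  # p(A) = r / (1 - (1 - r)^2) with r = 0.7
  sv <- rwr_multiplex(two_node_mx(), "A", rwr_config(restart = 0.7))
  tab <- tibble::as_tibble(sv)
  expect_equal(tab$score[tab$gene == "A"], 0.7 / 0.91, tolerance = 1e-10)
  expect_equal(tab$score[tab$gene == "B"], 0.21 / 0.91, tolerance = 1e-10)
  expect_true(attr(sv, "converged"))
})

test_that("iterative scores match the dense linear-algebra oracle", {
  withr::with_seed(207, {
    for (i in 1:12) {
      n <- sample(8:30, 1)
      L <- sample(1:3, 1)
      mx <- random_multiplex(n, L, 0.15)
      seeds <- sample(mx$nodes, sample(1:3, 1))
      r <- sample(c(0.3, 0.5, 0.7), 1)
      sv <- rwr_multiplex(mx, seeds, rwr_config(restart = r))
      oracle <- dense_rwr_oracle(mx, sort(seeds), restart = r, delta = 0.5)
      tab <- tibble::as_tibble(sv)
      expect_lt(max(abs(tab$score - oracle[tab$gene])), 1e-8)
      expect_equal(sum(tab$score), 1, tolerance = 1e-8)
      # the direct engine agrees with the iterative one
      dv <- rwr_multiplex(mx, seeds, rwr_config(restart = r),
                          engine = "direct")
      dtab <- tibble::as_tibble(dv)
      expect_lt(max(abs(tab$score - dtab$score[match(tab$gene, dtab$gene)])),
                1e-8)
    }
  })
})

test_that("non-seed mass decreases monotonically as restart grows", {
  withr::with_seed(11, {
    mx <- random_multiplex(20, 3, 0.2)
    seeds <- mx$nodes[1:2]
    mass <- vapply(c(0.3, 0.5, 0.7, 0.9, 1.0), function(r) {
      tab <- tibble::as_tibble(rwr_multiplex(mx, seeds, rwr_config(restart = r)))
      sum(tab$score[!tab$is_seed])
    }, double(1))
    expect_true(all(diff(mass) < 0))
  })
})

test_that("a single-layer multiplex reduces to standard RWR", {
  withr::with_seed(4, {
    nodes <- sprintf("N%02d", 1:15)
    edges <- random_edges(nodes, 0.25)
    mx1 <- build_multiplex(list(only = edges))
    seeds <- mx1$nodes[1:2]
    sv <- tibble::as_tibble(rwr_multiplex(mx1, seeds))
    # independent single-graph formulation: column-normalized adjacency
    nds <- mx1$nodes
    A <- matrix(0, length(nds), length(nds), dimnames = list(nds, nds))
    for (i in seq_len(nrow(mx1$layers$only))) {
      a <- mx1$layers$only$from[i]; b <- mx1$layers$only$to[i]
      A[a, b] <- 1; A[b, a] <- 1
    }
    W <- sweep(A, 2, pmax(colSums(A), 1), "/")
    s <- as.numeric(nds %in% seeds); s <- s / sum(s)
    p <- solve(diag(length(nds)) - 0.3 * W, 0.7 * s)
    expect_lt(max(abs(sv$score - (p / sum(p))[sv$gene])), 1e-8)
  })
})

test_that("interlayer jump probability changes scores but keeps them proper", {
  withr::with_seed(5, {
    mx <- random_multiplex(15, 3, 0.2)
    seeds <- mx$nodes[1]
    a <- tibble::as_tibble(rwr_multiplex(mx, seeds,
                                         rwr_config(interlayer_jump = 0.2)))
    b <- tibble::as_tibble(rwr_multiplex(mx, seeds,
                                         rwr_config(interlayer_jump = 0.8)))
    expect_equal(sum(a$score), 1, tolerance = 1e-8)
    expect_equal(sum(b$score), 1, tolerance = 1e-8)
    expect_false(isTRUE(all.equal(a$score, b$score[match(a$gene, b$gene)])))
  })
})

test_that("seeds outside the network are dropped with a message", {
  expect_message(sv <- rwr_multiplex(two_node_mx(), c("A", "ZZZ")),
                 "dropped: ZZZ")
  expect_equal(attr(sv, "seeds"), "A")
  expect_error(suppressMessages(rwr_multiplex(two_node_mx(), "ZZZ")),
               "no seed")
})

test_that("neighborhood extraction excludes seeds and breaks ties lexicographically", {
  # star: all leaves tie; the lexicographically smallest leaves win
  mx <- build_multiplex(list(
    l1 = tibble::tibble(from = "HUB", to = c("LEAF_C", "LEAF_A", "LEAF_B"))))
  sv <- rwr_multiplex(mx, "HUB")
  nb <- extract_neighborhood(sv, k = 2)
  expect_equal(nb$gene, c("LEAF_A", "LEAF_B"))
  expect_false("HUB" %in% nb$gene)

  # k larger than the number of non-seed genes returns them all, ranked
  nb_all <- extract_neighborhood(sv, k = 99)
  expect_equal(nrow(nb_all), 3)
  expect_equal(nb_all$rank, 1:3)
})

test_that("neighborhoods recover the seeds' planted community", {
  hits <- vapply(1:20, function(seed) {
    b <- generate_bundle(synthetic_config(rng_seed = seed))
    lcc <- largest_connected_component(b$multiplex)
    seeds <- intersect(b$groups$distal_like, lcc$nodes)
    kern <- rwr_kernel(lcc)
    nb <- onsetnet:::top_k_genes(kern$nodes,
                                 onsetnet:::kernel_scores(kern, seeds),
                                 seeds, 50)
    comm <- b$truth$community[match(nb, b$truth$gene)]
    mean(comm == "community1") >= 0.8
  }, logical(1))
  expect_gte(mean(hits), 0.5)
})

test_that("score tables write and tidy cleanly", {
  sv <- rwr_multiplex(two_node_mx(), "A")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_rwr_scores(sv, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_named(back, c("gene", "score", "is_seed", "rank"))
  g <- glance(sv)
  expect_equal(g$n_seeds, 1)
  expect_equal(g$score_sum, 1, tolerance = 1e-8)
})
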