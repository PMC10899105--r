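test_that("neighbor graphs hold exactly the two-step weights avoiding the center", {
  # star: center joined to 4 targets, no other beacons -> no two-step paths
  star <- bipartite_graph(data.frame(u = "a", v = paste0("v", 1:4),
                                     weight = 1L))
  ng <- neighbor_graph(star, "a")
  expect_equal(ng$ids, paste0("v", 1:4))
  expect_true(all(ng$W == 0))

  # two beacons sharing v1, v2: one two-step path between them
  sq <- bipartite_graph(data.frame(u = c("a", "a", "b", "b"),
                                   v = c("v1", "v2", "v1", "v2"),
                                   weight = 1L))
  ng <- neighbor_graph(sq, "a")
  expect_equal(ng$W["v1", "v2"], 1)

  # oracle equality on random graphs, both center types
  for (s in 1:4) {
    g <- random_bigraph(5, 5, p = 0.7, wmax = 3, seed = 200 + s)
    for (a in c(g$u_ids[1], g$v_ids[1])) {
      ng <- neighbor_graph(g, a)
      if (length(ng$ids) < 2) next
      for (pick in list(c(1, 2), c(2, length(ng$ids)))) {
        x <- ng$ids[pick[1]]; y <- ng$ids[pick[2]]
        if (x == y) next
        expect_equal(ng$W[x, y], oracle_w_i2(g, a, x, y))
      }
    }
  }
  expect_error(neighbor_graph(star, "zz"), "not in graph")
})

test_that("node evaluation follows the degree, component and ncut rules", {
  # fewer than four neighbors: not considered
  tri <- bipartite_graph(data.frame(u = "a", v = paste0("v", 1:3),
                                    weight = 2L))
  expect_equal(evaluate_node(neighbor_graph(tri, "a"))$status,
               "too_few_neighbors")

  # two disconnected cliques: ncut exactly 0, parts are the components
  W <- matrix(0, 6, 6, dimnames = list(paste0("n", 1:6), paste0("n", 1:6)))
  W[1:3, 1:3] <- 5; W[4:6, 4:6] <- 5; diag(W) <- 0
  ev <- evaluate_node(make_ng(W))
  expect_equal(ev$status, "evaluated")
  expect_equal(ev$ncut, 0)
  expect_setequal(ev$part1, paste0("n", 1:3))
  expect_setequal(ev$part2, paste0("n", 4:6))

  # more than two components: unevaluable
  W3 <- matrix(0, 6, 6, dimnames = list(paste0("n", 1:6), paste0("n", 1:6)))
  W3[1, 2] <- W3[2, 1] <- 1; W3[3, 4] <- W3[4, 3] <- 1
  W3[5, 6] <- W3[6, 5] <- 1
  expect_equal(evaluate_node(make_ng(W3))$status, "unevaluable_components")

  # the dumbbell p,q | r,s: minimum ncut is 2/21
  Wd <- matrix(0, 4, 4, dimnames = list(c("p", "q", "r", "s"),
                                        c("p", "q", "r", "s")))
  Wd["p", "q"] <- Wd["q", "p"] <- 10
  Wd["r", "s"] <- Wd["s", "r"] <- 10
  Wd["q", "r"] <- Wd["r", "q"] <- 1
  ev <- evaluate_node(make_ng(Wd))
  expect_equal(ev$ncut, 2 / 21)
  expect_setequal(ev$part1, c("p", "q"))
  expect_setequal(ev$part2, c("r", "s"))
})

test_that("minimum-ncut search matches subset-enumeration on random subgraphs", {
  for (s in 1:25) {
    d <- withr::with_seed(300 + s, sample(4:9, 1))
    W <- withr::with_seed(400 + s, {
      M <- matrix(rpois(d * d, 2), d, d)
      M <- M + t(M); diag(M) <- 0
      dimnames(M) <- list(paste0("n", 1:d), paste0("n", 1:d))
      M
    })
    if (max(minipath:::affinity_components(W)) != 1) next
    want <- oracle_min_ncut(W)
    ev <- evaluate_node(make_ng(W))
    expect_equal(ev$ncut, want$ncut, tolerance = 1e-12)
  }
})

test_that("spectral sweep recovers planted partitions on larger subgraphs", {
  # two planted 10-node blocks, weak bridge; force the spectral path
  withr::with_seed(55, {
    d <- 20
    W <- matrix(0, d, d)
    W[1:10, 1:10] <- rpois(100, 6)
    W[11:20, 11:20] <- rpois(100, 6)
    W <- W + t(W); diag(W) <- 0
    W[10, 11] <- W[11, 10] <- 1
    dimnames(W) <- list(sprintf("n%02d", 1:d), sprintf("n%02d", 1:d))
  })
  ev <- evaluate_node(make_ng(W), exact_max = 0)
  expect_setequal(ev$part1, sprintf("n%02d", 1:10))
  # and on two-component graphs the components come back exactly
  W0 <- W; W0[10, 11] <- W0[11, 10] <- 0
  ev0 <- evaluate_node(make_ng(W0), exact_max = 0)
  expect_equal(ev0$ncut, 0)
})

test_that("batched evaluation equals the single-node route", {
  g <- random_bigraph(8, 8, p = 0.7, wmax = 3, seed = 77)
  cuts <- evaluate_nodes(g)
  for (a in node_ids(g)[c(1, 5, 9, 16)]) {
    single <- evaluate_node(neighbor_graph(g, a))
    row <- cuts[cuts$node == a, ]
    expect_equal(row$status, single$status)
    expect_equal(row$ncut, single$ncut)
    expect_setequal(row$part1[[1]], single$part1)
  }
})

test_that("splitting rewires edges by partition and conserves weight", {
  g <- random_bigraph(8, 8, p = 0.8, wmax = 3, seed = 88)
  cuts <- evaluate_nodes(g)
  expect_true(all(cuts$ncut[cuts$status == "evaluated"] >= 0))
  expect_true(all(cuts$ncut[cuts$status == "evaluated"] <= 2))

  # cutoff 0 never splits
  expect_equal(length(split_nodes(g, cuts, 0)$split_map), 0)
  expect_error(split_nodes(g, cuts, -1), "non-negative")

  # split the single best candidate: node count +1, edges partitioned
  ev <- cuts[cuts$status == "evaluated", ]
  best <- ev$node[which.min(ev$ncut)]
  cutoff <- min(ev$ncut) + 1e-9
  one <- cuts[cuts$node == best, ]
  sp <- split_nodes(g, cuts[cuts$node == best, , drop = FALSE], cutoff)
  expect_equal(n_nodes(sp$graph), n_nodes(g) + 1)
  expect_equal(total_weight(sp$graph), total_weight(g))
  m <- sp$split_map[[best]]
  e2 <- sp$graph$edges
  nb1 <- sort(unique(c(e2$v[e2$u == m$new[1]], e2$u[e2$v == m$new[1]])))
  expect_equal(nb1, sort(m$part1))

  # when both endpoints of an edge are split, that edge disappears
  ge <- bipartite_graph(data.frame(
    u = c("a", "a", "a", "a", "b", "c", "d"),
    v = c("v1", "v2", "v3", "v4", "v1", "v1", "v1"),
    weight = 2L))
  forced <- structure(data.frame(
    node = c("a", "v1"), status = "evaluated", ncut = 0.01,
    part1 = I(list(c("v1", "v2"), c("a", "b"))),
    part2 = I(list(c("v3", "v4"), c("c", "d"))),
    stringsAsFactors = FALSE),
    class = c("node_cut_table", "data.frame"))
  both <- split_nodes(ge, forced, 0.05)
  expect_setequal(names(both$split_map), c("a", "v1"))
  e3 <- both$graph$edges
  # the a-v1 edge is gone entirely
  expect_false(any(grepl("^a_s", e3$u) & grepl("^v1_s", e3$v)))
  expect_equal(total_weight(both$graph), total_weight(ge) - 2L)
  # remaining edges follow the partitions
  expect_setequal(e3$u[e3$v == "v1_s1"], "b")
  expect_setequal(e3$u[e3$v == "v1_s2"], c("c", "d"))
  expect_setequal(e3$v[e3$u == "a_s1"], "v2")
  expect_setequal(e3$v[e3$u == "a_s2"], c("v3", "v4"))
})

test_that("fused nodes get lower normalized cuts than unaltered nodes", {
  sc <- place_nodes(800, c(120, 260), 0.5, seed = 91)
  g <- simulate_graph(sc, sim_params(10, 20), seed = 92)
  inj <- inject_fused_nodes(g, 0.10, seed = 93)
  fused <- inj$ledger$fusions$fused_id
  normal <- withr::with_seed(94, sample(setdiff(node_ids(inj$graph), fused), 60))
  cuts <- evaluate_nodes(inj$graph, nodes = c(fused, normal))
  nc <- stats::setNames(cuts$ncut, cuts$node)[cuts$status == "evaluated"]
  nf <- nc[names(nc) %in% fused]
  nn <- nc[!names(nc) %in% fused]
  expect_gt(mean(nn), mean(nf))
  expect_lt(stats::wilcox.test(nf, nn, alternative = "less")$p.value, 1e-4)
})
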