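test_that("node placement is uniform in the mask and reproducible", {
  sc <- place_nodes(4000, c(200, 450), 0.5, seed = 1)
  expect_equal(nrow(sc$coords), 4000)
  expect_true(all(sc$coords$x >= 0 & sc$coords$x <= 200))
  expect_true(all(sc$coords$y >= 0 & sc$coords$y <= 450))
  expect_identical(place_nodes(4000, c(200, 450), 0.5, seed = 1)$coords,
                   sc$coords)

  # type counts inside the binomial 99% interval
  big <- place_nodes(10000, c(200, 450), 0.5, seed = 2)
  n_u <- sum(big$coords$type == "U")
  expect_gt(n_u, qbinom(0.005, 10000, 0.5))
  expect_lt(n_u, qbinom(0.995, 10000, 0.5))

  # matrix masks restrict support
  mask <- matrix(FALSE, 50, 50)
  mask[1:10, ] <- TRUE
  mc <- place_nodes(500, mask, 0.5, seed = 3)
  expect_true(all(mc$coords$x <= 10))
  expect_error(place_nodes(10, matrix(FALSE, 5, 5)), "zero area")
})

test_that("spread follows the diffusion-length relation sqrt(8dDt)", {
  p <- sim_params(10, D = 2, t = 25, d = 2)
  expect_equal(p$spread, sqrt(8 * 2 * 2 * 25))
  expect_silent(sim_params(10, spread = sqrt(800), D = 2, t = 25, d = 2))
  expect_error(sim_params(10, spread = 30, D = 2, t = 25, d = 2),
               "inconsistent")
})

test_that("edge weights follow the Gaussian-kernel Poisson law", {
  # two coincident nodes: mean weight = amplitude
  sc <- structure(list(coords = data.frame(
    id = c("a", "b"), type = c("U", "V"), x = c(5, 5), y = c(5, 5)),
    mask = c(10, 10), seed = 0), class = "sim_scene")
  p10 <- sim_params(10, 50)
  draws <- vapply(1:2000, function(s) {
    e <- simulate_graph(sc, p10, seed = s)$edges
    if (nrow(e)) sum(e$weight) else 0L
  }, numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 10), 3 * se)

  # at distance = spread the mean is amplitude / e
  sc$coords$x <- c(0, 50)
  sc$coords$y <- c(0, 0)
  draws <- vapply(1:3000, function(s) {
    e <- simulate_graph(sc, p10, seed = s)$edges
    if (nrow(e)) sum(e$weight) else 0L
  }, numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 10 * exp(-1)), 3 * se)

  # amplitude zero gives an empty edge set; same-type pairs never connect
  expect_equal(n_edges(simulate_graph(sc, sim_params(0, 50), seed = 1)), 0)
  sc2 <- place_nodes(200, c(50, 50), 0.5, seed = 4)
  g <- simulate_graph(sc2, sim_params(5, 20), seed = 4)
  ty <- stats::setNames(sc2$coords$type, sc2$coords$id)
  expect_true(all(ty[g$edges$u] == "U" & ty[g$edges$v] == "V"))
})

test_that("weight distribution at fixed distance passes a Poisson GOF check", {
  n_rep <- 1e5
  a <- 6; sigma <- 50; dist <- 30
  lambda <- a * exp(-dist^2 / sigma^2)
  sc <- structure(list(coords = data.frame(
    id = c("a", "b"), type = c("U", "V"), x = c(0, dist), y = c(0, 0)),
    mask = c(100, 100), seed = 0), class = "sim_scene")
  # one big scene replicate: many iid pairs at the same distance
  reps <- withr::with_seed(99, {
    mm <- minipath:::model_means(sc, sim_params(a, sigma))
    stats::rpois(n_rep, mm$mu[1, 1])
  })
  hi <- max(reps)
  obs <- tabulate(reps + 1L, nbins = hi + 1L)
  expp <- dpois(0:hi, lambda)
  grp <- pmin(0:hi, qpois(0.9999, lambda))  # pool the far tail
  o <- tapply(obs, grp, sum)
  e <- tapply(expp, grp, sum) * n_rep
  keep <- e > 5
  chi2 <- sum((o[keep] - e[keep])^2 / e[keep])
  expect_lt(chi2, qchisq(0.999, sum(keep) - 1))
})

test_that("expected degree grows with spread", {
  sc <- place_nodes(600, c(100, 200), 0.5, seed = 5)
  degs <- vapply(c(5, 15, 40), function(s) {
    mean(node_degree(simulate_graph(sc, sim_params(5, s), seed = 6)))
  }, numeric(1))
  expect_true(all(diff(degs) > 0))
})

test_that("crosslink injection adds the ledgered unit weights", {
  g <- random_bigraph(20, 20, p = 0.4, wmax = 4, seed = 11)
  w0 <- total_weight(g)
  out <- inject_spurious_crosslinks(g, 0.10, seed = 12)
  expect_equal(nrow(out$ledger$crosslinks), round(0.10 * w0))
  expect_equal(total_weight(out$graph), w0 + round(0.10 * w0))
  # endpoints always have opposite types
  expect_true(all(out$ledger$crosslinks$u %in% g$u_ids))
  expect_true(all(out$ledger$crosslinks$v %in% g$v_ids))

  noop <- inject_spurious_crosslinks(g, 0, seed = 12)
  expect_equal(noop$graph$edges, g$edges)
  expect_equal(nrow(noop$ledger$crosslinks), 0)
  expect_error(inject_spurious_crosslinks(bipartite_graph(NULL), 0.1),
               "empty graph")
})

test_that("fusion events merge edge weights additively", {
  g <- random_bigraph(100, 100, p = 0.1, wmax = 3, seed = 13)
  out <- inject_fused_nodes(g, 0.05, seed = 14)
  expect_equal(nrow(out$ledger$fusions), round(0.05 * 200))
  expect_equal(n_nodes(out$graph), 200 - round(0.05 * 200))
  # fused pairs share a type
  same_type <- with(out$ledger$fusions,
    (original_1 %in% g$u_ids) == (original_2 %in% g$u_ids))
  expect_true(all(same_type))
  # per-neighbor weights are the sums of the originals'
  f <- out$ledger$fusions[1, ]
  olde <- g$edges
  for (orig_u in intersect(c(f$original_1, f$original_2), g$u_ids)) {
    nb <- olde[olde$u %in% c(f$original_1, f$original_2), ]
    expected <- tapply(nb$weight, nb$v, sum)
    got <- out$graph$edges[out$graph$edges$u == f$fused_id, ]
    expect_equal(stats::setNames(as.integer(expected[got$v]), NULL),
                 got$weight)
    break
  }
  expect_equal(inject_fused_nodes(g, 0, seed = 1)$graph$edges, g$edges)
  small <- random_bigraph(2, 2, p = 1, seed = 1)
  expect_error(inject_fused_nodes(small, 1, seed = 1), "not enough")
})

test_that("reactivity bias multiplies Poisson means per biased endpoint", {
  sc <- structure(list(coords = data.frame(
    id = c("a", "b"), type = c("U", "V"), x = c(0, 0), y = c(0, 0)),
    mask = c(10, 10), seed = 0), class = "sim_scene")
  p <- sim_params(5, 50)
  # fraction 0 reproduces simulate_graph draw-for-draw
  plain <- simulate_graph(sc, p, seed = 21)
  nob <- inject_reactivity_bias(sc, p, 0, bias_factor = 2, seed = 21)
  expect_equal(nob$graph$edges, plain$edges)

  # both endpoints biased at factor 2: mean weight 5 * 4
  draws <- vapply(1:3000, function(s) {
    out <- inject_reactivity_bias(sc, p, 1, bias_factor = 2, seed = s)
    e <- out$graph$edges
    if (nrow(e)) sum(e$weight) else 0L
  }, numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 20), 3 * se)
})
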