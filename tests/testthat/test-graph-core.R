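test_that("UEI tables round-trip through TSV and validate their contract", {
  tab <- toy_uei()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_uei_table(tab, path)
  back <- read_uei_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))

  empty <- uei_table(tab[0, ])
  write_uei_table(empty, path)
  expect_equal(nrow(read_uei_table(path)), 0)

  bad <- as.data.frame(tab)
  bad$read_count[3] <- 0L
  utils::write.table(bad, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_uei_table(path), "line\\(s\\): 4")
  expect_error(read_uei_table(textConnection("beacon_id\ttarget_id\n")),
               "missing column")
  expect_error(uei_table(transform(as.data.frame(tab),
                                   uei_id = rep("dup", 5))),
               "duplicate uei_id")
})

test_that("aggregation counts distinct UEIs, never read sums", {
  g <- aggregate_ueis(toy_uei())
  w <- stats::setNames(g$edges$weight, paste(g$edges$u, g$edges$v))
  expect_equal(w[["b1 t1"]], 3L)
  expect_equal(w[["b1 t2"]], 1L)
  expect_equal(w[["b2 t2"]], 1L)

  # node ids may not straddle the bipartition
  clash <- uei_table(data.frame(beacon_id = "x1", target_id = "x1",
                                uei_id = "e1", read_count = 1L))
  expect_error(aggregate_ueis(clash), "both beacon and target")

  # random table: weights recount the UEIs exactly
  withr::with_seed(7, {
    n <- 100
    tab <- uei_table(data.frame(
      beacon_id = sample(paste0("b", 1:5), n, replace = TRUE),
      target_id = sample(paste0("t", 1:2), n, replace = TRUE),
      uei_id = paste0("e", 1:n),
      read_count = sample.int(9L, n, replace = TRUE)))
  })
  g <- aggregate_ueis(tab)
  expect_equal(total_weight(g), 100L)
  brute <- table(paste(tab$beacon_id, tab$target_id))
  expect_equal(sort(as.integer(brute)), sort(g$edges$weight))
})

test_that("read count filter keeps records at or above the threshold", {
  tab <- toy_uei()
  expect_equal(nrow(read_count_filter(tab, 4)), 2)
  expect_equal(as.data.frame(read_count_filter(tab, 1)),
               as.data.frame(tab))
  expect_equal(nrow(read_count_filter(tab, 99)), 0)
  # monotone: stricter filters keep a subset
  for (k in 1:5) {
    expect_true(all(read_count_filter(tab, k + 1)$uei_id %in%
                      read_count_filter(tab, k)$uei_id))
  }
})

test_that("iterative low-product filter reaches a stable fixed point", {
  # unit-weight path: every node has < 2 products somewhere in the cascade
  path3 <- bipartite_graph(data.frame(u = c("u1", "u2"), v = "v1",
                                      weight = 1L))
  expect_equal(n_nodes(iterative_low_product_filter(path3)), 0)

  # K2,2 with weight 2 everywhere: all nodes have 4 products, untouched
  k22 <- bipartite_graph(expand.grid(u = c("u1", "u2"), v = c("v1", "v2"),
                                     stringsAsFactors = FALSE) |>
                           transform(weight = 2L))
  expect_equal(iterative_low_product_filter(k22)$edges, k22$edges)

  # a pendant with a single weight-2 edge has exactly 2 products: kept
  core <- expand.grid(u = c("u1", "u2"), v = c("v1", "v2"),
                      stringsAsFactors = FALSE)
  core$weight <- 3L
  pend <- rbind(core, data.frame(u = "u3", v = "v1", weight = 2L))
  gf <- iterative_low_product_filter(bipartite_graph(pend))
  expect_true("u3" %in% gf$u_ids)

  # idempotence on random graphs
  for (s in 1:5) {
    g <- random_bigraph(8, 8, p = 0.2, wmax = 2, seed = s)
    f1 <- iterative_low_product_filter(g)
    f2 <- iterative_low_product_filter(f1)
    expect_equal(f1$edges, f2$edges)
    expect_true(all(node_strength(f1) >= 2) || n_nodes(f1) == 0)
  }
})

test_that("largest component selection is deterministic and measured", {
  g <- random_bigraph(6, 6, p = 0.6, seed = 3)
  lc <- largest_component(g)
  if (lc$fraction == 1) expect_equal(sort(node_ids(lc$graph)),
                                     sort(node_ids(g)))

  # two components of 6 and 4 nodes
  comp1 <- data.frame(u = rep(paste0("au", 1:3), each = 3),
                      v = rep(paste0("av", 1:3), 3), weight = 1L)
  comp2 <- data.frame(u = rep(paste0("bu", 1:2), each = 2),
                      v = rep(paste0("bv", 1:2), 2), weight = 1L)
  two <- bipartite_graph(rbind(comp1, comp2))
  lc <- largest_component(two)
  expect_equal(n_nodes(lc$graph), 6)
  expect_equal(lc$fraction, 0.6)
  # the 80% reconstructability rule flags this dataset
  expect_lt(lc$fraction, 0.8)

  empty <- bipartite_graph(NULL)
  expect_equal(largest_component(empty)$fraction, 0)
})

test_that("graph exports round-trip (edge list, MTX, metadata)", {
  g <- random_bigraph(5, 7, p = 0.5, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, path)
  back <- read_edge_list(path)
  expect_equal(back$edges[order(back$edges$u, back$edges$v), ],
               g$edges[order(g$edges$u, g$edges$v), ],
               ignore_attr = TRUE)

  mtx <- withr::local_tempfile(fileext = ".mtx")
  write_adjacency_mtx(g, mtx)
  A <- Matrix::readMM(mtx)
  expect_equal(unname(as.matrix(A)), unname(as.matrix(adjacency_matrix(g))))
  expect_equal(readLines(sub("\\.mtx$", ".rownames.txt", mtx)), g$u_ids)

  meta <- withr::local_tempfile(fileext = ".json")
  write_graph_meta(g, meta)
  got <- jsonlite::read_json(meta, simplifyVector = TRUE)
  expect_equal(got$n_edges, n_edges(g))
  expect_equal(got$total_weight, total_weight(g))
})
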