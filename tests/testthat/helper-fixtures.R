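# Shared fixtures and independent oracles.  The oracles here are written
# from first principles (lookup tables, subset enumeration) so they share
# no code path with the package implementations they check.

# random bipartite graph with nu + nv nodes, edge probability p, integer
# weights in wmax
random_bigraph <- function(nu, nv, p = 0.4, wmax = 5, seed = 1) {
  withr::with_seed(seed, {
    us <- paste0("u", seq_len(nu))
    vs <- paste0("v", seq_len(nv))
    pairs <- expand.grid(u = us, v = vs, stringsAsFactors = FALSE)
    keep <- runif(nrow(pairs)) < p
    e <- pairs[keep, , drop = FALSE]
    e$weight <- sample.int(wmax, nrow(e), replace = TRUE)
    bipartite_graph(e, us, vs)
  })
}

# independent indirect-path oracle: weight lookup by pair key, explicit
# path enumeration
oracle_w_i3 <- function(g) {
  e <- g$edges
  wmap <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(e))) {
    assign(paste(e$u[r], e$v[r]), e$weight[r], envir = wmap)
  }
  wt <- function(u, v) {
    key <- paste(u, v)
    if (exists(key, envir = wmap)) get(key, envir = wmap) else 0
  }
  vapply(seq_len(nrow(e)), function(r) {
    x <- e$u[r]; y <- e$v[r]
    acc <- 0
    for (a in setdiff(g$v_ids, y)) {
      wxa <- wt(x, a)
      if (wxa == 0) next
      for (b in setdiff(g$u_ids, x)) {
        acc <- acc + wxa * wt(b, a) * wt(b, y)
      }
    }
    acc
  }, numeric(1))
}

# independent two-step neighbor-weight oracle for center a
oracle_w_i2 <- function(g, a, x, y) {
  e <- g$edges
  in_u <- a %in% g$u_ids
  wt <- function(u, v) {
    hit <- e$weight[e$u == u & e$v == v]
    if (length(hit)) hit else 0
  }
  others <- setdiff(if (in_u) g$u_ids else g$v_ids, a)
  sum(vapply(others, function(b) {
    if (in_u) wt(b, x) * wt(b, y) else wt(x, b) * wt(y, b)
  }, numeric(1)))
}

# independent exhaustive minimum normalized cut via subset enumeration
oracle_min_ncut <- function(W) {
  d <- nrow(W)
  deg <- rowSums(W)
  best <- Inf
  best_side <- NULL
  for (size in 1:floor(d / 2)) {
    combs <- utils::combn(d, size)
    for (cidx in seq_len(ncol(combs))) {
      s1 <- combs[, cidx]
      if (size == d / 2 && !(1 %in% s1)) next  # avoid double counting
      s2 <- setdiff(seq_len(d), s1)
      cutw <- sum(W[s1, s2])
      nc <- if (cutw == 0) 0 else cutw / sum(deg[s1]) + cutw / sum(deg[s2])
      if (nc < best) {
        best <- nc
        best_side <- s1
      }
    }
  }
  list(ncut = best, side1 = seq_len(d) %in% best_side)
}

# hand-built neighbor graph from an affinity matrix
make_ng <- function(W, center = "a") {
  ids <- rownames(W)
  structure(list(center = center, ids = ids, W = W),
            class = "neighbor_graph")
}

# small UEI table fixture
toy_uei <- function() {
  uei_table(data.frame(
    beacon_id = c("b1", "b1", "b1", "b1", "b2"),
    target_id = c("t1", "t1", "t1", "t2", "t2"),
    uei_id = paste0("e", 1:5),
    read_count = c(1L, 2L, 3L, 4L, 5L),
    stringsAsFactors = FALSE))
}
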