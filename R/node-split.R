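# Fused-node detection.  For each node a, its neighbors S_a (all of the
# opposite type) are connected among themselves by two-step paths that
# avoid a: w_i2(x, y) = sum_{b != a} w(b, x) w(b, y).  The neighbors of a
# genuine polony form one well-knit subgraph; the neighbors of a fused
# node fall into two groups with little weight between them, so the
# minimum normalized cut of the neighbor subgraph separates fused from
# normal nodes.

#' Two-step neighbor subgraph of a node
#'
#' @param g a [bipartite_graph()].
#' @param a a node id of `g`.
#' @return an object of class `neighbor_graph`: list with `center`, `ids`
#'   (the neighbors S_a, sorted), and `W`, the dense symmetric `w_i2`
#'   matrix over `ids` (zero diagonal; paths through `a` excluded).
#' @export
neighbor_graph <- function(g, a) {
  if (!a %in% node_ids(g)) stop("node ", a, " not in graph")
  in_u <- a %in% g$u_ids
  e <- g$edges
  if (in_u) {
    sel <- e$u == a
    s_a <- sort(e$v[sel])
    wa <- e$weight[sel][order(e$v[sel])]
  } else {
    sel <- e$v == a
    s_a <- sort(e$u[sel])
    wa <- e$weight[sel][order(e$u[sel])]
  }
  if (!length(s_a)) {
    return(structure(list(center = a, ids = character(),
                          W = matrix(0, 0, 0)), class = "neighbor_graph"))
  }
  A <- adjacency_matrix(g)
  if (in_u) {
    M <- Matrix::crossprod(A)    # V x V two-step products
    idx <- match(s_a, g$v_ids)
  } else {
    M <- Matrix::tcrossprod(A)   # U x U
    idx <- match(s_a, g$u_ids)
  }
  W <- as.matrix(M[idx, idx, drop = FALSE]) - outer(wa, wa)
  diag(W) <- 0
  dimnames(W) <- list(s_a, s_a)
  structure(list(center = a, ids = s_a, W = W), class = "neighbor_graph")
}

# connected components of a dense non-negative affinity matrix;
# returns an integer membership vector
affinity_components <- function(W) {
  n <- nrow(W)
  if (n == 0) return(integer())
  B <- (W > 0) * 1
  comp <- integer(n)
  cur <- 0L
  while (any(comp == 0L)) {
    cur <- cur + 1L
    reach <- logical(n)
    reach[which(comp == 0L)[1]] <- TRUE
    repeat {
      grown <- reach | (as.vector(B %*% reach) > 0)
      if (identical(grown, reach)) break
      reach <- grown
    }
    comp[reach] <- cur
  }
  comp
}

#' Normalized cut of a bipartition
#'
#' `cut / assoc(S1) + cut / assoc(S2)` with ordered-pair association sums
#' (each within-side edge counted twice, cut edges once per side), so the
#' value lies in `[0, 2]`.
#'
#' @param W symmetric non-negative affinity matrix (zero diagonal).
#' @param side1 logical vector: membership of side 1.
#' @return the normalized cut value.
#' @export
ncut_value <- function(W, side1) {
  stopifnot(length(side1) == nrow(W), any(side1), !all(side1))
  deg <- rowSums(W)
  cut <- sum(W[side1, !side1])
  a1 <- sum(deg[side1])
  a2 <- sum(deg[!side1])
  if (cut == 0) return(0)
  cut / a1 + cut / a2
}

# exact minimum-ncut bipartition by enumeration (one node pinned to side
# 1, all 2^(d-1) - 1 bipartitions scored in one vectorized pass)
exhaustive_min_ncut <- function(W) {
  d <- nrow(W)
  deg <- rowSums(W)
  tot <- sum(deg)
  masks <- 0:(2^(d - 1) - 2)
  bits <- matrix(0, length(masks), d)
  bits[, 1] <- 1
  for (b in seq_len(d - 1)) {
    bits[, b + 1] <- bitwAnd(bitwShiftR(masks, b - 1L), 1L)
  }
  q1 <- rowSums((bits %*% W) * bits)
  a1 <- as.vector(bits %*% deg)
  cutv <- a1 - q1
  nc <- ifelse(cutv == 0, 0, cutv / a1 + cutv / (tot - a1))
  best <- which.min(nc)
  list(side1 = bits[best, ] > 0, ncut = nc[best])
}

# Fiedler-style spectral bipartition: second eigenvector of the
# symmetrically normalized affinity, nodes ordered along the generalized
# eigenvector (ties by id), best prefix cut by exact ncut sweep
spectral_bipartition <- function(W, ids = rownames(W)) {
  d <- nrow(W)
  deg <- rowSums(W)
  ds <- 1 / sqrt(deg)
  N <- W * outer(ds, ds)
  if (d <= 400) {
    v2 <- eigen(N, symmetric = TRUE)$vectors[, 2]
  } else {
    f <- function(x, extra = NULL) as.vector(N %*% x)
    res <- local_seed(7L, igraph::arpack(
      f, sym = TRUE,
      options = list(n = d, nev = 2, ncv = min(d, 20), which = "LA",
                     maxiter = 5000)))
    v2 <- res$vectors[, 2]
  }
  u <- ds * v2
  ord <- order(u, ids)
  C <- W[ord, ord]
  x <- vapply(seq_len(d), function(k) sum(C[k, seq_len(k)]), numeric(1))
  q1 <- 2 * cumsum(x)
  a1 <- cumsum(deg[ord])
  k <- seq_len(d - 1)
  cutv <- a1[k] - q1[k]
  nc <- ifelse(cutv == 0, 0, cutv / a1[k] + cutv / (sum(deg) - a1[k]))
  best <- which.min(nc)
  side1 <- logical(d)
  side1[ord[seq_len(best)]] <- TRUE
  list(side1 = side1, ncut = nc[best])
}

#' Evaluate one node's neighbor subgraph
#'
#' A node is scored by the minimum normalized cut of its two-step
#' neighbor subgraph.  Nodes with fewer than `min_degree` neighbors are
#' not considered; a neighbor subgraph that splits into exactly two
#' connected components gets ncut 0.0 with the components as partitions;
#' one with more than two components is flagged unevaluable (too sparse
#' to tell a fusion from missing data).  Otherwise the minimum ncut
#' bipartition is found exactly by enumeration for small subgraphs
#' (`|S_a| <= exact_max`) and by a spectral sweep above that.
#'
#' @param ng a [neighbor_graph()].
#' @param min_degree minimum neighbor count to evaluate (default 4).
#' @param exact_max largest subgraph size for exact enumeration
#'   (default 13; ncut minimization is NP-hard, so larger subgraphs use
#'   the spectral relaxation).
#' @return a list with `node`, `status` (`evaluated`,
#'   `too_few_neighbors` or `unevaluable_components`), `ncut` (NA unless
#'   evaluated) and `part1`/`part2` (character vectors of neighbor ids).
#' @export
evaluate_node <- function(ng, min_degree = 4, exact_max = 13) {
  out <- list(node = ng$center, status = "evaluated", ncut = NA_real_,
              part1 = character(), part2 = character())
  d <- length(ng$ids)
  if (d < min_degree) {
    out$status <- "too_few_neighbors"
    return(out)
  }
  comp <- affinity_components(ng$W)
  ncomp <- max(comp)
  if (ncomp > 2) {
    out$status <- "unevaluable_components"
    return(out)
  }
  if (ncomp == 2) {
    out$ncut <- 0
    out$part1 <- ng$ids[comp == 1]
    out$part2 <- ng$ids[comp == 2]
    return(out)
  }
  res <- if (d <= exact_max) exhaustive_min_ncut(ng$W)
         else spectral_bipartition(ng$W, ng$ids)
  out$ncut <- res$ncut
  out$part1 <- ng$ids[res$side1]
  out$part2 <- ng$ids[!res$side1]
  out
}

#' Evaluate many nodes' neighbor subgraphs
#'
#' Batched version of [neighbor_graph()] + [evaluate_node()], sharing the
#' two-step product matrices across nodes.
#'
#' @param g a [bipartite_graph()].
#' @param nodes node ids to evaluate (default: all).
#' @param min_degree,exact_max see [evaluate_node()].
#' @return a `node_cut_table`: data frame with columns `node`, `status`,
#'   `ncut` and list columns `part1`, `part2`.
#' @export
evaluate_nodes <- function(g, nodes = NULL, min_degree = 4, exact_max = 13) {
  if (is.null(nodes)) nodes <- node_ids(g)
  stopifnot(all(nodes %in% node_ids(g)))
  A <- adjacency_matrix(g)
  e <- g$edges
  nbr_u <- split(e$v, e$u)
  wt_u <- split(e$weight, e$u)
  nbr_v <- split(e$u, e$v)
  wt_v <- split(e$weight, e$v)
  # for dense-ish graphs the two-step products via BLAS on a dense copy
  # are much faster than sparse algebra, and the |V|^2 result is modest
  # at the scales evaluated here
  dense <- Matrix::nnzero(A) > 0.02 * length(A)
  Ad <- if (dense) as.matrix(A) else NULL
  densify <- function(M) {
    if (Matrix::nnzero(M) > 0.05 * length(M)) as.matrix(M) else M
  }
  MU <- if (any(nodes %in% g$u_ids)) {
    if (dense) crossprod(Ad) else densify(Matrix::crossprod(A))
  }
  MV <- if (any(nodes %in% g$v_ids)) {
    if (dense) tcrossprod(Ad) else densify(Matrix::tcrossprod(A))
  }
  res <- vector("list", length(nodes))
  for (ii in seq_along(nodes)) {
    a <- nodes[ii]
    in_u <- a %in% g$u_ids
    s_a <- if (in_u) nbr_u[[a]] else nbr_v[[a]]
    if (is.null(s_a) || length(s_a) < min_degree) {
      res[[ii]] <- list(node = a, status = "too_few_neighbors",
                        ncut = NA_real_, part1 = character(),
                        part2 = character())
      next
    }
    o <- order(s_a)
    wa <- (if (in_u) wt_u[[a]] else wt_v[[a]])[o]
    s_a <- s_a[o]
    idx <- if (in_u) match(s_a, g$v_ids) else match(s_a, g$u_ids)
    W <- as.matrix((if (in_u) MU else MV)[idx, idx, drop = FALSE]) -
      outer(wa, wa)
    diag(W) <- 0
    dimnames(W) <- list(s_a, s_a)
    ng <- structure(list(center = a, ids = s_a, W = W),
                    class = "neighbor_graph")
    res[[ii]] <- evaluate_node(ng, min_degree = min_degree,
                               exact_max = exact_max)
  }
  structure(data.frame(
    node = vapply(res, `[[`, character(1), "node"),
    status = vapply(res, `[[`, character(1), "status"),
    ncut = vapply(res, `[[`, numeric(1), "ncut"),
    part1 = I(lapply(res, `[[`, "part1")),
    part2 = I(lapply(res, `[[`, "part2")),
    stringsAsFactors = FALSE),
    class = c("node_cut_table", "data.frame"))
}

#' Split nodes below a normalized-cut cutoff
#'
#' Every evaluated node with `ncut < cutoff` is replaced by two nodes
#' `<id>_s1` and `<id>_s2` inheriting its edges to the two neighbor
#' partitions respectively.  An edge whose two endpoints are both split
#' is deleted (its assignment would be ambiguous).  All decisions are
#' taken on the pre-split cut table in a single pass.
#'
#' @param g the [bipartite_graph()] the cut table was computed on.
#' @param cuts a [evaluate_nodes()] table.
#' @param cutoff non-negative ncut threshold; [split_quantile_cutoff()]
#'   derives one from the evaluated ncut distribution.
#' @return `list(graph, split_map)`; `split_map` is a named list
#'   `old id -> list(new, part1, part2)`.
#' @export
split_nodes <- function(g, cuts, cutoff) {
  if (length(cutoff) != 1 || !is.finite(cutoff) || cutoff < 0) {
    stop("cutoff must be a single non-negative number")
  }
  sel <- cuts$status == "evaluated" & !is.na(cuts$ncut) & cuts$ncut < cutoff
  split_ids <- cuts$node[sel]
  if (!length(split_ids)) {
    return(list(graph = g, split_map = stats::setNames(list(), character())))
  }
  part1 <- stats::setNames(cuts$part1[sel], split_ids)
  part2 <- stats::setNames(cuts$part2[sel], split_ids)
  new_id <- function(a, s) {
    cand <- paste0(a, "_s", s)
    while (cand %in% c(node_ids(g), split_ids)) cand <- paste0(cand, "x")
    cand
  }
  split_map <- lapply(split_ids, function(a) {
    list(new = c(new_id(a, 1), new_id(a, 2)),
         part1 = part1[[a]], part2 = part2[[a]])
  })
  names(split_map) <- split_ids
  e <- g$edges
  u_split <- e$u %in% split_ids
  v_split <- e$v %in% split_ids
  e <- e[!(u_split & v_split), , drop = FALSE]   # both endpoints split
  u_split <- e$u %in% split_ids
  v_split <- e$v %in% split_ids
  reassign <- function(center, other) {
    m <- split_map[[center]]
    if (other %in% m$part1) m$new[1] else m$new[2]
  }
  e$u[u_split] <- mapply(reassign, e$u[u_split], e$v[u_split])
  e$v[v_split] <- mapply(reassign, e$v[v_split], e$u[v_split])
  news <- function(ids) unlist(lapply(split_map[ids], `[[`, "new"))
  u_ids <- c(setdiff(g$u_ids, split_ids), news(intersect(split_ids, g$u_ids)))
  v_ids <- c(setdiff(g$v_ids, split_ids), news(intersect(split_ids, g$v_ids)))
  list(graph = bipartite_graph(e, u_ids, v_ids), split_map = split_map)
}

#' Quantile cutoff over evaluated normalized cuts
#'
#' Unevaluable and low-degree nodes are excluded from the distribution.
#'
#' @param cuts a [evaluate_nodes()] table.
#' @param q lower quantile in `[0, 1]` (linear interpolation).
#' @return the ncut threshold.
#' @export
split_quantile_cutoff <- function(cuts, q) {
  vals <- cuts$ncut[cuts$status == "evaluated"]
  if (!length(vals)) stop("no evaluated nodes")
  if (length(q) != 1 || !is.finite(q) || q < 0 || q > 1) {
    stop("q must be a single value in [0, 1]")
  }
  unname(stats::quantile(vals, probs = q, type = 7))
}

#' Write a node cut table as TSV
#'
#' @param cuts a [evaluate_nodes()] table.
#' @param path output path; partitions are comma-joined id lists.
#' @export
write_cut_table <- function(cuts, path) {
  out <- data.frame(
    node_id = cuts$node, status = cuts$status, ncut = cuts$ncut,
    partition_1 = vapply(cuts$part1, paste, character(1), collapse = ","),
    partition_2 = vapply(cuts$part2, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a split map as JSON
#'
#' @param split_map from [split_nodes()].
#' @param path output JSON path.
#' @export
write_split_map <- function(split_map, path) {
  jsonlite::write_json(split_map, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
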