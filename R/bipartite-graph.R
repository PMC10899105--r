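#' Weighted bipartite adjacency graph
#'
#' The universal substrate of the package: an undirected bipartite graph
#' whose two node sets correspond to the two polony (seed-strand) types,
#' conventionally called beacons (`U`) and targets (`V`).  Each edge carries
#' a positive integer weight: the number of unique event identifiers (UEIs),
#' i.e. sequenced concatemers, observed between the two polonies.
#'
#' @param edges data frame with columns `u`, `v`, `weight`.  One row per
#'   unordered beacon/target pair; weights must be integers >= 1.
#' @param u_ids,v_ids optional character vectors of node ids.  Defaults to
#'   the ids present in `edges`; supply explicitly to keep isolated nodes.
#' @return An object of class `bipartite_graph` with components `edges`
#'   (data frame `u`, `v`, `weight`), `u_ids` and `v_ids` (sorted character
#'   vectors).
#' @examples
#' g <- bipartite_graph(data.frame(u = "b1", v = c("t1", "t2"),
#'                                 weight = c(3L, 1L)))
#' total_weight(g)
#' @export
bipartite_graph <- function(edges, u_ids = NULL, v_ids = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(u = character(), v = character(), weight = integer())
  }
  stopifnot(is.data.frame(edges))
  need <- c("u", "v", "weight")
  if (!all(need %in% names(edges))) {
    stop("`edges` must have columns u, v, weight")
  }
  edges <- data.frame(u = as.character(edges$u), v = as.character(edges$v),
                      weight = edges$weight, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    w <- edges$weight
    if (any(!is.finite(w)) || any(w < 1) || any(w != round(w))) {
      stop("edge weights must be integers >= 1")
    }
    edges$weight <- as.integer(round(w))
  } else {
    edges$weight <- integer()
  }
  u_ids <- sort(unique(c(as.character(u_ids), edges$u)))
  v_ids <- sort(unique(c(as.character(v_ids), edges$v)))
  if (nrow(edges)) {
    pair_code <- (as.numeric(match(edges$u, u_ids)) - 1) * length(v_ids) +
      match(edges$v, v_ids)
    if (anyDuplicated(pair_code)) {
      stop("duplicate edges for the same (u, v) pair")
    }
  }
  if (length(intersect(u_ids, v_ids))) {
    stop("bipartition violated: ids in both U and V: ",
         paste(utils::head(intersect(u_ids, v_ids), 5), collapse = ", "))
  }
  structure(list(edges = edges, u_ids = u_ids, v_ids = v_ids),
            class = "bipartite_graph")
}

#' @exportS3Method base::print
print.bipartite_graph <- function(x, ...) {
  cat(sprintf(
    "bipartite_graph: %d beacon (U) + %d target (V) nodes, %d edges, total weight %d\n",
    length(x$u_ids), length(x$v_ids), nrow(x$edges), total_weight(x)))
  invisible(x)
}

#' Node and weight summaries
#'
#' @param g a [bipartite_graph()].
#' @return `n_nodes()`: integer node count; `n_edges()`: integer edge count;
#'   `total_weight()`: the sum of all edge weights (total UEI count);
#'   `node_ids()`: all node ids; `node_strength()`: named integer vector of
#'   total incident weight ("products") per node, including isolated nodes
#'   at 0; `node_degree()`: named integer vector of distinct-neighbor
#'   counts.
#' @export
n_nodes <- function(g) length(g$u_ids) + length(g$v_ids)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

#' @rdname n_nodes
#' @export
total_weight <- function(g) as.integer(sum(g$edges$weight))

#' @rdname n_nodes
#' @export
node_ids <- function(g) c(g$u_ids, g$v_ids)

#' @rdname n_nodes
#' @export
node_strength <- function(g) {
  ids <- node_ids(g)
  s <- integer(length(ids))
  names(s) <- ids
  if (nrow(g$edges)) {
    tu <- tapply(g$edges$weight, g$edges$u, sum)
    tv <- tapply(g$edges$weight, g$edges$v, sum)
    s[names(tu)] <- as.integer(tu)
    s[names(tv)] <- as.integer(tv)
  }
  s
}

#' @rdname n_nodes
#' @export
node_degree <- function(g) {
  ids <- node_ids(g)
  d <- integer(length(ids))
  names(d) <- ids
  if (nrow(g$edges)) {
    tu <- table(g$edges$u)
    tv <- table(g$edges$v)
    d[names(tu)] <- as.integer(tu)
    d[names(tv)] <- as.integer(tv)
  }
  d
}

#' Sparse adjacency matrix of a bipartite graph
#'
#' Rows are beacons (U), columns targets (V), both in lexicographic id
#' order, so the export is reproducible.
#'
#' @param g a [bipartite_graph()].
#' @return a `dgCMatrix` with `dimnames` set to the node ids.
#' @export
adjacency_matrix <- function(g) {
  i <- match(g$edges$u, g$u_ids)
  j <- match(g$edges$v, g$v_ids)
  Matrix::sparseMatrix(
    i = i, j = j, x = as.numeric(g$edges$weight),
    dims = c(length(g$u_ids), length(g$v_ids)),
    dimnames = list(g$u_ids, g$v_ids))
}

#' Convert to an igraph object
#'
#' @param g a [bipartite_graph()].
#' @return an undirected `igraph` graph with a logical `type` vertex
#'   attribute (`FALSE` for U, `TRUE` for V) and a `weight` edge attribute.
#' @export
as_igraph <- function(g) {
  ids <- node_ids(g)
  ig <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = ids)
  ig <- igraph::set_vertex_attr(
    ig, "type", value = ids %in% g$v_ids)
  if (nrow(g$edges)) {
    ig <- igraph::add_edges(
      ig, rbind(match(g$edges$u, ids), match(g$edges$v, ids)),
      weight = g$edges$weight)
  }
  ig
}

#' Induced subgraph on a node subset
#'
#' @param g a [bipartite_graph()].
#' @param keep character vector of node ids to retain.
#' @return the [bipartite_graph()] induced on `keep` (edges with both
#'   endpoints retained).
#' @export
subgraph_nodes <- function(g, keep) {
  keep <- as.character(keep)
  e <- g$edges[g$edges$u %in% keep & g$edges$v %in% keep, , drop = FALSE]
  bipartite_graph(e, u_ids = intersect(g$u_ids, keep),
                  v_ids = intersect(g$v_ids, keep))
}

#' Iteratively drop nodes with fewer than two products
#'
#' Repeatedly removes every node whose total incident UEI count is below
#' `min_products` until a fixed point is reached.  Mirrors the standard
#' experimental-data cleanup that strips likely uncorrected sequencing
#' errors before reconstruction.  The result is independent of removal
#' order because all sub-threshold nodes are removed simultaneously in
#' each round.
#'
#' @param g a [bipartite_graph()].
#' @param min_products minimum total incident weight to survive a round
#'   (default 2).
#' @return the filtered [bipartite_graph()].
#' @export
iterative_low_product_filter <- function(g, min_products = 2) {
  repeat {
    s <- node_strength(g)
    drop <- names(s)[s < min_products]
    if (!length(drop)) return(g)
    g <- subgraph_nodes(g, setdiff(node_ids(g), drop))
  }
}

#' Largest connected component
#'
#' @param g a [bipartite_graph()].
#' @return a list with `graph` (the induced subgraph on the largest
#'   component; ties broken by the component containing the smallest node
#'   id) and `fraction` (its share of the input's nodes, 0 for an empty
#'   graph).  Reconstructions are conventionally attempted only when
#'   `fraction >= 0.8`.
#' @export
largest_component <- function(g) {
  if (n_nodes(g) == 0) {
    return(list(graph = g, fraction = 0))
  }
  comp <- igraph::components(as_igraph(g))
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # deterministic tie-break: component holding the smallest member id
    firsts <- vapply(best, function(k) {
      min(names(comp$membership)[comp$membership == k])
    }, character(1))
    best <- best[order(firsts)][1]
  }
  keep <- names(comp$membership)[comp$membership == best]
  list(graph = subgraph_nodes(g, keep),
       fraction = length(keep) / n_nodes(g))
}
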