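# Quality and detection metrics: Procrustes disparity (global layout
# quality), k-nearest-neighbor overlap (local quality), best-match split
# overlap for recovered fusions, and true/false positive rates of the
# corrections against the injection ledgers.

layout_common <- function(ref, test, min_n = 3) {
  common <- intersect(rownames(ref), rownames(test))
  if (length(common) < min_n) {
    stop("need at least ", min_n, " common nodes, got ", length(common))
  }
  if (length(common) < nrow(ref) || length(common) < nrow(test)) {
    warning("layouts do not cover the same nodes; using the ",
            length(common), " common ones")
  }
  common
}

#' Procrustes disparity between two layouts
#'
#' Standardized Procrustes residual: both point sets are centered and
#' scaled to unit Frobenius norm, then optimally aligned by an orthogonal
#' transform (rotation or reflection — reconstructions from adjacency
#' alone have arbitrary chirality) with optimal scaling; the disparity is
#' the remaining sum of squared differences, `1 - (sum of singular
#' values)^2`, in `[0, 1]`.
#'
#' @param ref,test layout matrices with node ids as rownames.
#' @return the disparity (0 = identical up to similarity transform).
#' @export
procrustes_disparity <- function(ref, test) {
  common <- layout_common(ref, test)
  std <- function(M) {
    M <- scale(M, center = TRUE, scale = FALSE)
    M / norm(M, "F")
  }
  X <- std(ref[common, , drop = FALSE])
  Y <- std(test[common, , drop = FALSE])
  s <- sum(svd(crossprod(X, Y))$d)
  max(0, 1 - s^2)
}

#' Mean k-nearest-neighbor overlap between two layouts
#'
#' For each node, the fraction of its `k` nearest neighbors (Euclidean,
#' self excluded, distance ties broken by node id) that coincide between
#' the two layouts, averaged over nodes.
#'
#' @param ref,test layout matrices with node ids as rownames.
#' @param k neighborhood size (default 15); must satisfy
#'   `0 < k < number of common nodes`.
#' @return mean overlap in `[0, 1]`.
#' @export
knn_overlap <- function(ref, test, k = 15) {
  if (length(k) != 1 || k <= 0) stop("k must be a positive integer")
  common <- layout_common(ref, test, min_n = 2)
  if (k >= length(common)) {
    stop("k (", k, ") must be smaller than the number of common nodes (",
         length(common), ")")
  }
  knn_sets <- function(M) {
    D <- as.matrix(stats::dist(M[common, , drop = FALSE]))
    diag(D) <- Inf
    apply_order <- function(i) common[order(D[i, ], common)[seq_len(k)]]
    lapply(seq_along(common), apply_order)
  }
  a <- knn_sets(ref)
  b <- knn_sets(test)
  mean(mapply(function(x, y) length(intersect(x, y)), a, b)) / k
}

#' Best-match overlap between recovered and true partitions
#'
#' Each recovered part of a split node is matched to whichever of the two
#' original neighbor sets contains the larger fraction of it; the score
#' is the mean of the two best contained fractions (1 = perfect
#' recovery, label swaps allowed).  `method = "jaccard"` instead scores
#' each part by its best Jaccard index against the true sets.
#'
#' @param parts list of two nonempty character vectors: the recovered
#'   neighbor partitions of a split node.
#' @param truth list of two character vectors: the neighbor sets of the
#'   two original polonies.
#' @param method `"contained"` (default) or `"jaccard"`.
#' @return the overlap score in `[0, 1]`.
#' @export
split_overlap <- function(parts, truth, method = c("contained", "jaccard")) {
  method <- match.arg(method)
  stopifnot(length(parts) == 2, length(truth) == 2)
  if (!length(parts[[1]]) || !length(parts[[2]])) {
    stop("recovered parts must be nonempty")
  }
  score <- function(p) {
    max(vapply(truth, function(tset) {
      inter <- length(intersect(p, tset))
      if (method == "contained") inter / length(p)
      else inter / length(union(p, tset))
    }, numeric(1)))
  }
  mean(vapply(parts, score, numeric(1)))
}

#' Detection rates of corrections against the injection ledger
#'
#' Edge metrics: a removed edge is a true positive if it is a purely
#' spurious edge (a ledgered crosslink pair absent from the original
#' graph) and a false positive if it is an original edge; fractions are
#' normalized by the spurious-edge and original-edge counts.  Node
#' metrics: a split node is a true positive if ledgered as a fusion,
#' false positive otherwise; nodes the cut table marks unevaluable or
#' under-connected are excluded from both denominators and reported
#' separately.
#'
#' @param original_graph the pre-injection [bipartite_graph()].
#' @param ledger the error ledger from the injectors.
#' @param removed_edges data frame `u`, `v` of removed edges (from
#'   [filter_edges()]), or NULL.
#' @param split_map from [split_nodes()], or NULL.
#' @param cuts the [evaluate_nodes()] table used for splitting, or NULL.
#' @return a `detection_report` list with edge/node tp/fp fractions and
#'   the underlying counts.
#' @export
detection_rates <- function(original_graph, ledger, removed_edges = NULL,
                            split_map = NULL, cuts = NULL) {
  rep <- list()
  orig_key <- paste0(original_graph$edges$u, "\r", original_graph$edges$v)
  if (!is.null(removed_edges)) {
    known <- c(node_ids(original_graph), ledger$fusions$fused_id)
    orphan <- setdiff(c(removed_edges$u, removed_edges$v), known)
    if (length(orphan)) {
      stop("removed edges reference unknown node(s): ",
           paste(utils::head(orphan, 5), collapse = ", "))
    }
    cl_key <- unique(paste0(ledger$crosslinks$u, "\r", ledger$crosslinks$v))
    spurious <- setdiff(cl_key, orig_key)
    rm_key <- paste0(removed_edges$u, "\r", removed_edges$v)
    rep$edge_tp <- sum(rm_key %in% spurious)
    rep$edge_fp <- sum(rm_key %in% orig_key)
    rep$n_spurious_edges <- length(spurious)
    rep$n_original_edges <- length(orig_key)
    rep$edge_tp_fraction <-
      if (length(spurious)) rep$edge_tp / length(spurious) else NA_real_
    rep$edge_fp_fraction <- rep$edge_fp / length(orig_key)
  }
  if (!is.null(split_map)) {
    fused <- ledger$fusions$fused_id
    split_ids <- names(split_map)
    if (!is.null(cuts)) {
      evaluated <- cuts$node[cuts$status == "evaluated"]
      rep$n_unevaluable <- sum(cuts$status != "evaluated")
    } else {
      evaluated <- unique(c(split_ids, fused))
    }
    ev_fused <- intersect(evaluated, fused)
    ev_normal <- setdiff(evaluated, fused)
    rep$node_tp <- length(intersect(split_ids, ev_fused))
    rep$node_fp <- length(intersect(split_ids, ev_normal))
    rep$n_fused_evaluated <- length(ev_fused)
    rep$n_normal_evaluated <- length(ev_normal)
    rep$node_tp_fraction <-
      if (length(ev_fused)) rep$node_tp / length(ev_fused) else NA_real_
    rep$node_fp_fraction <-
      if (length(ev_normal)) rep$node_fp / length(ev_normal) else NA_real_
  }
  structure(rep, class = "detection_report")
}

#' Ledgered neighbor sets of a fusion's constituents
#'
#' Ground truth for split evaluation: the neighbor id sets of the two
#' original polonies in the pre-fusion graph.  By default the sets are
#' the literal pre-fusion ids, so a neighbor that was itself fused later
#' counts as a mismatch against the recovered partitions — the overlap
#' then measures how much of the original neighborhood is recovered
#' under its original identity.  With `map_fusions = TRUE` the ids are
#' mapped through the fusion ledger first, scoring only the partition
#' assignment itself.
#'
#' @param original_graph the graph before fusion injection.
#' @param ledger the fusion ledger.
#' @param fused_id one fused node id from the ledger.
#' @param map_fusions map neighbor ids through other fusions
#'   (default FALSE).
#' @return list of two character vectors (`S_b`, `S_c`).
#' @export
fusion_truth_sets <- function(original_graph, ledger, fused_id,
                              map_fusions = FALSE) {
  row <- ledger$fusions[ledger$fusions$fused_id == fused_id, , drop = FALSE]
  if (!nrow(row)) stop("fused id ", fused_id, " not in ledger")
  remap <- stats::setNames(node_ids(original_graph),
                           node_ids(original_graph))
  if (map_fusions) {
    remap[ledger$fusions$original_1] <- ledger$fusions$fused_id
    remap[ledger$fusions$original_2] <- ledger$fusions$fused_id
  }
  nbrs <- function(a) {
    e <- original_graph$edges
    unique(unname(remap[c(e$v[e$u == a], e$u[e$v == a])]))
  }
  list(nbrs(row$original_1), nbrs(row$original_2))
}

#' Layout quality report
#'
#' @param ref,test layout matrices (e.g. ground truth and
#'   reconstruction).
#' @param k neighborhood size for [knn_overlap()].
#' @param component_fraction optionally recorded largest-component share.
#' @return a list with `procrustes_disparity`, `knn_overlap`,
#'   `n_nodes_evaluated`, `component_fraction`.
#' @export
quality_report <- function(ref, test, k = 15, component_fraction = NA_real_) {
  common <- intersect(rownames(ref), rownames(test))
  list(procrustes_disparity = procrustes_disparity(ref, test),
       knn_overlap = knn_overlap(ref, test, k = k),
       n_nodes_evaluated = length(common),
       component_fraction = component_fraction)
}

#' Write a report as JSON
#'
#' @param report any metric report (list).
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
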