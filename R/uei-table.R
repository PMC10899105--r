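#' Read a UEI table from TSV
#'
#' A UEI table holds one row per sequenced concatemer: the beacon polony
#' it joins, the target polony, the unique event identifier (UEI) barcode,
#' and the number of reads supporting it.  This is the experimental input
#' before aggregation into an adjacency graph.
#'
#' @param path path to a tab-separated file with header columns
#'   `beacon_id`, `target_id`, `uei_id`, `read_count`.
#' @return a data frame of class `uei_table` with those four columns
#'   (`read_count` integer).
#' @export
read_uei_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("beacon_id", "target_id", "uei_id", "read_count")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("UEI table ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  tab <- tab[need]
  rc <- suppressWarnings(as.numeric(tab$read_count))
  bad <- which(!is.finite(rc) | rc < 1 | rc != round(rc))
  if (length(bad)) {
    # +1 for the header line so the message points at the file line
    stop("invalid read_count at file line(s): ",
         paste(utils::head(bad + 1L, 10), collapse = ", "))
  }
  tab$read_count <- as.integer(rc)
  uei_table(tab)
}

#' Construct / validate a UEI table
#'
#' @param records data frame with columns `beacon_id`, `target_id`,
#'   `uei_id`, `read_count`.
#' @return the validated `uei_table`.
#' @export
uei_table <- function(records) {
  need <- c("beacon_id", "target_id", "uei_id", "read_count")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  records <- records[need]
  for (col in need[1:3]) records[[col]] <- as.character(records[[col]])
  rc <- records$read_count
  if (length(rc) && (any(!is.finite(rc)) || any(rc < 1) || any(rc != round(rc)))) {
    stop("read_count must be an integer >= 1")
  }
  records$read_count <- as.integer(rc)
  if (anyDuplicated(records$uei_id)) {
    stop("duplicate uei_id: ",
         paste(utils::head(unique(records$uei_id[duplicated(records$uei_id)]), 5),
               collapse = ", "))
  }
  class(records) <- c("uei_table", "data.frame")
  records
}

#' Write a UEI table to TSV
#'
#' @param tab a [uei_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_uei_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Aggregate a UEI table into a bipartite graph
#'
#' The edge weight of a beacon/target pair is the number of distinct UEIs
#' observed for it.  Read counts support per-UEI filtering
#' ([read_count_filter()]) but are never summed into edge weights.
#'
#' @param tab a [uei_table()].
#' @return a [bipartite_graph()].
#' @export
aggregate_ueis <- function(tab) {
  both <- intersect(unique(tab$beacon_id), unique(tab$target_id))
  if (length(both)) {
    stop("id(s) appear as both beacon and target: ",
         paste(utils::head(both, 5), collapse = ", "))
  }
  if (!nrow(tab)) return(bipartite_graph(NULL))
  agg <- stats::aggregate(list(weight = tab$uei_id),
                          by = list(u = tab$beacon_id, v = tab$target_id),
                          FUN = length)
  bipartite_graph(agg)
}

#' Filter UEIs by read support
#'
#' @param tab a [uei_table()].
#' @param min_reads keep records with `read_count >= min_reads`
#'   (integer >= 1).
#' @return the filtered [uei_table()].
#' @export
read_count_filter <- function(tab, min_reads) {
  stopifnot(length(min_reads) == 1, is.finite(min_reads), min_reads >= 1)
  uei_table(as.data.frame(tab)[tab$read_count >= min_reads, , drop = FALSE])
}

#' Edge-list and adjacency exports
#'
#' `write_edge_list()`/`read_edge_list()` round-trip the graph as a TSV of
#' `u_id`, `v_id`, `weight`.  `write_adjacency_mtx()` writes the sparse
#' adjacency in Matrix Market format with two sidecar files giving the row
#' (U) and column (V) node orders.  `write_graph_meta()` writes node /
#' edge / UEI counts as JSON.
#'
#' @param g a [bipartite_graph()].
#' @param path output path (for MTX, the `.mtx` path; sidecars get
#'   `.rownames.txt` / `.colnames.txt` suffixes).
#' @return the main output path, invisibly.
#' @export
write_edge_list <- function(g, path) {
  e <- g$edges[order(g$edges$u, g$edges$v), , drop = FALSE]
  names(e) <- c("u_id", "v_id", "weight")
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("u_id", "v_id", "weight")
  if (!all(need %in% names(e))) {
    stop("edge list must have columns u_id, v_id, weight")
  }
  bipartite_graph(data.frame(u = e$u_id, v = e$v_id, weight = e$weight))
}

#' @rdname write_edge_list
#' @export
write_adjacency_mtx <- function(g, path) {
  A <- adjacency_matrix(g)
  Matrix::writeMM(A, path)
  base <- sub("\\.mtx$", "", path)
  writeLines(g$u_ids, paste0(base, ".rownames.txt"))
  writeLines(g$v_ids, paste0(base, ".colnames.txt"))
  invisible(path)
}

#' @rdname write_edge_list
#' @param n_ueis optional UEI count to record (defaults to the total edge
#'   weight, which equals the UEI count after aggregation).
#' @export
write_graph_meta <- function(g, path, n_ueis = total_weight(g)) {
  meta <- list(n_beacons = length(g$u_ids), n_targets = length(g$v_ids),
               n_nodes = n_nodes(g), n_edges = n_edges(g),
               total_weight = total_weight(g), n_ueis = n_ueis)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
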