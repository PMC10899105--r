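# Config-driven orchestration: simulation sweeps (simulate -> inject ->
# correct -> reconstruct -> evaluate) and the experimental-data filter
# chain (aggregate -> read-count or indirect-path filter -> low-product
# filter -> largest component).

#' Simulation experiment configuration
#'
#' @param n_nodes,mask,type_fraction scene parameters
#'   ([place_nodes()]).
#' @param amplitudes,spreads parameter grids ([sim_params()]).
#' @param error_type one of `"none"`, `"crosslink"`, `"fusion"`,
#'   `"bias"`.
#' @param error_fractions grid of injected error fractions.
#' @param cutoffs grid of correction quantile cutoffs (0 = no
#'   correction).
#' @param seeds integer seeds; every run is fully determined by
#'   `(config, seed)`.
#' @param refine_iterations,knn_k reconstruction / evaluation settings.
#' @param min_component_fraction reconstruct only when the largest
#'   component holds at least this node share (default 0.8).
#' @param bias_factor reactivity multiplier for `error_type = "bias"`.
#' @param use_true_params pass the simulation's true amplitude/spread to
#'   the reconstructor instead of profiling them from the (possibly
#'   corrupted) graph.  Default FALSE: an experimenter analyzing real
#'   data has no access to pre-error parameters, so profiling is the
#'   realistic policy.
#' @param out_dir optional output directory for per-run TSV/JSON
#'   artifacts.
#' @return a validated `experiment_config` list.
#' @export
experiment_config <- function(n_nodes = 4000, mask = c(200, 450),
                              type_fraction = 0.5,
                              amplitudes = c(1, 10, 100),
                              spreads = c(20, 50, 100),
                              error_type = "none", error_fractions = 0,
                              cutoffs = 0, seeds = 1,
                              refine_iterations = 100, knn_k = 15,
                              min_component_fraction = 0.8,
                              bias_factor = 2, use_true_params = FALSE,
                              out_dir = NULL) {
  error_type <- match.arg(error_type, c("none", "crosslink", "fusion",
                                        "bias"))
  cfg <- list(n_nodes = n_nodes, mask = mask, type_fraction = type_fraction,
              amplitudes = amplitudes, spreads = spreads,
              error_type = error_type, error_fractions = error_fractions,
              cutoffs = cutoffs, seeds = seeds,
              refine_iterations = refine_iterations, knn_k = knn_k,
              min_component_fraction = min_component_fraction,
              bias_factor = bias_factor, use_true_params = use_true_params,
              out_dir = out_dir)
  grids <- c("amplitudes", "spreads", "error_fractions", "cutoffs", "seeds")
  for (gname in grids) {
    if (!length(cfg[[gname]])) stop("empty grid: ", gname)
  }
  structure(cfg, class = "experiment_config")
}

#' Read an experiment configuration from JSON or YAML
#'
#' @param path config file path (`.json`, `.yaml` or `.yml`); fields as
#'   in [experiment_config()].
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(experiment_config, vals)
}

config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 1000000007
  sprintf("cfg%09.0f", h)
}

run_seed <- function(seed, idx) {
  as.integer(((seed %% 1000003) * 2039 + idx * 7919) %% 2147483647)
}

#' Run a simulation sweep with error injection and correction
#'
#' For every cell of the `(amplitude, spread, error_fraction, cutoff,
#' seed)` grid: simulate the adjacency graph, inject the configured
#' error, optionally correct it at the quantile cutoff (indirect-path
#' edge filtering for crosslinks, normalized-cut splitting for fusions),
#' check the 80% connectivity rule, reconstruct, and score against the
#' ground-truth scene.  Simulated graphs are not passed through the
#' iterative low-product filter (that cleanup targets experimental
#' sequencing errors).  Nodes without a ground-truth position (fused or
#' split ones) are excluded from the layout metrics.
#'
#' @param cfg an [experiment_config()].
#' @param verbose print per-stage counts (default FALSE).
#' @return a data frame with one row per grid cell: parameters, stage
#'   counts, `component_fraction`, `skipped`/`skip_reason`, disparity and
#'   k-NN overlap, detection tp/fp fractions, and the config hash.
#' @export
run_simulation_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(cfg$out_dir) ||
        file.access(cfg$out_dir, 2) != 0) {
      stop("output directory not writable: ", cfg$out_dir)
    }
  }
  hash <- config_hash(cfg)
  grid <- expand.grid(seed = cfg$seeds, amplitude = cfg$amplitudes,
                      spread = cfg$spreads,
                      error_fraction = cfg$error_fractions,
                      cutoff = cfg$cutoffs,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    cell <- grid[r, ]
    note <- function(...) if (verbose) message(sprintf(...))
    sd0 <- run_seed(cell$seed, r)
    scene <- place_nodes(cfg$n_nodes, cfg$mask, cfg$type_fraction,
                         seed = sd0)
    params <- sim_params(cell$amplitude, cell$spread)
    g0 <- simulate_graph(scene, params, seed = sd0 + 1L)
    note("cell %d: simulated %d nodes, %d edges, weight %d", r,
         n_nodes(g0), n_edges(g0), total_weight(g0))
    ledger <- empty_ledger()
    g <- g0
    if (cell$error_fraction > 0) {
      inj <- switch(cfg$error_type,
        none = list(graph = g0, ledger = ledger),
        crosslink = inject_spurious_crosslinks(g0, cell$error_fraction,
                                               seed = sd0 + 2L),
        fusion = inject_fused_nodes(g0, cell$error_fraction,
                                    seed = sd0 + 2L),
        bias = inject_reactivity_bias(scene, params, cell$error_fraction,
                                      bias_factor = cfg$bias_factor,
                                      seed = sd0))
      g <- inj$graph
      ledger <- inj$ledger
    }
    removed <- NULL
    split_map <- NULL
    cuts <- NULL
    if (cell$cutoff > 0 && cfg$error_type %in% c("crosslink", "fusion")) {
      if (cfg$error_type == "crosslink") {
        scores <- indirect_path_values(g)
        thr <- quantile_cutoff(scores, cell$cutoff)
        # edges strictly below the quantile threshold are removed; with
        # heavily tied integer scores this removes at most the intended
        # share of edges
        fe <- filter_edges(g, scores, thr, mode = "below")
        g <- fe$graph
        removed <- fe$removed
        note("cell %d: removed %d edges at w_i3 <= %.3g", r,
             nrow(removed), thr)
      } else {
        cuts <- evaluate_nodes(g)
        thr <- split_quantile_cutoff(cuts, cell$cutoff)
        sp <- split_nodes(g, cuts, thr)
        g <- sp$graph
        split_map <- sp$split_map
        note("cell %d: split %d nodes at ncut < %.3g", r,
             length(split_map), thr)
      }
    }
    lc <- largest_component(g)
    row <- data.frame(
      config = hash, seed = cell$seed, amplitude = cell$amplitude,
      spread = cell$spread, error_type = cfg$error_type,
      error_fraction = cell$error_fraction, cutoff = cell$cutoff,
      n_nodes = n_nodes(g), n_edges = n_edges(g),
      total_weight = total_weight(g),
      component_fraction = lc$fraction,
      skipped = FALSE, skip_reason = "",
      procrustes_disparity = NA_real_, knn_overlap = NA_real_,
      edge_tp_fraction = NA_real_, edge_fp_fraction = NA_real_,
      node_tp_fraction = NA_real_, node_fp_fraction = NA_real_,
      stringsAsFactors = FALSE)
    if (!is.null(removed) || !is.null(split_map)) {
      det <- detection_rates(g0, ledger, removed_edges = removed,
                             split_map = split_map, cuts = cuts)
      for (f in c("edge_tp_fraction", "edge_fp_fraction",
                  "node_tp_fraction", "node_fp_fraction")) {
        if (!is.null(det[[f]])) row[[f]] <- det[[f]]
      }
    }
    if (lc$fraction < cfg$min_component_fraction) {
      row$skipped <- TRUE
      row$skip_reason <- sprintf("largest component %.2f < %.2f",
                                 lc$fraction, cfg$min_component_fraction)
      note("cell %d: skipped (%s)", r, row$skip_reason)
    } else {
      rec <- reconstruct_layout(
        lc$graph,
        amplitude = if (isTRUE(cfg$use_true_params)) cell$amplitude,
        spread = if (isTRUE(cfg$use_true_params)) cell$spread,
        iterations = cfg$refine_iterations)
      truth <- cbind(x = scene$coords$x, y = scene$coords$y)
      rownames(truth) <- scene$coords$id
      common <- intersect(rownames(rec$layout), rownames(truth))
      row$procrustes_disparity <- suppressWarnings(
        procrustes_disparity(truth[common, , drop = FALSE],
                             rec$layout[common, , drop = FALSE]))
      row$knn_overlap <- suppressWarnings(
        knn_overlap(truth[common, , drop = FALSE],
                    rec$layout[common, , drop = FALSE], k = cfg$knn_k))
    }
    if (!is.null(cfg$out_dir)) {
      stem <- file.path(cfg$out_dir, sprintf("%s_run%03d", hash, r))
      utils::write.table(
        format(row, digits = 10), paste0(stem, ".tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    }
    rows[[r]] <- row
  }
  out <- do.call(rbind, rows)
  if (!is.null(cfg$out_dir)) {
    utils::write.table(format(out, digits = 10),
                       file.path(cfg$out_dir, paste0(hash, "_results.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Experimental-data filter chain
#'
#' Aggregate a UEI table into a bipartite graph, apply either a read
#' count filter (drop UEIs with fewer than `threshold` reads) or an
#' indirect-path filter (drop edges with `w_i3 < threshold`), then the
#' iterative fewer-than-two-products node filter, then keep the largest
#' connected component; report the remaining UEIs, edges and beacon /
#' target polonies at every stage.
#'
#' @param uei a [uei_table()] or a path to a UEI TSV.
#' @param filter `"read_count"` or `"indirect_path"` (or `"none"`).
#' @param threshold filter threshold (reads for `read_count`, integer
#'   w_i3 cutoff for `indirect_path`).
#' @param out_dir optional directory for the summary JSON and filtered
#'   edge list.
#' @param reconstruct also reconstruct a layout from the final graph
#'   (default FALSE).
#' @return a list with `graph` (final), `stages` (data frame of
#'   per-stage counts), `component_fraction`, and optionally `layout`.
#' @export
run_experimental_chain <- function(uei, filter = c("read_count",
                                                   "indirect_path", "none"),
                                   threshold = 1, out_dir = NULL,
                                   reconstruct = FALSE) {
  filter <- match.arg(filter)
  tab <- if (is.character(uei)) read_uei_table(uei) else uei
  stages <- list()
  stage <- function(name, g, ueis = total_weight(g)) {
    data.frame(stage = name, n_ueis = ueis, n_edges = n_edges(g),
               n_beacons = length(g$u_ids), n_targets = length(g$v_ids),
               stringsAsFactors = FALSE)
  }
  if (filter == "read_count" && threshold > 1) {
    tab <- read_count_filter(tab, threshold)
  }
  g <- aggregate_ueis(tab)
  stages$input <- stage("aggregated", g)
  if (filter == "indirect_path") {
    scores <- indirect_path_values(g)
    g <- filter_edges(g, scores, threshold, mode = "below")$graph
  }
  stages$filtered <- stage(paste0(filter, "_filtered"), g)
  g <- iterative_low_product_filter(g)
  stages$low_product <- stage("low_product_filtered", g)
  lc <- largest_component(g)
  g <- lc$graph
  stages$component <- stage("largest_component", g)
  out <- list(graph = g, stages = do.call(rbind, unname(stages)),
              component_fraction = lc$fraction)
  if (reconstruct && n_nodes(g) >= 4) {
    out$layout <- reconstruct_layout(g)$layout
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_edge_list(g, file.path(out_dir, "filtered_edges.tsv"))
    write_report(list(filter = filter, threshold = threshold,
                      component_fraction = lc$fraction,
                      stages = out$stages),
                 file.path(out_dir, "chain_summary.json"))
  }
  out
}
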