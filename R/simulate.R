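# Diffusion-based adjacency simulator: uniform polonies of two types in a
# 2D mask, Poisson edge weights with a Gaussian distance kernel, and
# injectors for the three artifact classes (spurious crosslinks, fused
# nodes, reactivity bias), each with a full ground-truth ledger.

local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Simulation parameters for the Gaussian Poisson adjacency model
#'
#' The expected number of concatemers (UEIs) between two polonies at
#' distance r is `amplitude * exp(-r^2 / spread^2)`; the observed edge
#' weight is a Poisson draw with that mean.  The spread plays the role of
#' the characteristic diffusion length `L_diff = sqrt(8 d D t)` of the
#' underlying hydrogel diffusion model, so it can alternatively be given
#' through the physical parameters `D` (diffusion constant), `t` (time
#' since polony creation) and `d` (dimensionality).
#'
#' @param amplitude positive real; sets edge weights at distance 0
#'   (reactivity x sequencing depth).
#' @param spread positive real, in the scene's pixel units.
#' @param D,t,d optional physical parameters; when supplied, `spread`
#'   defaults to `sqrt(8 * d * D * t)`, and if `spread` is also given the
#'   two must agree to relative tolerance 1e-9.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(amplitude, spread = NULL, D = NULL, t = NULL, d = NULL) {
  stopifnot(length(amplitude) == 1, is.finite(amplitude), amplitude >= 0)
  phys <- !is.null(D) || !is.null(t) || !is.null(d)
  if (phys) {
    if (is.null(D) || is.null(t) || is.null(d)) {
      stop("supply all of D, t, d or none")
    }
    l_diff <- sqrt(8 * d * D * t)
    if (is.null(spread)) {
      spread <- l_diff
    } else if (abs(spread - l_diff) > 1e-9 * max(spread, l_diff)) {
      stop(sprintf("spread %.6g inconsistent with sqrt(8dDt) = %.6g",
                   spread, l_diff))
    }
  }
  if (is.null(spread)) stop("supply `spread` or the physical parameters")
  stopifnot(is.finite(spread), spread > 0)
  structure(list(amplitude = amplitude, spread = spread,
                 D = D, t = t, d = d),
            class = "sim_params")
}

#' Place polonies uniformly in a 2D mask
#'
#' @param n_nodes number of polonies (default 4000).
#' @param mask either a numeric length-2 vector `c(width, height)` for a
#'   full rectangle (default `c(200, 450)` pixels) or a logical matrix
#'   treated as a pixel grid (TRUE = inside); rows index x, columns y.
#' @param type_fraction probability that a node is a beacon (type U),
#'   independent of position.
#' @param seed integer seed; the scene is reproducible given
#'   `(n_nodes, mask, type_fraction, seed)`.
#' @return an object of class `sim_scene`: a list with `coords` (data
#'   frame `id`, `type` in {"U","V"}, `x`, `y`), `mask`, and `seed`.
#' @export
place_nodes <- function(n_nodes = 4000, mask = c(200, 450),
                        type_fraction = 0.5, seed = 1) {
  stopifnot(n_nodes >= 1, type_fraction > 0, type_fraction < 1)
  local_seed(seed, {
    if (is.matrix(mask)) {
      inside <- which(mask)
      if (!length(inside)) stop("mask has zero area")
      cells <- sample(inside, n_nodes, replace = TRUE)
      # uniform position within each chosen pixel
      x <- (row(mask)[cells] - 1) + stats::runif(n_nodes)
      y <- (col(mask)[cells] - 1) + stats::runif(n_nodes)
    } else {
      stopifnot(length(mask) == 2, all(mask > 0))
      x <- stats::runif(n_nodes, 0, mask[1])
      y <- stats::runif(n_nodes, 0, mask[2])
    }
    type <- ifelse(stats::runif(n_nodes) < type_fraction, "U", "V")
    # degenerate draws (all one type) violate the two-type invariant
    if (length(unique(type)) < 2) {
      type[1] <- setdiff(c("U", "V"), type[1])
    }
    ids <- sprintf("n%0*d", nchar(n_nodes), seq_len(n_nodes))
    structure(list(
      coords = data.frame(id = ids, type = type, x = x, y = y,
                          stringsAsFactors = FALSE),
      mask = mask, seed = seed), class = "sim_scene")
  })
}

#' Write / read a scene as TSV
#'
#' @param scene a [place_nodes()] scene.
#' @param path TSV path (columns `node_id`, `type`, `x`, `y`).
#' @export
write_scene <- function(scene, path) {
  out <- scene$coords
  names(out)[1] <- "node_id"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("node_id", "type", "x", "y") %in% names(tab)))
  structure(list(coords = data.frame(id = tab$node_id, type = tab$type,
                                     x = tab$x, y = tab$y,
                                     stringsAsFactors = FALSE),
                 mask = NULL, seed = NA_integer_), class = "sim_scene")
}

# pairwise squared distances between two coordinate matrices
pair_dist2 <- function(P, Q) {
  outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * tcrossprod(P, Q)
}

# Poisson means of the adjacency model for a scene, optionally with
# per-node reactivity multipliers; returns list(u_ids, v_ids, mu)
model_means <- function(scene, params, node_factor = NULL) {
  co <- scene$coords
  iu <- which(co$type == "U")
  iv <- which(co$type == "V")
  mu <- params$amplitude *
    exp(-pmax(pair_dist2(as.matrix(co[iu, c("x", "y")]),
                         as.matrix(co[iv, c("x", "y")])), 0) /
          params$spread^2)
  if (!is.null(node_factor)) {
    fu <- node_factor[co$id[iu]]
    fv <- node_factor[co$id[iv]]
    fu[is.na(fu)] <- 1
    fv[is.na(fv)] <- 1
    mu <- mu * outer(fu, fv)
  }
  list(u_ids = co$id[iu], v_ids = co$id[iv], mu = mu)
}

poisson_graph <- function(mm) {
  w <- stats::rpois(length(mm$mu), as.vector(mm$mu))
  keep <- which(w > 0)
  nu <- length(mm$u_ids)
  edges <- data.frame(
    u = mm$u_ids[((keep - 1) %% nu) + 1],
    v = mm$v_ids[((keep - 1) %/% nu) + 1],
    weight = w[keep], stringsAsFactors = FALSE)
  bipartite_graph(edges, u_ids = mm$u_ids, v_ids = mm$v_ids)
}

#' Simulate an adjacency graph from a scene
#'
#' For every beacon/target pair the edge weight is drawn from a Poisson
#' distribution with mean `amplitude * exp(-dist^2 / spread^2)`; draws of
#' zero produce no edge, and same-type pairs are never connected.  All
#' pairs are enumerated exactly.
#'
#' @param scene a [place_nodes()] scene.
#' @param params a [sim_params()] object.
#' @param seed integer seed for the Poisson draws.
#' @return a [bipartite_graph()] whose node set is the whole scene
#'   (isolated nodes retained).
#' @export
simulate_graph <- function(scene, params, seed = 1) {
  mm <- model_means(scene, params)
  local_seed(seed, poisson_graph(mm))
}

empty_ledger <- function() {
  structure(list(
    crosslinks = data.frame(u = character(), v = character(),
                            added_weight = integer(),
                            stringsAsFactors = FALSE),
    fusions = data.frame(fused_id = character(), original_1 = character(),
                         original_2 = character(), stringsAsFactors = FALSE),
    biased = data.frame(id = character(), bias_factor = numeric(),
                        stringsAsFactors = FALSE)),
    class = "error_ledger")
}

#' Write an error ledger as JSON
#'
#' @param ledger an error ledger as returned by the injectors.
#' @param path output JSON path.
#' @export
write_ledger <- function(ledger, path) {
  jsonlite::write_json(unclass(ledger), path, dataframe = "columns",
                       pretty = TRUE)
  invisible(path)
}

#' Inject spurious crosslinks
#'
#' Adds `round(fraction * total_weight(g))` unit-weight spurious events.
#' Each event picks one beacon and one target uniformly at random,
#' independent of position — the signature of post-lysis chimeric PCR —
#' and increments that pair's weight by one (creating the edge if absent).
#' Every event is recorded in the ledger even when it lands on an
#' existing edge.
#'
#' @param g a [bipartite_graph()].
#' @param fraction spurious weight as a fraction of the total edge weight,
#'   in `[0, 1]`.
#' @param seed integer seed.
#' @return `list(graph, ledger)`; the ledger's `crosslinks` component has
#'   one row per event.
#' @export
inject_spurious_crosslinks <- function(g, fraction, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (n_nodes(g) == 0 || total_weight(g) == 0) {
    stop("cannot inject crosslinks into an empty graph")
  }
  n_events <- round(fraction * total_weight(g))
  ledger <- empty_ledger()
  if (n_events == 0) return(list(graph = g, ledger = ledger))
  local_seed(seed, {
    us <- sample(g$u_ids, n_events, replace = TRUE)
    vs <- sample(g$v_ids, n_events, replace = TRUE)
    ledger$crosslinks <- data.frame(u = us, v = vs,
                                    added_weight = rep(1L, n_events),
                                    stringsAsFactors = FALSE)
    add <- stats::aggregate(list(n = rep(1L, n_events)),
                            by = list(u = us, v = vs), FUN = sum)
    e <- g$edges
    key <- paste0(e$u, "\r", e$v)
    akey <- paste0(add$u, "\r", add$v)
    hit <- match(akey, key)
    e$weight[hit[!is.na(hit)]] <-
      e$weight[hit[!is.na(hit)]] + add$n[!is.na(hit)]
    new <- add[is.na(hit), , drop = FALSE]
    if (nrow(new)) {
      e <- rbind(e, data.frame(u = new$u, v = new$v, weight = new$n,
                               stringsAsFactors = FALSE))
    }
    list(graph = bipartite_graph(e, g$u_ids, g$v_ids), ledger = ledger)
  })
}

#' Inject fused nodes
#'
#' Performs `round(fraction * n_nodes(g))` fusion events.  Each event
#' picks two distinct same-type nodes, uniformly over all same-type pairs
#' of nodes not already involved in a fusion, and replaces them by a
#' single node whose weight to each neighbor is the sum of the two
#' originals' weights — the graph signature of two polonies sharing a
#' barcode.
#'
#' @param g a [bipartite_graph()].
#' @param fraction fusion events as a fraction of the node count, in
#'   `[0, 1]`.
#' @param seed integer seed.
#' @return `list(graph, ledger)`; `ledger$fusions` has one row per event
#'   with the new node id and the two originals.
#' @export
inject_fused_nodes <- function(g, fraction, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  n_events <- round(fraction * n_nodes(g))
  ledger <- empty_ledger()
  if (n_events == 0) return(list(graph = g, ledger = ledger))
  local_seed(seed, {
    elig <- list(U = g$u_ids, V = g$v_ids)
    fus <- vector("list", n_events)
    for (k in seq_len(n_events)) {
      npair <- vapply(elig, function(z) choose(length(z), 2), numeric(1))
      if (sum(npair) == 0) {
        stop(sprintf(
          "not enough unfused same-type nodes for %d fusion events (stopped at %d)",
          n_events, k - 1))
      }
      ty <- sample(names(elig), 1, prob = npair)
      pair <- sort(sample(elig[[ty]], 2))
      elig[[ty]] <- setdiff(elig[[ty]], pair)
      fus[[k]] <- data.frame(fused_id = sprintf("fused_%03d", k),
                             original_1 = pair[1], original_2 = pair[2],
                             stringsAsFactors = FALSE)
    }
    ledger$fusions <- do.call(rbind, fus)
    e <- g$edges
    remap <- stats::setNames(node_ids(g), node_ids(g))
    remap[ledger$fusions$original_1] <- ledger$fusions$fused_id
    remap[ledger$fusions$original_2] <- ledger$fusions$fused_id
    e$u <- unname(remap[e$u])
    e$v <- unname(remap[e$v])
    u_ids <- unique(unname(remap[g$u_ids]))
    v_ids <- unique(unname(remap[g$v_ids]))
    if (nrow(e)) {
      # sparse-matrix construction sums duplicate pairs in C
      Aagg <- Matrix::sparseMatrix(i = match(e$u, u_ids),
                                   j = match(e$v, v_ids),
                                   x = as.numeric(e$weight),
                                   dims = c(length(u_ids), length(v_ids)))
      s <- Matrix::summary(Aagg)
      e <- data.frame(u = u_ids[s$i], v = v_ids[s$j],
                      weight = as.integer(s$x), stringsAsFactors = FALSE)
    }
    list(graph = bipartite_graph(e, u_ids, v_ids), ledger = ledger)
  })
}

#' Simulate with per-node reactivity bias
#'
#' Re-runs the adjacency simulation with the Poisson mean of every pair
#' multiplied by `bias_factor` once per biased endpoint (so a pair with
#' both endpoints biased gets `bias_factor^2`).  Emulates polonies with
#' increased inherent reactivity.
#'
#' @param scene a [place_nodes()] scene.
#' @param params a [sim_params()] object.
#' @param node_fraction fraction of nodes biased, in `[0, 1]`.
#' @param bias_factor multiplicative reactivity factor (> 0, default 2).
#' @param seed integer seed (selection and Poisson draws; with
#'   `node_fraction = 0` the graph equals `simulate_graph(scene, params,
#'   seed)` exactly).
#' @return `list(graph, ledger)`; `ledger$biased` lists the biased nodes.
#' @export
inject_reactivity_bias <- function(scene, params, node_fraction,
                                   bias_factor = 2, seed = 1) {
  stopifnot(bias_factor > 0, node_fraction >= 0, node_fraction <= 1)
  ledger <- empty_ledger()
  ids <- scene$coords$id
  n_biased <- round(node_fraction * length(ids))
  # selection uses a derived stream so the zero-fraction case reproduces
  # simulate_graph(seed) draw-for-draw
  picked <- if (n_biased > 0) {
    local_seed(seed + 1000003L, sample(ids, n_biased))
  } else character()
  ledger$biased <- data.frame(id = picked,
                              bias_factor = rep(bias_factor, length(picked)),
                              stringsAsFactors = FALSE)
  nf <- stats::setNames(rep(bias_factor, length(picked)), picked)
  mm <- model_means(scene, params, node_factor = if (length(nf)) nf else NULL)
  list(graph = local_seed(seed, poisson_graph(mm)), ledger = ledger)
}
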