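#' Inter-ROI functional connectivity matrix
#'
#' Connectivity between two ROIs is the absolute Pearson correlation of their
#' representative time series (the sign of a correlation is not informative
#' for edge strength here), with a zeroed diagonal.
#'
#' @param roi_series An `n_rois x n_timepoints` matrix, one ROI per row.
#' @return An object of class `"roi_graph"` holding the symmetric weight
#'   matrix with entries in `[0, 1]`; no edges are masked yet (see
#'   [threshold_graph()]).
#' @export
connectivity_matrix <- function(roi_series) {
  roi_series <- as.matrix(roi_series)
  if (nrow(roi_series) < 2) abort("Need at least 2 ROIs.")
  sds <- apply(roi_series, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1]
    nm <- rownames(roi_series)[bad]
    abort(sprintf("ROI %s has a constant series; correlation is undefined.",
                  if (is.null(nm)) as.character(bad) else nm))
  }
  w <- abs(cor(t(roi_series)))
  diag(w) <- 0
  new_roi_graph(w, mask = NULL, density = NULL)
}

new_roi_graph <- function(weights, mask, density) {
  structure(list(
    n_nodes = nrow(weights),
    weights = weights,
    mask = mask,
    density = density
  ), class = "roi_graph")
}

#' @export
print.roi_graph <- function(x, ...) {
  cat(sprintf("ROI connectivity graph: %d nodes", x$n_nodes))
  if (!is.null(x$mask)) {
    cat(sprintf(", %d edges retained (density %.2f)",
                sum(x$mask[upper.tri(x$mask)]), x$density))
  } else {
    cat(" (unthresholded)")
  }
  cat("\n")
  invisible(x)
}

#' Proportional thresholding of a connectivity graph
#'
#' Retains the strongest `density` fraction of off-diagonal weights:
#' `round(density * n(n-1)/2)` edges. Ties at the cut break deterministically
#' toward the lexicographically smallest `(i, j)` pair, so the mask is a pure
#' function of the weights.
#'
#' @param graph A `"roi_graph"` (from [connectivity_matrix()]) or a symmetric
#'   weight matrix.
#' @param density Fraction of edges to keep, in `(0, 1]`.
#' @return The graph with a symmetric binary `mask` of retained edges.
#' @export
threshold_graph <- function(graph, density = 0.2) {
  if (is.matrix(graph)) graph <- new_roi_graph(graph, NULL, NULL)
  stopifnot(inherits(graph, "roi_graph"))
  if (density <= 0 || density > 1) abort("`density` must lie in (0, 1].")
  n <- graph$n_nodes
  ut <- which(upper.tri(graph$weights), arr.ind = TRUE)
  w <- graph$weights[ut]
  n_keep <- round(density * n * (n - 1) / 2)
  # strongest first; ties by (i, j) lexical order
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- head(ord, n_keep)
  mask <- matrix(0L, n, n, dimnames = dimnames(graph$weights))
  mask[ut[keep, , drop = FALSE]] <- 1L
  mask <- mask + t(mask)
  new_roi_graph(graph$weights, mask = mask, density = density)
}

masked_igraph <- function(graph, weighted = FALSE) {
  if (is.null(graph$mask)) {
    abort("Graph has no retention mask; call threshold_graph() first.")
  }
  adj <- if (weighted) graph$weights * graph$mask else graph$mask
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                      weighted = if (weighted) TRUE else NULL,
                                      diag = FALSE)
}

#' Diversity coefficient of node strength across modules
#'
#' Normalized Shannon entropy of how a node's strength distributes over
#' community modules: 0 when all strength points into a single module, 1 when
#' it is spread equally over all `M` modules. When no module partition is
#' supplied, modules come from greedy modularity maximization on the masked
#' weighted graph (deterministic).
#'
#' @param graph A thresholded `"roi_graph"`.
#' @param modules Optional integer module id per node.
#' @return Numeric vector of per-node diversity coefficients in `[0, 1]`.
#' @export
diversity_coefficient <- function(graph, modules = NULL) {
  stopifnot(inherits(graph, "roi_graph"))
  wadj <- graph$weights * graph$mask
  if (is.null(modules)) {
    g <- masked_igraph(graph, weighted = TRUE)
    comm <- igraph::cluster_fast_greedy(g)
    modules <- igraph::membership(comm)
  }
  modules <- as.integer(modules)
  mod_ids <- sort(unique(modules))
  m_count <- length(mod_ids)
  vapply(seq_len(graph$n_nodes), function(i) {
    s_mod <- vapply(mod_ids, function(mod) {
      sum(wadj[i, modules == mod])
    }, numeric(1))
    s <- sum(s_mod)
    if (s == 0 || m_count <= 1) return(0)
    p <- s_mod[s_mod > 0] / s
    -sum(p * log(p)) / log(m_count)
  }, numeric(1))
}

#' Node-level graph measures of a thresholded connectivity graph
#'
#' The eight node-level measures used as per-ROI features. Degree,
#' betweenness, k-coreness, subgraph, eigenvector and PageRank centralities
#' are computed on the binary masked graph; node strength and the diversity
#' coefficient use the retained weights.
#'
#' * `degree` — retained edges incident to the node.
#' * `node_strength` — sum of retained edge weights.
#' * `diversity_coefficient` — see [diversity_coefficient()].
#' * `betweenness_centrality` — unnormalized shortest-path betweenness with
#'   fractional credit for tied paths; within components on disconnected
#'   graphs.
#' * `k_coreness_centrality` — the node's core number.
#' * `subgraph_centrality` — `sum_j v_j(i)^2 exp(lambda_j)` over the adjacency
#'   eigenpairs (closed walks weighted by inverse factorial of length).
#' * `eigenvector_centrality` — entry of the unit-norm, non-negative principal
#'   eigenvector; errors on an edgeless graph.
#' * `pagerank_centrality` — damping 0.85, uniform teleport; sums to 1.
#'
#' @param graph A thresholded `"roi_graph"`.
#' @return A tibble with one row per node and the eight measure columns.
#' @export
local_graph_measures <- function(graph) {
  stopifnot(inherits(graph, "roi_graph"))
  g <- masked_igraph(graph)
  adj <- graph$mask
  storage.mode(adj) <- "double"
  if (sum(adj) == 0) {
    abort("Graph has no edges; eigenvector centrality is undefined.")
  }
  eig <- eigen(adj, symmetric = TRUE)
  # subgraph centrality from the full eigendecomposition
  subgraph <- as.numeric((eig$vectors^2) %*% exp(eig$values))
  # Perron eigenvector: unit norm, entries made non-negative
  ev <- abs(eig$vectors[, 1])
  ev <- ev / sqrt(sum(ev^2))
  tibble::tibble(
    node = seq_len(graph$n_nodes),
    degree = as.numeric(igraph::degree(g)),
    node_strength = as.numeric(rowSums(graph$weights * graph$mask)),
    diversity_coefficient = diversity_coefficient(graph),
    betweenness_centrality = as.numeric(igraph::betweenness(g, normalized = FALSE)),
    k_coreness_centrality = as.numeric(igraph::coreness(g)),
    subgraph_centrality = subgraph,
    eigenvector_centrality = ev,
    pagerank_centrality = as.numeric(igraph::page_rank(g, damping = 0.85)$vector)
  )
}

#' Graph-level measures: assortativity and small-worldness
#'
#' Assortativity is the Pearson correlation of degrees at either end of the
#' retained edges; a graph whose degrees are all equal has no defined
#' correlation and is reported as 0 with a flag. Small-worldness is
#' `sigma = (C / C_rand) / (L / L_rand)` with `C` the mean binary clustering
#' coefficient (nodes of degree < 2 contribute 0), `L` the characteristic
#' path length over the largest connected component, and the null values
#' averaged over seeded degree-preserving rewirings. A null ensemble with zero
#' clustering yields `sigma = Inf` with a flag.
#'
#' @param graph A thresholded `"roi_graph"` with at least one edge.
#' @param n_rewires Number of rewired null graphs (default 20).
#' @param seed Integer seed for the rewiring null.
#' @param swaps_per_edge Rewiring attempts per edge in each null draw.
#' @return A list with `assortativity`, `small_worldness`, and logical flags
#'   `assortativity_degenerate`, `small_worldness_infinite`.
#' @export
global_graph_measures <- function(graph, n_rewires = 20, seed = 1L,
                                  swaps_per_edge = 10) {
  stopifnot(inherits(graph, "roi_graph"))
  g <- masked_igraph(graph)
  if (igraph::ecount(g) < 1) abort("Graph must have at least one edge.")

  assort <- igraph::assortativity_degree(g)
  assort_flag <- !is.finite(assort)
  if (assort_flag) assort <- 0

  cpl <- function(gr) {
    comps <- igraph::components(gr)
    main <- which.max(comps$csize)
    sub <- igraph::induced_subgraph(gr, which(comps$membership == main))
    if (igraph::vcount(sub) < 2) return(NA_real_)
    igraph::mean_distance(sub)
  }
  clust <- function(gr) {
    mean(igraph::transitivity(gr, type = "localundirected", isolates = "zero"))
  }

  c_obs <- clust(g)
  l_obs <- cpl(g)

  old <- .Random.seed_guard(as.integer(seed))
  on.exit(old(), add = TRUE)
  niter <- max(1L, as.integer(swaps_per_edge * igraph::ecount(g)))
  nulls <- lapply(seq_len(n_rewires), function(b) {
    igraph::rewire(g, igraph::keeping_degseq(niter = niter))
  })
  c_rand <- mean(vapply(nulls, clust, numeric(1)))
  l_rand <- mean(vapply(nulls, cpl, numeric(1)))

  sw_flag <- FALSE
  if (c_rand == 0) {
    sigma <- Inf
    sw_flag <- TRUE
  } else {
    sigma <- (c_obs / c_rand) / (l_obs / l_rand)
  }
  list(assortativity = assort, small_worldness = sigma,
       assortativity_degenerate = assort_flag,
       small_worldness_infinite = sw_flag)
}
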