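#' Names and meanings of the 42 per-ROI features
#'
#' The per-ROI feature vector concatenates 32 orthonormal Haar wavelet
#' coefficients (`d3` x 16, `d4` x 8, `a4` x 8) with the 10 graph measures of
#' the ROI connectivity graph, in a fixed order used everywhere in the
#' package. Feature matrices use the compact ids `f01..f42`; this table maps
#' them to descriptive names.
#'
#' @return A tibble with columns `feature` (`f01..f42`), `name`, and `group`
#'   (`"wavelet"` or `"graph"`).
#' @export
feature_names <- function() {
  wavelet <- c(sprintf("d3_%02d", 1:16), sprintf("d4_%02d", 1:8),
               sprintf("a4_%02d", 1:8))
  graph <- c("degree", "node_strength", "diversity_coefficient",
             "betweenness_centrality", "k_coreness_centrality",
             "subgraph_centrality", "eigenvector_centrality",
             "pagerank_centrality", "assortativity", "small_worldness")
  tibble::tibble(
    feature = sprintf("f%02d", 1:42),
    name = c(wavelet, graph),
    group = rep(c("wavelet", "graph"), c(32, 10))
  )
}

#' Extract the 42-feature vector for every ROI of one subject
#'
#' Per ROI: the 32 Haar wavelet coefficients of its representative time
#' series ([hwt_features()]), the eight node-level graph measures at its node
#' of the thresholded connectivity graph ([local_graph_measures()]), and the
#' two graph-level measures (assortativity, small-worldness) replicated into
#' every ROI's vector.
#'
#' @param roi_series An `n_rois x n_timepoints` matrix, one ROI per row.
#' @param density Proportional threshold retained-edge density, in `(0, 1]`.
#' @param n_rewires Rewired null graphs for small-worldness.
#' @param seed Integer seed for the rewiring null.
#' @return A tibble with one row per ROI: `roi` plus `f01..f42`.
#' @seealso [extract_features()] for whole cohorts, [feature_names()] for the
#'   id-to-name map.
#' @export
extract_roi_features <- function(roi_series, density = 0.2, n_rewires = 20,
                                 seed = 1L) {
  roi_series <- as.matrix(roi_series)
  n_rois <- nrow(roi_series)
  roi_names <- rownames(roi_series)
  if (is.null(roi_names)) roi_names <- sprintf("ROI_%03d", seq_len(n_rois))

  wav <- t(apply(roi_series, 1, hwt_features))

  graph <- threshold_graph(connectivity_matrix(roi_series), density)
  loc <- local_graph_measures(graph)
  glob <- global_graph_measures(graph, n_rewires = n_rewires, seed = seed)
  # an infinite small-worldness sentinel (null ensemble without clustering,
  # possible on very sparse graphs) is recorded as 0 in the feature vector:
  # sigma is positive whenever defined, so 0 stays distinguishable
  if (!is.finite(glob$small_worldness)) glob$small_worldness <- 0

  feats <- cbind(
    wav,
    as.matrix(loc[, c("degree", "node_strength", "diversity_coefficient",
                      "betweenness_centrality", "k_coreness_centrality",
                      "subgraph_centrality", "eigenvector_centrality",
                      "pagerank_centrality")]),
    assortativity = rep(glob$assortativity, n_rois),
    small_worldness = rep(glob$small_worldness, n_rois)
  )
  colnames(feats) <- sprintf("f%02d", 1:42)
  dplyr::bind_cols(tibble::tibble(roi = roi_names), tibble::as_tibble(feats))
}

#' Extract per-ROI features for a whole cohort
#'
#' Maps [extract_roi_features()] over every subject of a cohort tibble,
#' carrying the subject id and class label along. The small-worldness null
#' seed is derived per subject from `seed` so the result is deterministic and
#' independent of subject order.
#'
#' @param cohort A cohort tibble (from [simulate_cohort()] or
#'   [read_cohort()]) with `subject_id`, `label` and `series` columns.
#' @inheritParams extract_roi_features
#' @return A tibble with columns `subject_id`, `label`, `roi`, `f01..f42`,
#'   one row per (subject, ROI).
#' @export
extract_features <- function(cohort, density = 0.2, n_rewires = 20,
                             seed = 1L) {
  stopifnot(all(c("subject_id", "label", "series") %in% names(cohort)))
  seed <- as.integer(seed)
  rows <- purrr::map2(cohort$series, seq_len(nrow(cohort)), function(mat, i) {
    extract_roi_features(mat, density = density, n_rewires = n_rewires,
                         seed = seed + i)
  })
  out <- dplyr::bind_rows(
    purrr::pmap(list(cohort$subject_id, as.character(cohort$label), rows),
                function(id, lab, ft) {
                  dplyr::bind_cols(
                    tibble::tibble(subject_id = id, label = lab,
                                   .rows = nrow(ft)),
                    ft)
                })
  )
  out$label <- factor(out$label, levels = levels(cohort$label))
  out
}
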