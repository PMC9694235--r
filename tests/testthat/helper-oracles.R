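# Independent oracles used across the suite. Everything here is written from
# the definitions, not from the package's code paths.

# Dense orthonormal Haar analysis matrix: row-per-coefficient, built from the
# explicit step-function basis (not the package's pairwise recursion).
# Coefficient order: d1 (n/2), d2 (n/4), ..., dL, then the final approximation.
haar_matrix <- function(n, levels) {
  rows <- list()
  for (l in seq_len(levels)) {
    block <- 2^l
    half <- block / 2
    for (k in seq_len(n / block)) {
      v <- numeric(n)
      i0 <- (k - 1) * block
      v[(i0 + 1):(i0 + half)] <- 1 / sqrt(block)
      v[(i0 + half + 1):(i0 + block)] <- -1 / sqrt(block)
      rows[[length(rows) + 1]] <- v
    }
  }
  block <- 2^levels
  for (k in seq_len(n / block)) {
    v <- numeric(n)
    i0 <- (k - 1) * block
    v[(i0 + 1):(i0 + block)] <- 1 / sqrt(block)
    rows[[length(rows) + 1]] <- v
  }
  do.call(rbind, rows)
}

# --- brute-force graph measures on a binary adjacency matrix -----------------

bf_degree <- function(adj) rowSums(adj)

bf_strength <- function(weights, adj) rowSums(weights * adj)

# all shortest paths by exhaustive simple-path enumeration (n <= 6)
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  all_paths <- function(from, to) {
    paths <- list()
    walk <- function(path) {
      cur <- path[length(path)]
      if (cur == to) {
        paths[[length(paths) + 1]] <<- path
        return()
      }
      for (nb in which(adj[cur, ] > 0)) {
        if (!nb %in% path) walk(c(path, nb))
      }
    }
    walk(from)
    paths
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      for (p in shortest) {
        inner <- setdiff(p, c(s, t))
        # symmetric: each unordered pair credits interior nodes once
        for (v in inner) btw[v] <- btw[v] + 1 / sigma
      }
    }
  }
  btw
}

# core numbers by iterative peeling: at stage k, repeatedly strip nodes whose
# remaining degree is <= k; stripped nodes have core number k
bf_kcore <- function(adj) {
  n <- nrow(adj)
  core <- integer(n)
  alive <- rep(TRUE, n)
  k <- 0
  while (any(alive)) {
    repeat {
      idx <- which(alive)
      degs <- vapply(idx, function(v) sum(adj[v, alive]), numeric(1))
      victims <- idx[degs <= k]
      if (length(victims) == 0) break
      core[victims] <- k
      alive[victims] <- FALSE
      if (!any(alive)) break
    }
    k <- k + 1
  }
  core
}

# subgraph centrality via the truncated matrix-power series sum_k A^k / k!
bf_subgraph <- function(adj, kmax = 40) {
  n <- nrow(adj)
  acc <- diag(n)
  term <- diag(n)
  for (k in seq_len(kmax)) {
    term <- term %*% adj / k
    acc <- acc + term
  }
  diag(acc)
}

# principal eigenvector by power iteration on A + I (shift keeps bipartite
# graphs convergent), unit norm, non-negative
bf_eigenvector <- function(adj, iters = 5000) {
  n <- nrow(adj)
  v <- rep(1 / sqrt(n), n)
  m <- adj + diag(n)
  for (i in seq_len(iters)) {
    v2 <- as.numeric(m %*% v)
    v2 <- v2 / sqrt(sum(v2^2))
    if (max(abs(v2 - v)) < 1e-13) {
      v <- v2
      break
    }
    v <- v2
  }
  abs(v)
}

# PageRank by direct linear solve (no power iteration, no igraph)
bf_pagerank <- function(adj, d = 0.85) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  stopifnot(all(deg > 0))
  m <- t(adj / deg)
  solve(diag(n) - d * m, rep((1 - d) / n, n))
}

# degree-degree Pearson correlation over edge endpoints (both orientations)
bf_assortativity <- function(adj) {
  deg <- rowSums(adj)
  ends <- which(adj > 0, arr.ind = TRUE) # both orientations of each edge
  suppressWarnings(cor(deg[ends[, 1]], deg[ends[, 2]]))
}

# --- graph enumeration -------------------------------------------------------

is_connected_adj <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] > 0))))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

# all labeled connected graphs on n nodes (n <= 5 keeps this tractable)
enumerate_connected_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  npairs <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^npairs - 1)) {
    adj <- matrix(0, n, n)
    bits <- bitwAnd(mask, 2^(seq_len(npairs) - 1)) > 0
    sel <- pairs[bits, , drop = FALSE]
    adj[sel] <- 1
    adj <- adj + t(adj)
    if (is_connected_adj(adj)) out[[length(out) + 1]] <- adj
  }
  out
}

# all connected 6-node graphs up to isomorphism, via the igraph graph atlas
# (atlas indices 53..208 are the 156 graphs on 6 unlabeled nodes)
atlas_connected_graphs_6 <- function() {
  out <- list()
  for (i in 53:208) {
    g <- igraph::graph_from_atlas(i)
    if (igraph::vcount(g) == 6 && igraph::is_connected(g) &&
        igraph::ecount(g) >= 1) {
      out[[length(out) + 1]] <- as.matrix(igraph::as_adjacency_matrix(g))
    }
  }
  out
}

# wrap an adjacency (+ optional weights) as a thresholded roi_graph with the
# mask equal to the adjacency itself
graph_from_adjacency <- function(adj, weights = NULL) {
  if (is.null(weights)) weights <- adj * 1.0
  structure(list(n_nodes = nrow(adj), weights = weights,
                 mask = adj, density = sum(adj) / (nrow(adj) * (nrow(adj) - 1))),
            class = "roi_graph")
}

# --- data generators ---------------------------------------------------------

separable_1d <- function() {
  list(x = matrix(c(0.1, 0.2, 0.8, 0.9), ncol = 1), y = c(0L, 0L, 1L, 1L))
}

# Planted-subcluster data on two features (XOR-corner layout): class 1 holds
# a main corner (high, high) plus a small subcluster at the opposite corner
# (low, low); class 0 holds the two mixed corners. The additive per-feature
# NEWFM score cannot express the interaction, so standard training overlooks
# the subcluster; the subpattern NEWFM trained on the misclassified instances
# is what must recover it.
planted_subcluster <- function(seed, n0 = 50, n1_main = 40, n_sub = 8) {
  set.seed(seed)
  corner <- function(n, mx, my, s = 0.08) cbind(rnorm(n, mx, s), rnorm(n, my, s))
  x <- rbind(corner(n0 / 2, 0.2, 0.8), corner(n0 / 2, 0.8, 0.2),
             corner(n1_main, 0.8, 0.8), corner(n_sub, 0.2, 0.2))
  y <- c(rep(0L, n0), rep(1L, n1_main + n_sub))
  list(x = x, y = y, sub_idx = n0 + n1_main + seq_len(n_sub))
}

# random fabricated NEWFM model (sorted centers, random weights) for
# consistency checks that must hold for any model state
random_newfm <- function(p = 4, m = 3) {
  centers <- array(0, dim = c(m, 2, p))
  weights <- array(runif(m * 2 * p), dim = c(m, 2, p))
  for (f in seq_len(p)) {
    for (cls in 1:2) centers[, cls, f] <- sort(runif(m))
  }
  structure(list(
    n_features = p, feature_names = NULL, m = m,
    centers = centers, weights = weights,
    feature_ranges = rbind(rep(0, p), rep(1, p)),
    selected_features = seq_len(p),
    hyperparams = list(m = m, alpha = 0.1, delta = 0.1, max_epochs = 0,
                       patience = 3),
    epochs_run = 0L, train_accuracy = NA_real_, accuracy_history = numeric()
  ), class = "newfm")
}

small_cohort_spec <- function(seed = 1, ...) {
  args <- list(
    n_per_class = c(AD = 8, MCI = 4, NC = 4), n_rois = 8,
    informative_rois = 1:3, spectral_effect = 3, connectivity_effect = 0.4,
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}
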