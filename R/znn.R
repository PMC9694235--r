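#' Split a feature vector into contiguous equal blocks
#'
#' The ZNN input layer and every inter-layer hand-off divide their features
#' into `k` contiguous, order-preserving blocks of equal size.
#'
#' @param p Number of features (or a vector whose length is used).
#' @param k Number of blocks; must divide `p`.
#' @return List of `k` integer index vectors.
#' @examples
#' split_features(320, 16) # 16 blocks of 20
#' @export
split_features <- function(p, k) {
  if (length(p) > 1) p <- length(p)
  p <- as.integer(p)
  k <- as.integer(k)
  if (k < 1) abort("`k` must be a positive count.")
  if (p %% k != 0) {
    abort(sprintf("%d features cannot be split into %d equal blocks.", p, k))
  }
  size <- p %/% k
  lapply(seq_len(k), function(j) seq.int((j - 1L) * size + 1L, j * size))
}

validate_layer_config <- function(p, layers) {
  layers <- as.integer(layers)
  if (length(layers) < 1 || any(layers < 1)) {
    abort("`layers` must be a vector of positive ZLU counts.")
  }
  if (p %% layers[1] != 0) {
    abort(sprintf(
      "input width %d is not divisible by the first layer's %d ZLUs.",
      p, layers[1]))
  }
  if (length(layers) > 1) {
    for (i in seq_len(length(layers) - 1)) {
      if ((2L * layers[i]) %% layers[i + 1] != 0) {
        abort(sprintf(
          "layer %d emits %d TSDs, not divisible by layer %d's %d ZLUs.",
          i, 2L * layers[i], i + 1, layers[i + 1]))
      }
    }
  }
  layers
}

# forward one layer: per-unit TSD pairs, concatenated (t_m1, t_c1, t_m2, ...)
layer_tsds <- function(units, blocks, input) {
  mats <- Map(function(unit, idx) {
    predict(unit, input[, idx, drop = FALSE])
  }, units, blocks)
  do.call(cbind, mats)
}

#' Fit a zoom-in neural network (ZNN)
#'
#' A ZNN stacks layers of zoom-in learning units ([zlu()]) in a purely
#' feedforward hierarchy — there is no backpropagation and no gradient. The
#' input features are split into `layers[1]` contiguous blocks, one per
#' first-layer ZLU. Each trained ZLU emits its subpattern/refined TSD pair for
#' *every* training instance (not only the group it trained on), and the
#' concatenated pairs `(t_m1, t_c1, t_m2, t_c2, ...)` are split into
#' `layers[2]` blocks feeding the next layer, and so on. A final output NEWFM
#' is trained on the last layer's TSD vector and produces the network's class
#' and TSD score. At test time only the subpattern and refined learners of
#' each ZLU are consulted.
#'
#' For layerwise diagnostics, a readout NEWFM is also trained on every
#' intermediate layer's TSD matrix (see [layer_accuracies()]); readouts take
#' no part in the forward pass.
#'
#' @inheritParams zlu
#' @param layers Integer vector of ZLU counts per layer, e.g. `c(16, 4)`.
#'   `ncol(x)` must be divisible by `layers[1]`, and twice each layer's count
#'   by the next layer's count.
#' @param n_select_zlu Features kept by selection inside each first-layer
#'   ZLU's standard training (`NULL` keeps all).
#' @return An object of class `"znn"`: the input split, per-layer ZLU lists,
#'   layer readout NEWFMs, the output NEWFM, and the training accuracy.
#' @examples
#' set.seed(1)
#' x <- matrix(runif(400), ncol = 8)
#' y <- as.integer(x[, 1] + x[, 5] > 1)
#' net <- znn(x, y, layers = c(4, 2))
#' predict(net, x)[1:5]
#' @seealso [predict.znn()], [layer_accuracies()]
#' @export
znn <- function(x, y, layers = c(16, 4), m = 3, alpha = 0.1, delta = 0.1,
                max_epochs = 50, patience = 3, n_select_zlu = NULL,
                min_count = 4) {
  x <- as_feature_matrix(x)
  y <- as_binary_labels(y)
  layers <- validate_layer_config(ncol(x), layers)

  input_split <- split_features(ncol(x), layers[1])
  cur <- x
  blocks <- input_split
  zlu_layers <- vector("list", length(layers))
  readouts <- vector("list", length(layers))

  for (i in seq_along(layers)) {
    units <- lapply(blocks, function(idx) {
      zlu(cur[, idx, drop = FALSE], y, m = m, alpha = alpha, delta = delta,
          max_epochs = max_epochs, patience = patience,
          n_select = if (i == 1) n_select_zlu else NULL,
          min_count = min_count)
    })
    zlu_layers[[i]] <- units
    cur <- layer_tsds(units, blocks, cur)
    readouts[[i]] <- newfm(cur, y, m = m, alpha = alpha, delta = delta,
                           max_epochs = max_epochs, patience = patience)
    if (i < length(layers)) {
      blocks <- split_features(ncol(cur), layers[i + 1])
    }
  }

  output <- newfm(cur, y, m = m, alpha = alpha, delta = delta,
                  max_epochs = max_epochs, patience = patience)

  structure(list(
    n_features = ncol(x),
    layer_config = layers,
    input_split = input_split,
    layers = zlu_layers,
    readouts = readouts,
    output = output,
    hyperparams = list(m = m, alpha = alpha, delta = delta,
                       max_epochs = max_epochs, patience = patience,
                       n_select_zlu = n_select_zlu, min_count = min_count),
    train_accuracy = mean(predict(output, cur) == y)
  ), class = "znn")
}

# forward pass up to (and including) layer `upto`; returns the TSD matrix
znn_forward <- function(object, x, upto = length(object$layers)) {
  cur <- x
  blocks <- object$input_split
  for (i in seq_len(upto)) {
    units <- object$layers[[i]]
    cur <- layer_tsds(units, blocks, cur)
    if (i < length(object$layers)) {
      blocks <- split_features(ncol(cur), object$layer_config[i + 1])
    }
  }
  cur
}

#' Predict from a zoom-in neural network
#'
#' Runs the feedforward test path: every layer's ZLUs emit their TSD pairs
#' (standard learners are never consulted), and the output NEWFM turns the
#' final TSD vector into a class or a defuzzified score.
#'
#' @param object A fitted [znn()].
#' @param newdata Instance matrix with `object$n_features` columns.
#' @param type `"class"` for 0/1 labels, `"tsd"` for the output NEWFM's
#'   defuzzified score in `[0, 1]`.
#' @param ... Unused.
#' @return Integer or numeric vector, one value per row of `newdata`.
#' @export
predict.znn <- function(object, newdata, type = c("class", "tsd"), ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(newdata)
  if (ncol(x) != object$n_features) {
    abort(sprintf("`newdata` has %d features; the network expects %d.",
                  ncol(x), object$n_features))
  }
  final <- znn_forward(object, x)
  predict(object$output, final, type = type)
}

#' Per-layer accuracies of a fitted ZNN
#'
#' Scores each ZLU layer through its readout NEWFM (trained on that layer's
#' training TSD matrix) and the output layer through the network's own output
#' NEWFM, on any instance set. The layerwise profile shows how discrimination
#' accumulates as TSD pairs are stacked.
#'
#' @param object A fitted [znn()].
#' @param x Instance matrix.
#' @param y Binary labels.
#' @return A tibble with columns `layer` (`"zlu_1"`, ..., `"output"`) and
#'   `accuracy` (fraction correct in `[0, 1]`).
#' @export
layer_accuracies <- function(object, x, y) {
  stopifnot(inherits(object, "znn"))
  x <- as_feature_matrix(x)
  y <- as_binary_labels(y)
  n_layers <- length(object$layers)
  acc <- numeric(n_layers + 1)
  for (i in seq_len(n_layers)) {
    tsds <- znn_forward(object, x, upto = i)
    acc[i] <- mean(predict(object$readouts[[i]], tsds) == y)
  }
  acc[n_layers + 1] <- mean(predict(object, x) == y)
  tibble::tibble(
    layer = c(paste0("zlu_", seq_len(n_layers)), "output"),
    accuracy = acc
  )
}

#' @export
print.znn <- function(x, ...) {
  cat("Zoom-in neural network (ZNN)\n")
  cat(sprintf("  input features: %d, ZLU layers: [%s], output NEWFM on %d TSDs\n",
              x$n_features, paste(x$layer_config, collapse = ", "),
              2L * x$layer_config[length(x$layer_config)]))
  cat(sprintf("  training accuracy: %.3f\n", x$train_accuracy))
  invisible(x)
}
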