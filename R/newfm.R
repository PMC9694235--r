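#' Fit a neuro-fuzzy NEWFM classifier
#'
#' NEWFM (neural network with weighted fuzzy membership functions) is a
#' supervised feedforward neuro-fuzzy classifier. Each feature carries, per
#' class, a small bank of triangular membership functions whose bounded
#' weighted sum (BSWFM, capped at 1) is that class's fuzzy activation for the
#' feature. Training is online and winner-take-all: for every instance the
#' membership-maximal function of the true class pulls its center toward the
#' observed value by `alpha` and gains `delta` weight, while the winner of the
#' opposing class loses `delta` weight; supports are re-derived from the
#' neighbouring centers so `left <= center <= right` always holds. Training
#' stops at `max_epochs` or after `patience` epochs without improvement in
#' training accuracy, and the best-scoring epoch's state is kept. There is no
#' gradient and no backpropagation anywhere in the fit.
#'
#' @param x Numeric matrix or data frame of instances (rows) by features
#'   (columns).
#' @param y Binary labels: a vector coercible to 0/1 (logical, factor with two
#'   levels, or numeric 0/1). Both classes must be present.
#' @param m Number of membership functions per feature per class (>= 2).
#' @param alpha Learning rate for the winner's center pull, in (0, 1].
#' @param delta Weight increment/decrement per update, in (0, 1].
#' @param max_epochs Maximum training epochs.
#' @param patience Epochs without training-accuracy improvement before
#'   stopping early.
#' @param n_select If non-`NULL`, keep only this many features after training,
#'   ranked by the non-overlap area between the two class BSWFM curves (see
#'   [newfm_select_features()]).
#' @param selected Optional fixed feature subset (1-based indices) to score
#'   with, bypassing built-in selection (used by zoom-in learning units that
#'   share one selection across their three learners).
#' @param ranges Optional 2 x p matrix of per-feature (min, max) ranges;
#'   defaults to the training-data ranges. Degenerate ranges are widened by a
#'   small pad and flagged.
#'
#' @return An object of class `"newfm"`: a list with the membership-function
#'   state (`centers`, `weights` as `m x 2 x p` arrays), `feature_ranges`,
#'   `selected_features`, hyperparameters, `epochs_run`, `train_accuracy` and
#'   `accuracy_history`.
#'
#' @examples
#' x <- matrix(c(0.1, 0.2, 0.8, 0.9), ncol = 1)
#' y <- c(0, 0, 1, 1)
#' fit <- newfm(x, y)
#' predict(fit, x)
#' predict(fit, x, type = "tsd")
#' @seealso [predict.newfm()], [newfm_select_features()], [zlu()], [znn()]
#' @export
newfm <- function(x, y, m = 3, alpha = 0.1, delta = 0.1, max_epochs = 50,
                  patience = 3, n_select = NULL, selected = NULL,
                  ranges = NULL) {
  x <- as_feature_matrix(x)
  y <- as_binary_labels(y)
  if (nrow(x) != length(y)) {
    abort("`x` and `y` disagree on the number of instances.")
  }
  if (length(unique(y)) < 2) {
    abort("NEWFM training needs instances of both classes.")
  }
  if (m < 2) abort("`m` must be at least 2 membership functions.")
  p <- ncol(x)
  if (p == 0) abort("`x` must have at least one feature.")

  if (is.null(ranges)) {
    ranges <- rbind(apply(x, 2, min), apply(x, 2, max))
  }
  ranges <- validate_ranges(ranges, p)

  init <- newfm_init_state(ranges, m)
  sel <- if (is.null(selected)) seq_len(p) else validate_selected(selected, p)

  # online updates are processed in a deterministic class-balanced
  # interleaving: with class-blocked input order, one class's consecutive
  # punishments would decay the other's weights multiplicatively to zero
  # within a single epoch
  ord <- interleave_classes(y)
  fit <- newfm_train_cpp(as.numeric(init$centers), as.numeric(init$weights),
                         m, x[ord, , drop = FALSE], as.integer(y[ord]),
                         alpha, delta,
                         as.integer(max_epochs), as.integer(patience),
                         as.integer(sel - 1L))

  model <- structure(list(
    n_features = p,
    feature_names = colnames(x),
    m = m,
    centers = array(fit$centers, dim = c(m, 2, p)),
    weights = array(fit$weights, dim = c(m, 2, p)),
    feature_ranges = ranges,
    selected_features = sel,
    hyperparams = list(m = m, alpha = alpha, delta = delta,
                       max_epochs = max_epochs, patience = patience),
    epochs_run = fit$epochs_run,
    train_accuracy = fit$train_accuracy,
    accuracy_history = fit$accuracy_history
  ), class = "newfm")

  if (!is.null(n_select) && is.null(selected)) {
    model$selected_features <- newfm_select_features(model, n_select)
    model$train_accuracy <- mean(predict(model, x) == y)
  }
  model
}

# deterministic class-balanced processing order: within each class, scatter
# the instances by a golden-ratio (low-discrepancy) sequence so contiguous
# clusters in the input never update in long unopposed runs, then weave the
# two classes by within-class position
interleave_classes <- function(y) {
  phi <- (sqrt(5) - 1) / 2
  scatter <- function(idx) idx[order((seq_along(idx) * phi) %% 1)]
  i0 <- scatter(which(y == 0L))
  i1 <- scatter(which(y == 1L))
  pos <- c((seq_along(i0) - 0.5) / length(i0),
           (seq_along(i1) - 0.5) / length(i1))
  c(i0, i1)[order(pos)]
}

# initial state: centers evenly spaced over the feature range, weights zero
newfm_init_state <- function(ranges, m) {
  p <- ncol(ranges)
  centers <- array(0, dim = c(m, 2, p))
  for (f in seq_len(p)) {
    cs <- seq(ranges[1, f], ranges[2, f], length.out = m)
    centers[, 1, f] <- cs
    centers[, 2, f] <- cs
  }
  list(centers = centers, weights = array(0, dim = c(m, 2, p)))
}

validate_ranges <- function(ranges, p) {
  ranges <- as.matrix(ranges)
  if (nrow(ranges) != 2 || ncol(ranges) != p) {
    abort("`ranges` must be a 2 x n_features matrix of (min, max).")
  }
  if (any(!is.finite(ranges))) abort("Feature ranges must be finite.")
  degenerate <- ranges[2, ] <= ranges[1, ]
  if (any(degenerate)) {
    # widen flat ranges by a machine-epsilon-scaled pad so MFs stay valid
    pad <- pmax(abs(ranges[1, degenerate]), 1) * sqrt(.Machine$double.eps)
    ranges[1, degenerate] <- ranges[1, degenerate] - pad
    ranges[2, degenerate] <- ranges[2, degenerate] + pad
    attr(ranges, "degenerate") <- which(degenerate)
  }
  ranges
}

validate_selected <- function(selected, p) {
  selected <- as.integer(selected)
  if (length(selected) == 0 || anyNA(selected) ||
      any(selected < 1L | selected > p)) {
    abort("`selected` must be feature indices in 1..n_features.")
  }
  selected
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix or data frame.")
  }
  if (anyNA(x)) abort("`x` must not contain missing values.")
  x
}

as_binary_labels <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  y <- as.integer(y)
  if (anyNA(y) || any(!y %in% c(0L, 1L))) {
    abort("`y` must be binary (0/1, logical, or a two-level factor).")
  }
  y
}

#' Predict classes, scores or defuzzified outputs from a NEWFM
#'
#' Class scores are the per-class sums of BSWFM activations over the selected
#' features. `type = "class"` returns the argmax (ties go to class 0);
#' `type = "tsd"` returns the Takagi-Sugeno defuzzified output, the normalized
#' class contrast `(s1 - s0) / (s1 + s0)` mapped to `[0, 1]` (0.5 when both
#' scores are zero); `type = "score"` returns the raw two-column score matrix.
#'
#' @param object A fitted [newfm()] model.
#' @param newdata Matrix or data frame of instances.
#' @param type One of `"class"`, `"tsd"`, `"score"`.
#' @param ... Unused.
#' @return An integer vector of 0/1 classes, a numeric vector in `[0, 1]`, or
#'   an `n x 2` score matrix.
#' @export
predict.newfm <- function(object, newdata, type = c("class", "tsd", "score"),
                          ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(newdata)
  if (ncol(x) != object$n_features) {
    abort(sprintf("`newdata` has %d features; the model expects %d.",
                  ncol(x), object$n_features))
  }
  sc <- newfm_scores_cpp(as.numeric(object$centers),
                         as.numeric(object$weights), object$m, x,
                         as.integer(object$selected_features - 1L))
  switch(type,
    score = {
      colnames(sc) <- c("class0", "class1")
      sc
    },
    class = as.integer(sc[, 2] > sc[, 1]),
    tsd = {
      den <- sc[, 1] + sc[, 2]
      t_raw <- ifelse(den > 0, (sc[, 2] - sc[, 1]) / den, 0)
      (t_raw + 1) / 2
    }
  )
}

#' Evaluate one BSWFM curve of a fitted NEWFM
#'
#' @param object A fitted [newfm()] model.
#' @param feature Feature index (1-based).
#' @param class Class, 0 or 1.
#' @param at Numeric vector of evaluation points.
#' @return Numeric vector of bounded-sum activations in `[0, 1]`.
#' @export
newfm_bswfm <- function(object, feature, class, at) {
  stopifnot(inherits(object, "newfm"))
  feature <- as.integer(feature)
  if (feature < 1L || feature > object$n_features) {
    abort("`feature` out of range.")
  }
  if (!class %in% c(0, 1)) abort("`class` must be 0 or 1.")
  newfm_bswfm_cpp(as.numeric(object$centers), as.numeric(object$weights),
                  object$m, feature - 1L, as.integer(class), as.numeric(at))
}

#' Rank features by class separation of their fuzzy membership curves
#'
#' The built-in NEWFM feature selection scores each feature by the non-overlap
#' area between its two class BSWFM curves, `integral |b1(x) - b0(x)| dx` over
#' the feature's training range (trapezoid rule on a 256-point grid). Features
#' whose class curves coincide score 0; well-separated features score high.
#' Ties break toward the lower feature index.
#'
#' @param object A fitted [newfm()] model.
#' @param n_keep Number of features to keep (1..n_features).
#' @param grid_points Grid resolution for the trapezoid rule.
#' @return Integer vector of the `n_keep` top-ranked feature indices, in rank
#'   order.
#' @export
newfm_select_features <- function(object, n_keep, grid_points = 256) {
  stopifnot(inherits(object, "newfm"))
  n_keep <- as.integer(n_keep)
  if (n_keep < 1L || n_keep > object$n_features) {
    abort("`n_keep` must be between 1 and the number of features.")
  }
  areas <- vapply(seq_len(object$n_features), function(f) {
    xs <- seq(object$feature_ranges[1, f], object$feature_ranges[2, f],
              length.out = grid_points)
    b0 <- newfm_bswfm(object, f, 0, xs)
    b1 <- newfm_bswfm(object, f, 1, xs)
    d <- abs(b1 - b0)
    h <- diff(xs)
    sum((d[-1] + d[-length(d)]) / 2 * h)
  }, numeric(1))
  # ranking ties resolve toward the lower feature index
  ord <- order(-areas, seq_along(areas))
  head(ord, n_keep)
}

#' @export
print.newfm <- function(x, ...) {
  cat("NEWFM neuro-fuzzy classifier\n")
  cat(sprintf("  features: %d (%d selected), m = %d MFs/feature/class\n",
              x$n_features, length(x$selected_features), x$m))
  cat(sprintf("  epochs run: %d, training accuracy: %.3f\n",
              x$epochs_run, x$train_accuracy))
  invisible(x)
}
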