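# broom-style tidiers and ggplot2 autoplot methods for the fitted objects

#' Tidy a NEWFM into its membership-function table
#'
#' @param x A fitted [newfm()].
#' @param ... Unused.
#' @return A tibble with one row per (feature, class, membership function):
#'   `feature`, `class`, `mf`, `left`, `center`, `right`, `weight`,
#'   `selected`.
#' @method tidy newfm
#' @export
tidy.newfm <- function(x, ...) {
  m <- x$m
  rows <- list()
  for (f in seq_len(x$n_features)) {
    for (cls in 0:1) {
      cs <- x$centers[, cls + 1, f]
      left <- c(cs[1] - (cs[2] - cs[1]), cs[-m])
      right <- c(cs[-1], cs[m] + (cs[m] - cs[m - 1]))
      rows[[length(rows) + 1]] <- tibble::tibble(
        feature = f, class = cls, mf = seq_len(m),
        left = left, center = cs, right = right,
        weight = x$weights[, cls + 1, f],
        selected = f %in% x$selected_features
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Model-level summary of a NEWFM fit
#'
#' @param x A fitted [newfm()].
#' @param ... Unused.
#' @return One-row tibble: `n_features`, `n_selected`, `m`, `epochs_run`,
#'   `train_accuracy`.
#' @method glance newfm
#' @export
glance.newfm <- function(x, ...) {
  tibble::tibble(
    n_features = x$n_features,
    n_selected = length(x$selected_features),
    m = x$m,
    epochs_run = x$epochs_run,
    train_accuracy = x$train_accuracy
  )
}

#' Plot the class BSWFM curves of a NEWFM
#'
#' One panel per plotted feature, the two class curves overlaid; the area
#' where the curves separate is exactly what the built-in feature selection
#' scores.
#'
#' @param object A fitted [newfm()].
#' @param features Feature indices to plot (default: up to the first 6
#'   selected features).
#' @param grid_points Curve resolution.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot newfm
#' @export
autoplot.newfm <- function(object, features = NULL, grid_points = 200, ...) {
  if (is.null(features)) {
    features <- head(object$selected_features, 6)
  }
  curves <- dplyr::bind_rows(lapply(features, function(f) {
    xs <- seq(object$feature_ranges[1, f], object$feature_ranges[2, f],
              length.out = grid_points)
    dplyr::bind_rows(lapply(0:1, function(cls) {
      tibble::tibble(feature = paste0("feature ", f), x = xs,
                     class = factor(cls),
                     activation = newfm_bswfm(object, f, cls, xs))
    }))
  }))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$x, y = .data$activation,
                               colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~feature, scales = "free_x") +
    ggplot2::labs(x = "feature value", y = "BSWFM activation",
                  colour = "class") +
    ggplot2::ylim(0, 1)
}

#' Tidy a fitted ZNN into a per-unit summary
#'
#' @param x A fitted [znn()].
#' @param ... Unused.
#' @return A tibble with one row per ZLU: `layer`, `unit`, `n_features`,
#'   `n_mi`, `n_cci`, fallback flags.
#' @method tidy znn
#' @export
tidy.znn <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$layers), function(i) {
    dplyr::bind_rows(lapply(seq_along(x$layers[[i]]), function(j) {
      u <- x$layers[[i]][[j]]
      tibble::tibble(
        layer = i, unit = j, n_features = u$n_features,
        n_mi = length(u$mi), n_cci = length(u$cci),
        subpattern_fallback = u$subpattern_fallback,
        refined_fallback = u$refined_fallback
      )
    }))
  }))
}

#' Model-level summary of a ZNN fit
#'
#' @param x A fitted [znn()].
#' @param ... Unused.
#' @return One-row tibble: `n_features`, `n_layers`, `n_zlus`,
#'   `train_accuracy`.
#' @method glance znn
#' @export
glance.znn <- function(x, ...) {
  tibble::tibble(
    n_features = x$n_features,
    n_layers = length(x$layer_config),
    n_zlus = sum(x$layer_config),
    train_accuracy = x$train_accuracy
  )
}

#' Tidy an assessment into its layerwise accuracy table
#'
#' @param x A `"znn_assessment"` (from [run_assessment()]).
#' @param ... Unused.
#' @return A tibble with columns `layer`, `split`, `accuracy` (percent).
#' @method tidy znn_assessment
#' @export
tidy.znn_assessment <- function(x, ...) {
  tidyr::pivot_longer(x$accuracies, cols = c("train", "test"),
                      names_to = "split", values_to = "accuracy")
}

#' One-row summary of an assessment
#'
#' @param x A `"znn_assessment"`.
#' @param ... Unused.
#' @return Tibble: `task`, `n_rois`, `n_layers`, `train_accuracy`,
#'   `test_accuracy` (percent).
#' @method glance znn_assessment
#' @export
glance.znn_assessment <- function(x, ...) {
  tibble::tibble(
    task = x$task,
    n_rois = length(x$selected_rois),
    n_layers = length(x$layers),
    train_accuracy = x$train_accuracy,
    test_accuracy = x$test_accuracy
  )
}

#' Plot layerwise accuracies of an assessment
#'
#' Train and test accuracy per layer, showing how discrimination accumulates
#' as ZLU layers stack.
#'
#' @param object A `"znn_assessment"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot znn_assessment
#' @export
autoplot.znn_assessment <- function(object, ...) {
  df <- tidy.znn_assessment(object)
  df$layer <- factor(df$layer, levels = object$accuracies$layer)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer, y = .data$accuracy,
                                   colour = .data$split,
                                   group = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(title = paste("ZNN assessment", object$task),
                  x = NULL, y = "accuracy (%)", colour = NULL)
}
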