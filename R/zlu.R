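#' Fit a zoom-in learning unit (ZLU)
#'
#' A ZLU wraps three NEWFM learners. A *standard* NEWFM is trained on all
#' instances; its predictions partition the training set into misclassified
#' instances (MIs) and correctly classified instances (CCIs). A *subpattern*
#' NEWFM is then trained on the MIs — zooming in on the pattern the standard
#' fit missed — and a *refined* NEWFM on the CCIs, learning the clean part of
#' the data in more detail. At test time only the subpattern and refined
#' learners are consulted; each emits a Takagi-Sugeno defuzzified (TSD) score,
#' and the pair feeds the next layer of a [znn()].
#'
#' When the MI (or CCI) group has fewer than `min_count` instances or only one
#' class, the corresponding learner falls back to a copy of the standard model
#' so the unit's outputs are always defined; the fallback is flagged.
#'
#' Feature selection (`n_select`) runs once, inside the standard training; the
#' selected subset is shared by the subpattern and refined learners unless
#' `reselect = TRUE`, in which case each fits its own selection on its group.
#'
#' @inheritParams newfm
#' @param n_select Features kept by the standard NEWFM's built-in selection
#'   (`NULL` keeps all).
#' @param min_count Minimum group size for fitting a dedicated subpattern or
#'   refined NEWFM.
#' @param reselect Re-run feature selection independently inside the
#'   subpattern/refined fits instead of inheriting the standard selection.
#' @return An object of class `"zlu"`: list with `standard`, `subpattern`,
#'   `refined` NEWFM models, fallback flags, and the MI/CCI index sets.
#' @examples
#' set.seed(1)
#' x <- matrix(runif(60), ncol = 2)
#' y <- as.integer(x[, 1] > 0.5)
#' unit <- zlu(x, y)
#' head(predict(unit, x))
#' @seealso [zlu_groups()], [znn()]
#' @export
zlu <- function(x, y, m = 3, alpha = 0.1, delta = 0.1, max_epochs = 50,
                patience = 3, n_select = NULL, min_count = 4,
                reselect = FALSE) {
  x <- as_feature_matrix(x)
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2) {
    abort("ZLU training needs instances of both classes.")
  }

  standard <- newfm(x, y, m = m, alpha = alpha, delta = delta,
                    max_epochs = max_epochs, patience = patience,
                    n_select = n_select)
  groups <- zlu_groups(standard, x, y)

  fit_group <- function(idx) {
    if (length(idx) < min_count || length(unique(y[idx])) < 2) {
      return(list(model = standard, fallback = TRUE))
    }
    sel <- if (reselect) NULL else standard$selected_features
    n_sel <- if (reselect) n_select else NULL
    model <- newfm(x[idx, , drop = FALSE], y[idx], m = m, alpha = alpha,
                   delta = delta, max_epochs = max_epochs,
                   patience = patience, n_select = n_sel, selected = sel,
                   ranges = standard$feature_ranges)
    list(model = model, fallback = FALSE)
  }

  sub <- fit_group(groups$mi)
  ref <- fit_group(groups$cci)

  structure(list(
    standard = standard,
    subpattern = sub$model,
    refined = ref$model,
    subpattern_fallback = sub$fallback,
    refined_fallback = ref$fallback,
    mi = groups$mi,
    cci = groups$cci,
    n_features = standard$n_features
  ), class = "zlu")
}

#' Partition instances into misclassified and correctly classified groups
#'
#' Instance grouping under a trained standard NEWFM: every instance lands in
#' exactly one of MI (prediction differs from the label) or CCI (prediction
#' matches). The two index sets always partition `seq_len(nrow(x))`.
#'
#' @param model A fitted [newfm()] model.
#' @param x Instance matrix.
#' @param y Binary labels.
#' @return List with integer index vectors `mi` and `cci`.
#' @export
zlu_groups <- function(model, x, y) {
  y <- as_binary_labels(y)
  pred <- predict(model, x)
  list(mi = which(pred != y), cci = which(pred == y))
}

#' TSD output pair of a zoom-in learning unit
#'
#' The test path of a ZLU: inputs go directly to the subpattern and refined
#' NEWFMs (the standard learner is never consulted after training), each
#' producing a Takagi-Sugeno defuzzified score in `[0, 1]`.
#'
#' @param object A fitted [zlu()].
#' @param newdata Instance matrix.
#' @param ... Unused.
#' @return An `n x 2` matrix with columns `t_m` (subpattern TSD) and `t_c`
#'   (refined TSD).
#' @export
predict.zlu <- function(object, newdata, ...) {
  out <- cbind(
    t_m = predict(object$subpattern, newdata, type = "tsd"),
    t_c = predict(object$refined, newdata, type = "tsd")
  )
  out
}

#' @export
print.zlu <- function(x, ...) {
  cat("Zoom-in learning unit (ZLU)\n")
  cat(sprintf("  features: %d, |MI| = %d, |CCI| = %d\n", x$n_features,
              length(x$mi), length(x$cci)))
  cat(sprintf("  subpattern fallback: %s, refined fallback: %s\n",
              x$subpattern_fallback, x$refined_fallback))
  invisible(x)
}
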