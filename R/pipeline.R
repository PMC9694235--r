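#' Hold-out split with a fixed training count per class
#'
#' Samples `n_train_per_class` subjects per class (uniform, without
#' replacement, seeded) into the training set; everything else is the test
#' set. With reference cohort sizes of 34 AD / 89 MCI / 45 NC and 23 training
#' subjects per class, the test set is 11 AD / 66 MCI / 22 NC.
#'
#' @param cohort Cohort tibble with `subject_id` and `label` columns.
#' @param n_train_per_class Training subjects drawn per class (default 23).
#' @param seed Integer seed.
#' @return The cohort tibble with an added `split` column (`"train"` /
#'   `"test"`).
#' @export
make_holdout <- function(cohort, n_train_per_class = 23, seed = 1L) {
  stopifnot(all(c("subject_id", "label") %in% names(cohort)))
  counts <- table(cohort$label)
  small <- names(counts)[counts < n_train_per_class]
  if (length(small)) {
    abort(sprintf("Class %s has %d subjects, fewer than %d training slots.",
                  small[1], counts[[small[1]]], n_train_per_class))
  }
  old <- .Random.seed_guard(as.integer(seed))
  on.exit(old(), add = TRUE)
  split <- rep("test", nrow(cohort))
  for (cls in levels(factor(cohort$label))) {
    idx <- which(cohort$label == cls)
    split[sample(idx, n_train_per_class)] <- "train"
  }
  dplyr::mutate(cohort, split = split)
}

feature_cols <- function() sprintf("f%02d", 1:42)

# wide matrix (subjects x 42) for one ROI, plus aligned ids and labels
roi_instance_matrix <- function(features, roi) {
  sub <- features[features$roi == roi, , drop = FALSE]
  x <- as.matrix(sub[, feature_cols()])
  rownames(x) <- sub$subject_id
  list(x = x, labels = sub$label, subject_id = sub$subject_id)
}

# deterministic stratified fold assignment
stratified_folds <- function(y, folds, seed) {
  old <- .Random.seed_guard(as.integer(seed))
  on.exit(old(), add = TRUE)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Rank ROIs by single-ROI NEWFM accuracy
#'
#' For every ROI, a NEWFM is fit on that ROI's 42 features with the built-in
#' selection reducing them to `n_keep`; its accuracy is estimated by a seeded
#' stratified cross-validation *within the supplied (training) subjects*, so
#' ranking never touches held-out data. ROIs are ranked by accuracy,
#' descending, ties toward the lower ROI index; the selected feature subset of
#' a full-data fit is recorded per ROI.
#'
#' @param features Long feature tibble (from [extract_features()]), already
#'   restricted to training subjects.
#' @param task Assessment task name (see [assessment_tasks()]).
#' @param n_keep Features kept per ROI (default 20 of 42).
#' @param folds Cross-validation folds (default 5; reduced automatically if a
#'   class is smaller).
#' @param seed Integer seed for fold assignment.
#' @param ... NEWFM hyperparameters passed to [newfm()].
#' @return A `"roi_ranking"` tibble with columns `rank`, `roi`, `accuracy`
#'   and `selected` (list column of feature indices in rank order).
#' @export
rank_rois <- function(features, task, n_keep = 20, folds = 5, seed = 1L,
                      ...) {
  stopifnot(all(c("roi", "label") %in% names(features)))
  rois <- unique(features$roi)
  y_all <- task_labels(features$label[features$roi == rois[1]], task)
  if (length(unique(y_all)) < 2) {
    abort("Both task classes must be present to rank ROIs.")
  }
  folds <- min(folds, min(table(y_all)))

  res <- purrr::map(seq_along(rois), function(i) {
    inst <- roi_instance_matrix(features, rois[i])
    y <- task_labels(inst$labels, task)
    fold <- stratified_folds(y, folds, seed = seed + i)
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      te <- fold == f
      fit <- newfm(inst$x[tr, , drop = FALSE], y[tr], n_select = n_keep, ...)
      correct <- correct + sum(predict(fit, inst$x[te, , drop = FALSE]) == y[te])
    }
    full <- newfm(inst$x, y, n_select = n_keep, ...)
    tibble::tibble(
      roi = rois[i],
      accuracy = correct / length(y),
      selected = list(full$selected_features)
    )
  })
  out <- dplyr::bind_rows(res)
  # accuracy descending, ties by original ROI order
  ord <- order(-out$accuracy, seq_len(nrow(out)))
  out <- out[ord, ]
  out <- dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
  class(out) <- c("roi_ranking", class(out))
  out
}

#' Top-k ROIs of a ranking
#'
#' @param ranking A `"roi_ranking"` (from [rank_rois()]).
#' @param k Number of ROIs to keep (default 16).
#' @return Character vector of the first `k` ROI names in rank order.
#' @export
select_top_rois <- function(ranking, k = 16) {
  if (k > nrow(ranking)) {
    abort(sprintf("Cannot select %d ROIs from a ranking of %d.",
                  k, nrow(ranking)))
  }
  ranking$roi[seq_len(k)]
}

#' Design matrix of selected ROI features
#'
#' Assembles the classifier input: for each chosen ROI (in rank order), the
#' ROI's selected features (in selection order), concatenated into one wide
#' row per subject. With 16 ROIs of 20 features each, this is the 320-wide
#' ZNN input.
#'
#' @param features Long feature tibble.
#' @param ranking A `"roi_ranking"` carrying per-ROI selections.
#' @param rois Character vector of ROIs to include (subset of the ranking).
#' @return List with `x` (subjects x features matrix), `subject_id`, `labels`.
#' @export
roi_design_matrix <- function(features, ranking, rois) {
  missing <- setdiff(rois, ranking$roi)
  if (length(missing)) {
    abort(sprintf("ROIs not in the ranking: %s.",
                  paste(missing, collapse = ", ")))
  }
  parts <- lapply(rois, function(r) {
    inst <- roi_instance_matrix(features, r)
    sel <- ranking$selected[[match(r, ranking$roi)]]
    x <- inst$x[, sel, drop = FALSE]
    colnames(x) <- paste0(r, "_", colnames(x))
    list(x = x, subject_id = inst$subject_id, labels = inst$labels)
  })
  ids <- parts[[1]]$subject_id
  for (p in parts) {
    if (!identical(p$subject_id, ids)) {
      abort("Subjects differ across ROIs; the feature table is malformed.")
    }
  }
  list(x = do.call(cbind, lapply(parts, `[[`, "x")),
       subject_id = ids, labels = parts[[1]]$labels)
}

#' Run one complete one-vs-rest assessment
#'
#' The end-to-end experimental protocol on a cohort: hold-out split, per-ROI
#' feature extraction, ROI ranking on the training split only, top-`n_rois`
#' selection, ZNN training on the concatenated selected features, and
#' layerwise train/test accuracies. Test labels are never visible to feature
#' selection, ROI ranking or training.
#'
#' @param cohort Cohort tibble (`subject_id`, `label`, `series`).
#' @param task Assessment task name.
#' @param layers ZLU counts per layer for the ZNN.
#' @param n_train_per_class Training subjects per class.
#' @param n_rois ROIs kept after ranking.
#' @param n_keep Features kept per ROI.
#' @param density,n_rewires Connectivity graph parameters (see
#'   [extract_roi_features()]).
#' @param folds Cross-validation folds inside [rank_rois()].
#' @param seed Integer seed governing the split, fold assignment and nulls.
#' @param features Optional precomputed feature tibble (skips extraction).
#' @param ... NEWFM hyperparameters passed down to [znn()] and [rank_rois()].
#' @return A `"znn_assessment"` object: the task, split, ranking, selected
#'   ROIs, fitted model, and an `accuracies` tibble (layer x train/test, in
#'   percent).
#' @export
run_assessment <- function(cohort, task, layers = c(16, 4),
                           n_train_per_class = 23, n_rois = 16, n_keep = 20,
                           density = 0.2, n_rewires = 20, folds = 5,
                           seed = 1L, features = NULL, ...) {
  split <- make_holdout(cohort, n_train_per_class, seed = seed)
  if (is.null(features)) {
    features <- extract_features(cohort, density = density,
                                 n_rewires = n_rewires, seed = seed)
  }
  features <- dplyr::left_join(features,
                               split[, c("subject_id", "split")],
                               by = "subject_id")
  train_feats <- features[features$split == "train", , drop = FALSE]

  ranking <- rank_rois(train_feats, task, n_keep = n_keep, folds = folds,
                       seed = seed, ...)
  rois <- select_top_rois(ranking, n_rois)

  train_dm <- roi_design_matrix(train_feats, ranking, rois)
  test_feats <- features[features$split == "test", , drop = FALSE]
  test_dm <- roi_design_matrix(test_feats, ranking, rois)

  y_train <- task_labels(train_dm$labels, task)
  y_test <- task_labels(test_dm$labels, task)

  model <- znn(train_dm$x, y_train, layers = layers, ...)

  acc_train <- layer_accuracies(model, train_dm$x, y_train)
  acc_test <- layer_accuracies(model, test_dm$x, y_test)
  accuracies <- tibble::tibble(
    layer = acc_train$layer,
    train = 100 * acc_train$accuracy,
    test = 100 * acc_test$accuracy
  )

  structure(list(
    task = task,
    layers = model$layer_config,
    split = split[, c("subject_id", "label", "split")],
    ranking = ranking,
    selected_rois = rois,
    model = model,
    accuracies = accuracies,
    train_accuracy = accuracies$train[nrow(accuracies)],
    test_accuracy = accuracies$test[nrow(accuracies)]
  ), class = "znn_assessment")
}

#' @export
print.znn_assessment <- function(x, ...) {
  cat(sprintf("ZNN assessment %s: ZLU layers [%s], %d ROIs\n", x$task,
              paste(x$layers, collapse = ", "), length(x$selected_rois)))
  print(as.data.frame(x$accuracies), row.names = FALSE)
  invisible(x)
}

#' Discriminative ROIs shared by several assessment tasks
#'
#' Intersects per-task ROI selections (e.g. the 16 top-ranked ROIs of each
#' one-vs-rest task); ROIs present in every list are the task-overarching
#' discriminative regions. Order follows the first list.
#'
#' @param rankings A list of character vectors of ROI names, or a tibble with
#'   `task` and `roi` columns (one list per task).
#' @return Character vector of ROIs common to all lists.
#' @examples
#' roi_overlap(split(aal90_task_rois()$roi, aal90_task_rois()$task))
#' @export
roi_overlap <- function(rankings) {
  if (is.data.frame(rankings)) {
    stopifnot(all(c("task", "roi") %in% names(rankings)))
    rankings <- split(rankings$roi, rankings$task)
  }
  if (!is.list(rankings) || length(rankings) < 2 ||
      !all(vapply(rankings, is.character, logical(1)))) {
    abort("`rankings` must be a list of at least two character ROI lists.")
  }
  Reduce(intersect, rankings)
}
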