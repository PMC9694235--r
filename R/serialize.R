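# Model serialization: nested JSON with a format-version field per object.
# Numbers are written with 17 significant digits so a write/read cycle
# round-trips the model bit-exactly.

newfm_to_list <- function(model) {
  list(
    format = "zoomnn/newfm@1",
    n_features = model$n_features,
    feature_names = model$feature_names,
    m = model$m,
    centers = as.numeric(model$centers),
    weights = as.numeric(model$weights),
    feature_ranges = as.numeric(model$feature_ranges),
    selected_features = model$selected_features,
    hyperparams = model$hyperparams,
    epochs_run = model$epochs_run,
    train_accuracy = model$train_accuracy,
    accuracy_history = model$accuracy_history
  )
}

list_to_newfm <- function(x) {
  check_format(x, "zoomnn/newfm@1")
  p <- as.integer(x$n_features)
  m <- as.integer(x$m)
  structure(list(
    n_features = p,
    feature_names = unlist(x$feature_names),
    m = m,
    centers = array(as.numeric(x$centers), dim = c(m, 2, p)),
    weights = array(as.numeric(x$weights), dim = c(m, 2, p)),
    feature_ranges = matrix(as.numeric(x$feature_ranges), nrow = 2),
    selected_features = as.integer(unlist(x$selected_features)),
    hyperparams = x$hyperparams,
    epochs_run = as.integer(x$epochs_run),
    train_accuracy = as.numeric(x$train_accuracy),
    accuracy_history = as.numeric(unlist(x$accuracy_history))
  ), class = "newfm")
}

zlu_to_list <- function(model) {
  list(
    format = "zoomnn/zlu@1",
    standard = newfm_to_list(model$standard),
    subpattern = if (model$subpattern_fallback) NULL else
      newfm_to_list(model$subpattern),
    refined = if (model$refined_fallback) NULL else
      newfm_to_list(model$refined),
    subpattern_fallback = model$subpattern_fallback,
    refined_fallback = model$refined_fallback,
    mi = model$mi,
    cci = model$cci,
    n_features = model$n_features
  )
}

list_to_zlu <- function(x) {
  check_format(x, "zoomnn/zlu@1")
  standard <- list_to_newfm(x$standard)
  sub <- if (isTRUE(x$subpattern_fallback)) standard else
    list_to_newfm(x$subpattern)
  ref <- if (isTRUE(x$refined_fallback)) standard else
    list_to_newfm(x$refined)
  structure(list(
    standard = standard, subpattern = sub, refined = ref,
    subpattern_fallback = isTRUE(x$subpattern_fallback),
    refined_fallback = isTRUE(x$refined_fallback),
    mi = as.integer(unlist(x$mi)), cci = as.integer(unlist(x$cci)),
    n_features = as.integer(x$n_features)
  ), class = "zlu")
}

znn_to_list <- function(model) {
  list(
    format = "zoomnn/znn@1",
    n_features = model$n_features,
    layer_config = model$layer_config,
    input_split = model$input_split,
    layers = lapply(model$layers, function(layer) lapply(layer, zlu_to_list)),
    readouts = lapply(model$readouts, newfm_to_list),
    output = newfm_to_list(model$output),
    hyperparams = model$hyperparams,
    train_accuracy = model$train_accuracy
  )
}

list_to_znn <- function(x) {
  check_format(x, "zoomnn/znn@1")
  structure(list(
    n_features = as.integer(x$n_features),
    layer_config = as.integer(unlist(x$layer_config)),
    input_split = lapply(x$input_split, function(i) as.integer(unlist(i))),
    layers = lapply(x$layers, function(layer) lapply(layer, list_to_zlu)),
    readouts = lapply(x$readouts, list_to_newfm),
    output = list_to_newfm(x$output),
    hyperparams = x$hyperparams,
    train_accuracy = as.numeric(x$train_accuracy)
  ), class = "znn")
}

check_format <- function(x, expected) {
  if (is.null(x$format) || !identical(as.character(x$format), expected)) {
    abort(sprintf(
      "Model format-version mismatch: expected '%s', found '%s'.",
      expected, if (is.null(x$format)) "<none>" else as.character(x$format)))
  }
}

model_to_list <- function(model) {
  if (inherits(model, "newfm")) return(newfm_to_list(model))
  if (inherits(model, "zlu")) return(zlu_to_list(model))
  if (inherits(model, "znn")) return(znn_to_list(model))
  abort("`model` must be a newfm, zlu or znn object.")
}

#' Write a fitted model to JSON
#'
#' Serializes a [newfm()], [zlu()] or [znn()] model to a nested JSON document
#' with a format-version field; numbers are written at full precision so the
#' model round-trips bit-exactly through [read_model()].
#'
#' @param model A fitted `newfm`, `zlu` or `znn` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path JSON file path.
#' @return The deserialized model object.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("Model file '%s' not found.", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  fmt <- as.character(x$format %||% "")
  switch(fmt,
    "zoomnn/newfm@1" = list_to_newfm(x),
    "zoomnn/zlu@1" = list_to_zlu(x),
    "zoomnn/znn@1" = list_to_znn(x),
    abort(sprintf("Unrecognized model format-version '%s' in '%s'.",
                  if (nzchar(fmt)) fmt else "<none>", path))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
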