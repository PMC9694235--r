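#' Write a cohort to disk as delimited text
#'
#' One tab-separated table per subject (first column `roi`, remaining columns
#' `t001..tNNN`), a `manifest.tsv` (columns `subject_id`, `label`, `path`
#' relative to the directory), and — when a spec is supplied — the generating
#' spec as `cohort_spec.yaml`.
#'
#' @param cohort Cohort tibble (`subject_id`, `label`, `series`).
#' @param dir Output directory; created if missing.
#' @param spec Optional [cohort_spec()] to record alongside the data.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("Cannot create directory '%s'.", dir))
  paths <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    mat <- cohort$series[[i]]
    df <- data.frame(roi = rownames(mat), mat, check.names = FALSE)
    colnames(df) <- c("roi", sprintf("t%03d", seq_len(ncol(mat))))
    paths[i] <- paste0(cohort$subject_id[i], ".tsv")
    write.table(df, file.path(dir, paths[i]), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  manifest <- data.frame(subject_id = cohort$subject_id,
                         label = as.character(cohort$label),
                         path = paths)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(spec)) {
    s <- unclass(spec)
    s$n_per_class <- as.list(s$n_per_class)
    s$spectral_profile <- as.list(s$spectral_profile)
    s$connectivity_profile <- as.list(s$connectivity_profile)
    yaml::write_yaml(s, file.path(dir, "cohort_spec.yaml"))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.tsv` and the subject tables.
#' @return A cohort tibble (`subject_id`, `label` factor, `series` list of
#'   matrices).
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) {
    abort(sprintf("Expected manifest file '%s' not found.", manifest_path))
  }
  manifest <- read.delim(manifest_path, stringsAsFactors = FALSE)
  series <- lapply(manifest$path, function(p) {
    f <- file.path(dir, p)
    if (!file.exists(f)) abort(sprintf("Expected subject file '%s' not found.", f))
    df <- read.delim(f, stringsAsFactors = FALSE, check.names = FALSE)
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- df$roi
    dimnames(mat) <- list(df$roi, NULL)
    mat
  })
  tibble::tibble(
    subject_id = manifest$subject_id,
    label = factor(manifest$label, levels = unique(manifest$label)),
    series = series
  )
}
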