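#' The three one-vs-rest AD assessment tasks
#'
#' Assessments are binary one-vs-rest pairings of the three subject classes:
#' `A-NM` (AD vs pooled NC+MCI), `N-AM` (NC vs pooled AD+MCI) and `M-AN`
#' (MCI vs pooled AD+NC). Together they partition the label space.
#'
#' @return A tibble with columns `task` and `positive` (the positive class).
#' @export
assessment_tasks <- function() {
  tibble::tibble(
    task = c("A-NM", "N-AM", "M-AN"),
    positive = c("AD", "NC", "MCI")
  )
}

#' Binary labels for a one-vs-rest assessment task
#'
#' @param labels Vector (or factor) of class labels (`AD`, `MCI`, `NC`).
#' @param task Task name: `"A-NM"`, `"N-AM"` or `"M-AN"`.
#' @return Integer 0/1 vector; 1 marks the task's positive class.
#' @examples
#' task_labels(c("AD", "MCI", "NC"), "A-NM") # 1 0 0
#' @export
task_labels <- function(labels, task) {
  tasks <- assessment_tasks()
  if (!task %in% tasks$task) {
    abort(sprintf("Unknown task '%s'; expected one of %s.", task,
                  paste(tasks$task, collapse = ", ")))
  }
  pos <- tasks$positive[tasks$task == task]
  as.integer(as.character(labels) == pos)
}
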