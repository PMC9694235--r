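#' Specify a synthetic rs-fMRI cohort
#'
#' Defines the statistical structure of a simulated resting-state fMRI cohort
#' shaped like an AD/MCI/NC atlas-ROI study: each subject is an
#' `n_rois x n_timepoints` matrix of ROI-representative signals. Per-ROI base
#' signals are standardized AR(1) processes. Class information enters two
#' ways, matching what the downstream features can see:
#'
#' * **Spectral effect** — a slow sinusoid (period `period` timepoints,
#'   subject-random phase) added to the `informative_rois`, with amplitude
#'   `spectral_effect * spectral_profile[class]`. Its energy lands in the
#'   low-frequency Haar wavelet bands.
#' * **Connectivity effect** — a latent AR(1) factor shared by the ROIs in
#'   `connectivity_block`, mixed in with weight
#'   `sqrt(connectivity_effect * connectivity_profile[class])`, so the
#'   within-block correlation equals `connectivity_effect *
#'   connectivity_profile[class]`. The factor construction makes the implied
#'   correlation matrix positive semidefinite for any admissible effect; an
#'   effect of 1 or more is rejected.
#'
#' @param n_per_class Named counts per class, default `c(AD = 34, MCI = 89,
#'   NC = 45)`.
#' @param n_rois Number of atlas ROIs (default 90).
#' @param n_timepoints Timepoints per ROI series (default 140).
#' @param informative_rois ROI indices carrying the class-dependent sinusoid.
#' @param spectral_effect Base sinusoid amplitude (signal units).
#' @param connectivity_effect Base within-block correlation in `[0, 1)`.
#' @param connectivity_block ROI indices sharing the latent factor; defaults
#'   to `informative_rois`.
#' @param noise_sd Marginal standard deviation of the AR(1) background.
#' @param ar_coef AR(1) coefficient of the background and latent processes.
#' @param period Sinusoid period in timepoints.
#' @param spectral_profile,connectivity_profile Named per-class multipliers of
#'   the two effects.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec.
#' @return An object of class `"cohort_spec"`.
#' @examples
#' spec <- cohort_spec(n_per_class = c(AD = 5, MCI = 5, NC = 5), n_rois = 10)
#' cohort <- simulate_cohort(spec)
#' cohort
#' @seealso [simulate_cohort()], [write_cohort()]
#' @export
cohort_spec <- function(n_per_class = c(AD = 34, MCI = 89, NC = 45),
                        n_rois = 90, n_timepoints = 140,
                        informative_rois = 1:10, spectral_effect = 1,
                        connectivity_effect = 0.3,
                        connectivity_block = informative_rois,
                        noise_sd = 1, ar_coef = 0.3, period = 32,
                        spectral_profile = c(AD = 1, MCI = 0.5, NC = 0),
                        connectivity_profile = c(AD = 1, MCI = 0.5, NC = 0),
                        seed = 1L) {
  if (is.null(names(n_per_class)) || any(!nzchar(names(n_per_class)))) {
    abort("`n_per_class` must be a named vector of class counts.")
  }
  if (any(n_per_class < 1) || n_rois < 1 || n_timepoints < 1) {
    abort("All counts must be positive.")
  }
  informative_rois <- sort(unique(as.integer(informative_rois)))
  connectivity_block <- sort(unique(as.integer(connectivity_block)))
  if (length(informative_rois) &&
      (min(informative_rois) < 1 || max(informative_rois) > n_rois)) {
    abort("`informative_rois` must lie in 1..n_rois.")
  }
  if (length(connectivity_block) &&
      (min(connectivity_block) < 1 || max(connectivity_block) > n_rois)) {
    abort("`connectivity_block` must lie in 1..n_rois.")
  }
  if (noise_sd <= 0) abort("`noise_sd` must be positive.")
  if (abs(ar_coef) >= 1) abort("`ar_coef` must lie in (-1, 1).")
  if (connectivity_effect < 0) abort("`connectivity_effect` must be >= 0.")
  classes <- names(n_per_class)
  for (nm in c("spectral_profile", "connectivity_profile")) {
    prof <- get(nm)
    if (!all(classes %in% names(prof))) {
      abort(sprintf("`%s` must name every class in `n_per_class`.", nm))
    }
  }
  rho <- connectivity_effect * connectivity_profile[classes]
  if (any(rho >= 1)) {
    bad <- classes[which.max(rho)]
    abort(sprintf(paste0(
      "connectivity_effect * profile = %.3f for class %s makes the implied ",
      "correlation of ROI block [%s] non-positive-semidefinite ",
      "(within-block correlation must stay below 1)."),
      max(rho), bad, paste(range(connectivity_block), collapse = "..")))
  }

  structure(list(
    n_per_class = n_per_class, n_rois = as.integer(n_rois),
    n_timepoints = as.integer(n_timepoints),
    informative_rois = informative_rois, spectral_effect = spectral_effect,
    connectivity_effect = connectivity_effect,
    connectivity_block = connectivity_block, noise_sd = noise_sd,
    ar_coef = ar_coef, period = period,
    spectral_profile = spectral_profile[classes],
    connectivity_profile = connectivity_profile[classes],
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic rs-fMRI cohort spec\n")
  cat(sprintf("  %s; %d ROIs x %d timepoints\n",
              paste(sprintf("%s=%d", names(x$n_per_class), x$n_per_class),
                    collapse = ", "),
              x$n_rois, x$n_timepoints))
  cat(sprintf("  spectral effect %.3g on %d ROIs, connectivity effect %.3g on %d ROIs, seed %d\n",
              x$spectral_effect, length(x$informative_rois),
              x$connectivity_effect, length(x$connectivity_block), x$seed))
  invisible(x)
}

# standardized AR(1): phi-recursive filter over unit innovations, burn-in
# dropped, marginal variance ~ 1
ar1_series <- function(n, phi, burn = 20L) {
  e <- rnorm(n + burn) * sqrt(1 - phi^2)
  x <- as.numeric(stats::filter(e, phi, method = "recursive"))
  x[(burn + 1):(burn + n)]
}

#' Simulate a synthetic rs-fMRI cohort
#'
#' Draws every subject of the spec in a fixed order from a single RNG stream
#' seeded by `spec$seed`, so an identical spec reproduces a bit-identical
#' cohort.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `subject_id`, `label` (factor over the
#'   spec's classes) and `series` (list of `n_rois x n_timepoints` matrices
#'   with `ROI_###` rownames).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  classes <- names(spec$n_per_class)
  tt <- seq_len(spec$n_timepoints)
  roi_names <- sprintf("ROI_%03d", seq_len(spec$n_rois))
  in_block <- seq_len(spec$n_rois) %in% spec$connectivity_block
  informative <- seq_len(spec$n_rois) %in% spec$informative_rois

  old <- .Random.seed_guard(spec$seed)
  on.exit(old(), add = TRUE)

  rows <- list()
  for (cls in classes) {
    amp <- spec$spectral_effect * spec$spectral_profile[[cls]]
    rho <- spec$connectivity_effect * spec$connectivity_profile[[cls]]
    w <- sqrt(rho)
    for (s in seq_len(spec$n_per_class[[cls]])) {
      g <- ar1_series(spec$n_timepoints, spec$ar_coef)
      mat <- matrix(0, spec$n_rois, spec$n_timepoints,
                    dimnames = list(roi_names, NULL))
      for (r in seq_len(spec$n_rois)) {
        base <- ar1_series(spec$n_timepoints, spec$ar_coef)
        sig <- if (in_block[r]) sqrt(1 - w^2) * base + w * g else base
        sig <- sig * spec$noise_sd
        if (informative[r] && amp != 0) {
          phase <- runif(1, 0, 2 * pi)
          sig <- sig + amp * sin(2 * pi * tt / spec$period + phase)
        }
        mat[r, ] <- sig
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = sprintf("%s_%03d", cls, s),
        label = cls,
        series = list(mat)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$label <- factor(out$label, levels = classes)
  out
}

# seed the session RNG and return a restorer for the previous state
.Random.seed_guard <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}

#' Simulate a voxel set around an ROI-representative signal
#'
#' Real atlas ROIs hold 2000-3000 voxels whose per-timepoint average is used
#' as the ROI's representative signal. This generator produces such a voxel
#' set: each voxel is the ROI signal plus independent Gaussian noise, so the
#' voxel average converges to the ROI signal as the voxel count grows.
#'
#' @param roi_signal Numeric ROI time series.
#' @param n_voxels Number of voxels (>= 1).
#' @param voxel_noise_sd Standard deviation of the per-voxel noise.
#' @param seed Integer seed.
#' @return An `n_voxels x length(roi_signal)` matrix, one voxel per row.
#' @seealso [average_of_voxels()]
#' @export
generate_voxel_set <- function(roi_signal, n_voxels, voxel_noise_sd = 1,
                               seed = 1L) {
  n_voxels <- as.integer(n_voxels)
  if (is.na(n_voxels) || n_voxels < 1) {
    abort("`n_voxels` must be a positive count.")
  }
  roi_signal <- as.numeric(roi_signal)
  old <- .Random.seed_guard(as.integer(seed))
  on.exit(old(), add = TRUE)
  noise <- matrix(rnorm(n_voxels * length(roi_signal), sd = voxel_noise_sd),
                  nrow = n_voxels)
  sweep(noise, 2, roi_signal, `+`)
}
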