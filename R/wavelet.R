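#' Average-of-voxels (AOV) representative signal
#'
#' Reduces a set of voxel time series to the ROI's representative signal: the
#' per-timepoint arithmetic mean over voxels.
#'
#' @param voxels A matrix (voxels in rows) or a list of equal-length numeric
#'   series.
#' @return Numeric series of per-timepoint means.
#' @examples
#' average_of_voxels(rbind(c(1, 3), c(3, 5))) # 2 4
#' @export
average_of_voxels <- function(voxels) {
  if (is.list(voxels) && !is.data.frame(voxels)) {
    if (length(voxels) == 0) abort("`voxels` must contain at least one series.")
    lens <- lengths(voxels)
    if (length(unique(lens)) != 1) {
      abort("All voxel series must have equal length.")
    }
    voxels <- do.call(rbind, lapply(voxels, as.numeric))
  }
  voxels <- as.matrix(voxels)
  if (nrow(voxels) == 0 || ncol(voxels) == 0) {
    abort("`voxels` must contain at least one series.")
  }
  colMeans(voxels)
}

#' Orthonormal Haar discrete wavelet transform
#'
#' Recursive orthonormal Haar analysis: at each level, adjacent pairs of the
#' current approximation map to `a = (x1 + x2) / sqrt(2)` and
#' `d = (x1 - x2) / sqrt(2)`. The sqrt(2) normalization makes the transform
#' energy-preserving (Parseval), so coefficient energies are directly
#' comparable across levels.
#'
#' @param x Numeric series; its length must be divisible by `2^levels`.
#' @param levels Number of decomposition levels.
#' @return A list with `d`, a list of detail coefficient vectors `d1..d<levels>`
#'   (finest first), and `a`, the final approximation coefficients.
#' @examples
#' haar_transform(c(1, -1), 1) # a = 0, d = sqrt(2)
#' @export
haar_transform <- function(x, levels) {
  x <- as.numeric(x)
  levels <- as.integer(levels)
  if (levels < 1) abort("`levels` must be a positive count.")
  n <- length(x)
  if (n %% 2^levels != 0) {
    abort(sprintf(
      "series length %d is not divisible by 2^%d; truncate or pad first.",
      n, levels))
  }
  d <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    odd <- a[seq(1, length(a), by = 2)]
    even <- a[seq(2, length(a), by = 2)]
    d[[l]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  names(d) <- paste0("d", seq_len(levels))
  list(d = d, a = a)
}

#' The 32 Haar wavelet features of an ROI time series
#'
#' Truncates the series to its first 128 timepoints (the largest power of two
#' inside a 140-point acquisition), runs a 4-level orthonormal Haar transform,
#' and returns the level-3 details (16), level-4 details (8) and level-4
#' approximation (8) — exactly 32 coefficients capturing the low-frequency
#' structure of the signal.
#'
#' @param x Numeric series of length >= 128.
#' @return Named numeric vector of length 32 (`d3_01..d3_16`, `d4_01..d4_08`,
#'   `a4_01..a4_08`).
#' @examples
#' f <- hwt_features(rep(5, 140))
#' f[["a4_01"]] # 5 * 2^2 = 20
#' @export
hwt_features <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 128) {
    abort(sprintf("series length %d < 128; cannot extract wavelet features.",
                  length(x)))
  }
  ht <- haar_transform(x[1:128], 4)
  out <- c(ht$d[["d3"]], ht$d[["d4"]], ht$a)
  names(out) <- c(sprintf("d3_%02d", 1:16), sprintf("d4_%02d", 1:8),
                  sprintf("a4_%02d", 1:8))
  out
}
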