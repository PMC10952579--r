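#' Gaussian-smoothed histogram (kernel density on a fixed grid)
#'
#' Density estimate of a sample evaluated at evenly spaced bin centers over a
#' stated range, using a Gaussian kernel with Silverman's rule-of-thumb
#' bandwidth by default, renormalized to integrate to 1 over the range.
#'
#' @param samples numeric vector (n >= 2, finite).
#' @param range length-2 range of the grid; default the sample range.
#' @param bins number of grid points (default 200).
#' @param bw Gaussian kernel bandwidth; default Silverman
#'   (\code{stats::bw.nrd0}), with a tiny floor so constant samples yield a
#'   single sharp peak at their value.
#' @return a \code{SmoothedHistogram}: list with \code{centers},
#'   \code{density} (non-negative, integrates to 1 over the range) and
#'   \code{bw}.
#' @export
smoothed_histogram <- function(samples, range = NULL, bins = 200L, bw = NULL) {
  if (length(samples) < 2L) stop("smoothed_histogram(): need at least 2 samples")
  if (!all(is.finite(samples))) stop("smoothed_histogram(): non-finite samples")
  if (is.null(range)) range <- base::range(samples)
  if (diff(range) <= 0) {
    if (stats::sd(samples) == 0) {
      range <- samples[1] + c(-1, 1)   # degenerate input: unit window
    } else {
      stop("smoothed_histogram(): zero-width range")
    }
  }
  if (is.null(bw)) {
    bw <- if (stats::sd(samples) > 0) stats::bw.nrd0(samples)
          else diff(range) / 100
  }
  d <- stats::density(samples, bw = bw, from = range[1], to = range[2],
                      n = bins)
  step <- diff(d$x[1:2])
  mass <- sum(d$y) * step
  y <- if (mass > 0) d$y / mass else d$y
  structure(list(centers = d$x, density = y, bw = bw, range = range),
            class = "SmoothedHistogram")
}

#' Locate the modes of a smoothed histogram
#'
#' Interior strict local maxima of the density curve, optionally filtered by
#' a minimum height relative to the global maximum.
#'
#' @param sh a \code{SmoothedHistogram}.
#' @param min_rel_height discard maxima below this fraction of the global
#'   maximum (default 0, keep all).
#' @return numeric vector of mode locations (bin centers).
#' @export
find_modes <- function(sh, min_rel_height = 0) {
  y <- sh$density
  y[y < 1e-12 * max(y)] <- 0    # suppress FFT tail noise of the KDE
  # plateau-aware: a mode is a maximal run of equal values strictly above
  # both neighbors (grid ties, e.g. a peak split across two bins, count once)
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  idx <- integer(0)
  for (j in seq_len(k)) {
    if (j == 1L || j == k) next                   # boundary runs excluded
    if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L]) {
      idx <- c(idx, as.integer((starts[j] + ends[j]) %/% 2))
    }
  }
  idx <- idx[y[idx] >= min_rel_height * max(y)]
  sh$centers[idx]
}
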