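#' Discretize ROI intensities into equal-width gray levels
#'
#' Texture matrices operate on a small number of gray levels rather than raw
#' intensities. Levels are equal-width bins spanning the per-ROI min-max
#' (which also makes every discretization-based feature invariant under
#' positive affine rescaling of the intensities). The maximum intensity maps
#' to level `n_bins`; a constant ROI maps every voxel to level 1.
#'
#' @param roi an `roi_voxels` object.
#' @param n_bins number of gray levels (>= 2); 32 is the package default.
#' @return A `discretized_roi`: `levels` (bounding-box grid of integer levels,
#'   `NA` outside the mask), `n_bins`, `bin_edges`, and the per-level in-mask
#'   histogram `counts`.
#' @export
discretize <- function(roi, n_bins = 32L) {
  stopifnot(inherits(roi, "roi_voxels"))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  lo <- min(roi$values)
  hi <- max(roi$values)
  grid <- roi$grid
  if (hi == lo) {
    lev <- grid
    lev[!is.na(lev)] <- 1
    edges <- lo + c(0, seq_len(n_bins))  # arbitrary unit-width edges
  } else {
    edges <- seq(lo, hi, length.out = n_bins + 1L)
    width <- (hi - lo) / n_bins
    lev <- floor((grid - lo) / width) + 1
    lev[lev > n_bins] <- n_bins  # the maximum closes the top bin
  }
  lev <- array(as.integer(lev), dim = dim(grid))
  structure(
    list(
      levels = lev,
      n_bins = n_bins,
      bin_edges = edges,
      counts = tabulate(lev[!is.na(lev)], nbins = n_bins),
      n_voxels = roi$n_voxels
    ),
    class = "discretized_roi"
  )
}

#' First-order (histogram) intensity features
#'
#' The 14 features computed from the in-mask intensity histogram: mean,
#' median, minimum, maximum, range, variance, standard deviation, mean
#' absolute deviation, root mean square, energy, skewness, excess kurtosis,
#' histogram entropy and histogram uniformity. Variance (and the moments
#' built on it) uses the population (1/N) form; kurtosis is excess kurtosis;
#' entropy/uniformity are computed on the `n_bins`-level discretized
#' histogram with entropy in bits. Skewness and kurtosis of a constant ROI
#' are defined as 0.
#'
#' @param roi an `roi_voxels` object with at least 27 voxels.
#' @param n_bins gray levels used for the entropy/uniformity histogram.
#' @return Named numeric vector of length 14.
#' @export
intensity_features <- function(roi, n_bins = 32L) {
  x <- roi$values
  if (length(x) == 0L) stop("empty ROI: no in-mask voxels")
  n <- length(x)
  mu <- mean(x)
  v <- sum((x - mu)^2) / n
  s <- sqrt(v)
  skew <- if (s > 0) sum((x - mu)^3) / n / s^3 else 0
  kurt <- if (s > 0) sum((x - mu)^4) / n / s^4 - 3 else 0
  p <- discretize(roi, n_bins)$counts / n
  p_pos <- p[p > 0]
  c(
    Mean = mu,
    Median = stats::median(x),
    Minimum = min(x),
    Maximum = max(x),
    Range = max(x) - min(x),
    Variance = v,
    StandardDeviation = s,
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RootMeanSquare = sqrt(mean(x^2)),
    Energy = sum(x^2),
    Skewness = skew,
    Kurtosis = kurt,
    Entropy = -sum(p_pos * log2(p_pos)),
    Uniformity = sum(p^2)
  )
}
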