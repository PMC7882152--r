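#' One-level 3D stationary Haar wavelet decomposition
#'
#' Undecimated (stationary) transform: each axis is filtered with the Haar
#' low-pass (l = (1, 1)/sqrt(2)) or high-pass (h = (1, -1)/sqrt(2)) filter
#' under periodic boundary handling, without downsampling, so every subband
#' lives on the original voxel grid and the original ROI mask applies
#' unchanged. Subband names follow the axis order (x, y, z): `LLH` means
#' low-pass along x and y, high-pass along z.
#'
#' @param volume an `image_volume` (every axis must be at least the filter
#'   length, 2).
#' @return Named list of 8 `image_volume`s in the order LLL, LLH, LHL, LHH,
#'   HLL, HLH, HHL, HHH.
#' @export
wavelet_subbands <- function(volume) {
  x <- volume$data
  dm <- dim(x)
  if (any(dm < 2L)) stop("every axis must be >= 2 voxels for the Haar filter")
  s <- 1 / sqrt(2)
  shift1 <- function(a, axis) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[axis]] <- c(seq_len(dm[axis])[-1], 1L)  # periodic shift by one
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  filt <- function(a, axis, kind) {
    b <- shift1(a, axis)
    if (kind == "L") (a + b) * s else (a - b) * s
  }
  bands <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  out <- lapply(bands, function(code) {
    ks <- strsplit(code, "")[[1]]
    a <- filt(x, 1L, ks[1])
    a <- filt(a, 2L, ks[2])
    a <- filt(a, 3L, ks[3])
    image_volume(a, spacing = volume$spacing, subject_id = volume$subject_id)
  })
  names(out) <- bands
  out
}
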