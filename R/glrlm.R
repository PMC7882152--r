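#' Gray-level run-length matrix for one direction
#'
#' A run is a maximal sequence of in-mask voxels with the same discretized
#' level along the lattice direction; runs are broken by mask boundaries (a
#' hole in the mask splits a run, it is never bridged). The bounding-box grid
#' is decomposed into lattice lines parallel to the direction; runs are read
#' off each line with absent voxels acting as separators.
#'
#' @param disc a `discretized_roi`.
#' @param direction integer offset (dx, dy, dz), one of the 13 unique 3D
#'   directions.
#' @return A `texture_matrix` of kind `"GLRLM"`: `matrix` (n_levels x
#'   max_run_length counts), `n_runs`, `direction`.
#' @export
glrlm <- function(disc, direction) {
  stopifnot(inherits(disc, "discretized_roi"))
  d <- as.integer(direction)
  lev <- disc$levels
  dm <- dim(lev)
  co <- arrayInd(seq_along(lev), dm)
  tpos <- as.vector(co %*% d)        # strictly increasing along the line
  d2 <- sum(d * d)
  # integer line id: component of the coordinate orthogonal to the direction
  perp <- co * d2 - tpos %*% t(d)
  K <- 2 * max(abs(perp)) + 2  # collision-free base for encoding the id
  li <- (perp[, 1] * K + perp[, 2]) * K + perp[, 3]
  ord <- order(li, tpos)
  lv <- as.vector(lev)[ord]
  lo <- li[ord]
  n <- length(lv)
  # run breaks: new line, or level change (NA-safe); consecutive cells within
  # a line are always lattice-adjacent because every bbox cell is enumerated
  same_line <- c(FALSE, lo[-1] == lo[-n])
  same_lev <- c(FALSE, !is.na(lv[-1]) & !is.na(lv[-n]) & lv[-1] == lv[-n])
  grp <- cumsum(!(same_line & same_lev))
  valid <- !is.na(lv)
  run_len <- tabulate(grp[valid])
  first <- !duplicated(grp[valid])
  run_lev <- lv[valid][first]
  run_len <- run_len[run_len > 0L]
  stopifnot(length(run_len) == length(run_lev))
  lmax <- max(1L, max(lev, na.rm = TRUE))
  maxlen <- max(1L, run_len)
  mat <- matrix(0, lmax, maxlen)
  tab <- tabulate((run_lev - 1L) * maxlen + run_len, nbins = lmax * maxlen)
  mat <- matrix(tab, lmax, maxlen, byrow = TRUE)
  structure(
    list(kind = "GLRLM", matrix = mat, n_runs = sum(mat),
         direction = d, empty = sum(mat) == 0L),
    class = "texture_matrix"
  )
}

# features of one run-length count matrix r(g, l)
.glrlm_features_one <- function(R) {
  nr <- sum(R)
  np <- sum(sweep(R, 2, seq_len(ncol(R)), "*"))  # voxels covered by runs
  g <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  l <- matrix(seq_len(ncol(R)), nrow(R), ncol(R), byrow = TRUE)
  rg <- rowSums(R)
  rl <- colSums(R)
  c(
    ShortRunEmphasis = sum(R / l^2) / nr,
    LongRunEmphasis = sum(R * l^2) / nr,
    GrayLevelNonuniformity = sum(rg^2) / nr,
    RunLengthNonuniformity = sum(rl^2) / nr,
    RunPercentage = nr / np,
    LowGrayLevelRunEmphasis = sum(R / g^2) / nr,
    HighGrayLevelRunEmphasis = sum(R * g^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(R / (g^2 * l^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(R * g^2 / l^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(R * l^2 / g^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(R * g^2 * l^2) / nr
  )
}

#' The 11 GLRLM texture features
#'
#' The classical run-length set: SRE, LRE, GLN, RLN, run percentage, low/high
#' gray-level run emphasis, and the four joint short/long x low/high
#' emphases. Computed per direction and averaged over the 13 unique 3D
#' directions (every direction of a non-empty ROI carries at least one run).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 11.
#' @export
glrlm_features <- function(disc, directions = texture_directions()) {
  per_dir <- list()
  for (r in seq_len(nrow(directions))) {
    tm <- glrlm(disc, directions[r, ])
    if (tm$empty) next
    per_dir[[length(per_dir) + 1L]] <- .glrlm_features_one(tm$matrix)
  }
  if (length(per_dir) == 0L) stop("no direction yields a run")
  colMeans(do.call(rbind, per_dir))
}
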