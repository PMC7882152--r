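#' The 13 unique 3D lattice directions
#'
#' Offsets (dx, dy, dz) covering every 26-neighbourhood direction up to sign;
#' co-occurrences and runs are symmetric in the direction, so 13 suffice.
#'
#' @return A 13 x 3 integer matrix, one offset per row.
#' @export
texture_directions <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[!(d[, 1] == 0 & d[, 2] == 0 & d[, 3] == 0), , drop = FALSE]
  # keep one of each +/- pair: first nonzero component positive
  keep <- apply(d, 1, function(v) v[min(which(v != 0))] > 0)
  m <- d[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  rownames(m) <- apply(m, 1, paste, collapse = ",")
  m
}

# shift-aligned index ranges for pairing a voxel with its neighbour at +off
.offset_ranges <- function(n, off) {
  len <- n - abs(off)
  if (len < 1L) return(NULL)
  base <- seq_len(len)
  if (off >= 0L) list(a = base, b = base + off) else list(a = base + abs(off), b = base)
}

#' Gray-level co-occurrence matrix for one direction
#'
#' Counts pairs of discretized levels at lattice offset `direction * distance`
#' where both voxels are in-mask, counts each ordered pair both ways
#' (symmetrization), and normalizes to sum 1 when any pair exists. Directions
#' along which no valid in-mask pair exists are flagged empty and excluded
#' from feature aggregation.
#'
#' @param disc a `discretized_roi`.
#' @param direction integer offset (dx, dy, dz).
#' @param distance lattice step multiplier (default 1).
#' @return A `texture_matrix` of kind `"GLCM"`: `matrix` (n_bins x n_bins,
#'   symmetric, sums to 1 when non-empty), `n_pairs`, `direction`, `empty`.
#' @export
glcm <- function(disc, direction, distance = 1L) {
  stopifnot(inherits(disc, "discretized_roi"))
  off <- as.integer(direction) * as.integer(distance)
  lev <- disc$levels
  dm <- dim(lev)
  ng <- disc$n_bins
  rx <- .offset_ranges(dm[1], off[1])
  ry <- .offset_ranges(dm[2], off[2])
  rz <- .offset_ranges(dm[3], off[3])
  counts <- matrix(0, ng, ng)
  n_pairs <- 0L
  if (!is.null(rx) && !is.null(ry) && !is.null(rz)) {
    a <- lev[rx$a, ry$a, rz$a, drop = FALSE]
    b <- lev[rx$b, ry$b, rz$b, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      av <- a[ok]; bv <- b[ok]
      tab <- tabulate((av - 1L) * ng + bv, nbins = ng * ng)
      m <- matrix(tab, ng, ng, byrow = TRUE)
      counts <- m + t(m)            # symmetrize: each pair counted both ways
      n_pairs <- 2L * length(av)
    }
  }
  # trim to levels 1..max observed: min-max binning always uses the full
  # 1..n_bins range for a non-constant ROI, and a constant ROI yields [[1]]
  lmax <- max(1L, max(lev, na.rm = TRUE))
  counts <- counts[seq_len(lmax), seq_len(lmax), drop = FALSE]
  mat <- if (n_pairs > 0L) counts / n_pairs else counts
  structure(
    list(kind = "GLCM", matrix = mat, n_pairs = n_pairs,
         direction = off, empty = n_pairs == 0L),
    class = "texture_matrix"
  )
}

# features of one normalized GLCM; levels indexed 1..ng
.glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)  # = px by symmetry
  mux <- sum(seq_len(ng) * px)
  muy <- sum(seq_len(ng) * py)
  sdx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # diagonal (difference) and cross-diagonal (sum) marginals
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), numeric(1))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hx <- ent(px); hy <- ent(py); hxy <- ent(P)
  # joint entropies against the independence surrogate p(i)p(j)
  pq <- outer(px, py)
  pos <- P > 0 & pq > 0
  hxy1 <- -sum(P[pos] * log2(pq[pos]))
  pos2 <- pq > 0
  hxy2 <- -sum(pq[pos2] * log2(pq[pos2]))
  da <- sum(k_diff * p_diff)
  denom_imc1 <- max(hx, hy)
  imc1 <- if (denom_imc1 > 0) (hxy - hxy1) / denom_imc1 else 0
  imc2_arg <- 1 - exp(-2 * (hxy2 - hxy))
  imc2 <- if (hxy2 > 0 && imc2_arg > 0) sqrt(imc2_arg) else 0
  corr <- if (sdx > 0 && sdy > 0) (sum(i * j * P) - mux * muy) / (sdx * sdy) else 0
  offdiag <- abs(i - j) > 0
  c(
    Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent(p_diff),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    Dissimilarity = sum(abs(i - j) * P),
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    InverseDifferenceMoment = sum(P / (1 + (i - j)^2)),
    InverseDifferenceMomentNormalized = sum(P / (1 + ((i - j) / ng)^2)),
    InverseDifference = sum(P / (1 + abs(i - j))),
    InverseDifferenceNormalized = sum(P / (1 + abs(i - j) / ng)),
    InverseVariance = sum(P[offdiag] / (i[offdiag] - j[offdiag])^2),
    IMC1 = imc1,
    IMC2 = imc2,
    MaximumProbability = max(P),
    SumAverage = sum(k_sum * p_sum),
    SumEntropy = ent(p_sum)
  )
}

#' The 22 GLCM texture features
#'
#' Each feature is computed per direction on the normalized symmetric
#' co-occurrence matrix and averaged over the non-empty directions (isotropic
#' aggregation at distance 1 over all 13 unique 3D directions). For a
#' degenerate single-level ROI, correlation, IMC1 and IMC2 are defined 0 so
#' constant input stays finite.
#'
#' @param disc a `discretized_roi`.
#' @param directions matrix of offsets, one per row.
#' @param distance lattice step.
#' @return Named numeric vector of length 22.
#' @export
glcm_features <- function(disc, directions = texture_directions(), distance = 1L) {
  per_dir <- list()
  for (r in seq_len(nrow(directions))) {
    tm <- glcm(disc, directions[r, ], distance)
    if (tm$empty) next
    per_dir[[length(per_dir) + 1L]] <- .glcm_features_one(tm$matrix)
  }
  if (length(per_dir) == 0L) stop("no direction yields a valid voxel pair")
  colMeans(do.call(rbind, per_dir))
}
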