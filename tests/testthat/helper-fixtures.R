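# fixtures and independent brute-force oracles used across the suite

# build an roi_voxels object directly from an array (NA = outside the mask),
# bypassing the mask-size validation so tiny hand examples are expressible
make_roi <- function(arr) {
  structure(
    list(values = arr[!is.na(arr)], grid = arr,
         bounding_box = rbind(c(1L, 1L, 1L), dim(arr)),
         n_voxels = sum(!is.na(arr)), roi_name = "toy", subject_id = "toy"),
    class = "roi_voxels"
  )
}

random_roi <- function(dim3 = c(5, 5, 5), p_mask = 0.8, seed = 1) {
  set.seed(seed)
  arr <- array(stats::rnorm(prod(dim3)), dim = dim3)
  arr[stats::runif(length(arr)) > p_mask] <- NA
  if (sum(!is.na(arr)) < 2) arr[1:2] <- stats::rnorm(2)
  make_roi(arr)
}

# brute-force symmetric normalized GLCM: explicit triple loop over voxels
bf_glcm_matrix <- function(lev, off) {
  dm <- dim(lev)
  ng <- max(lev, na.rm = TRUE)
  counts <- matrix(0, ng, ng)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
    if (ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] || kk < 1 || kk > dm[3]) next
    b <- lev[ii, jj, kk]
    if (is.na(b)) next
    counts[a, b] <- counts[a, b] + 1
    counts[b, a] <- counts[b, a] + 1
  }
  if (sum(counts) > 0) counts / sum(counts) else counts
}

# brute-force run enumerator: walk each voxel, start a run only where the
# predecessor along the direction is absent or differently leveled
bf_glrlm_matrix <- function(lev, off) {
  dm <- dim(lev)
  ng <- max(lev, na.rm = TRUE)
  runs <- list()
  inb <- function(i, j, k) i >= 1 && i <= dm[1] && j >= 1 && j <= dm[2] &&
    k >= 1 && k <= dm[3]
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    pi <- i - off[1]; pj <- j - off[2]; pk <- k - off[3]
    prev <- if (inb(pi, pj, pk)) lev[pi, pj, pk] else NA
    if (!is.na(prev) && prev == a) next   # interior of a run
    len <- 1
    ni <- i + off[1]; nj <- j + off[2]; nk <- k + off[3]
    while (inb(ni, nj, nk) && !is.na(lev[ni, nj, nk]) && lev[ni, nj, nk] == a) {
      len <- len + 1
      ni <- ni + off[1]; nj <- nj + off[2]; nk <- nk + off[3]
    }
    runs[[length(runs) + 1]] <- c(a, len)
  }
  rl <- do.call(rbind, runs)
  mat <- matrix(0, ng, max(rl[, 2]))
  for (r in seq_len(nrow(rl))) mat[rl[r, 1], rl[r, 2]] <- mat[rl[r, 1], rl[r, 2]] + 1
  mat
}

# brute-force AUC: pairwise concordance with ties counted 1/2
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# small two-class feature matrix with planted mean-shift features
planted_features <- function(n1 = 37, n0 = 36, p_null = 100, n_planted = 4,
                             effect = 2, seed = 1) {
  set.seed(seed)
  n <- n1 + n0
  X <- matrix(stats::rnorm(n * (p_null + n_planted)), n)
  y <- c(rep(1, n1), rep(0, n0))
  for (j in seq_len(n_planted)) X[y == 1, j] <- X[y == 1, j] + effect
  colnames(X) <- c(sprintf("planted%02d", seq_len(n_planted)),
                   sprintf("null%03d", seq_len(p_null)))
  list(X = as.data.frame(X), y = y,
       labels = ifelse(y == 1, "CHE", "nCHE"),
       planted = sprintf("planted%02d", seq_len(n_planted)))
}

# tiny cohort configuration for imaging-level tests
tiny_cohort <- function(n = 6, rois = c("right_Lc1", "left_PC"),
                        effect_rois = "right_Lc1", shape = c(16, 16, 16),
                        shift = 12, var_ratio = 2.5, smooth_ratio = 1.5,
                        seed = 11) {
  cohort_config(
    n_che = n, n_nche = n, roi_names = rois, effect_rois = effect_rois,
    roi_shape = shape, intensity_shift = shift, variance_ratio = var_ratio,
    smoothness_ratio = smooth_ratio, seed = seed
  )
}
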