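#' Synthetic cohort configuration
#'
#' Defines the two-class study conditions the generator emulates: a CHE
#' (covert hepatic encephalopathy) and an nCHE cirrhotic group with
#' per-subject ROI volumes whose intensity level, variance and spatial
#' texture differ by class in the effect ROIs, plus clinical covariates drawn
#' from the class-conditional distributions observed in such cohorts
#' (venous ammonia, Child-Pugh stage, NCT-A, DST, age, sex, education).
#'
#' Volumes are baseline Gaussian random fields: white noise convolved with an
#' isotropic Gaussian kernel of length `smooth_sigma` voxels. In effect ROIs
#' the CHE class gets `intensity_shift` added to the mean, its voxel standard
#' deviation scaled by `sqrt(variance_ratio)` and its smoothing length scaled
#' by `smoothness_ratio` (the texture knob: co-occurrence and run-length
#' features respond monotonically to spatial autocorrelation).
#'
#' @param n_che,n_nche subjects per class (>= 2 each).
#' @param roi_names mask names; default the 10 bilateral precuneus regions.
#' @param roi_shape voxel dimensions of each per-ROI volume (>= 8 per axis).
#' @param effect_rois subset of `roi_names` carrying the class effects.
#' @param intensity_shift CHE minus nCHE mean intensity, image units.
#' @param variance_ratio CHE / nCHE voxel variance in effect ROIs (> 0).
#' @param smoothness_ratio CHE / nCHE smoothing length in effect ROIs (> 0).
#' @param baseline_mean,baseline_sd background field level and scale
#'   (arbitrary normalized-T1 units).
#' @param smooth_sigma baseline Gaussian smoothing length, voxels.
#' @param clinical_params per-class clinical distributions; see
#'   [default_clinical_params()].
#' @param seed master RNG seed; every per-subject stream derives from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_che = 54L, n_nche = 52L,
                          roi_names = precuneus_rois(),
                          roi_shape = c(24L, 24L, 24L),
                          effect_rois = c("right_PEp", "right_Lc1"),
                          intensity_shift = 5,
                          variance_ratio = 1.5,
                          smoothness_ratio = 1.4,
                          baseline_mean = 100,
                          baseline_sd = 10,
                          smooth_sigma = 1.5,
                          clinical_params = default_clinical_params(),
                          seed = 20201124L) {
  if (n_che < 2L || n_nche < 2L) stop("need at least 2 subjects per class")
  if (!all(effect_rois %in% roi_names)) stop("effect_rois must be a subset of roi_names")
  if (any(c(variance_ratio, smoothness_ratio) <= 0)) stop("ratios must be > 0")
  if (any(roi_shape < 8L)) stop("roi_shape must be >= 8 voxels per axis")
  for (cls in c("CHE", "nCHE")) {
    pr <- clinical_params[[cls]]$child_pugh_probs
    if (abs(sum(pr) - 1) > 1e-8) stop("child_pugh_probs for ", cls, " do not sum to 1")
    if (clinical_params[[cls]]$p_male < 0 || clinical_params[[cls]]$p_male > 1)
      stop("p_male for ", cls, " must be a probability")
  }
  structure(
    list(n_che = as.integer(n_che), n_nche = as.integer(n_nche),
         roi_names = roi_names, roi_shape = as.integer(roi_shape),
         effect_rois = effect_rois, intensity_shift = intensity_shift,
         variance_ratio = variance_ratio, smoothness_ratio = smoothness_ratio,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         smooth_sigma = smooth_sigma, clinical_params = clinical_params,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @export
precuneus_rois <- function() {
  as.vector(outer(c("right", "left"), c("PC", "PEp", "PEm", "PEr", "Lc1"),
                  paste, sep = "_"))
}

#' Default class-conditional clinical distributions
#'
#' Continuous covariates are parameterized by mean and sd: venous ammonia
#' (NH3, umol/L) is log-normal (positive support) matched to the configured
#' moments; NCT-A (s), DST (correct count), age (years) and education (years)
#' are normal truncated at 0. Child-Pugh stage and sex are categorical with
#' class-conditional probabilities. Defaults reflect the training-set
#' distributions typical of HBV-cirrhosis CHE cohorts: CHE subjects have
#' markedly higher ammonia, worse Child-Pugh stage, slower NCT-A and lower
#' DST than nCHE subjects, with similar age/sex/education.
#'
#' @return Nested list: `$CHE` / `$nCHE`, each with `nh3`, `nct_a`, `dst`,
#'   `age`, `education` (mean, sd), `child_pugh_probs` (A, B, C), `p_male`.
#' @export
default_clinical_params <- function() {
  list(
    CHE = list(
      nh3 = c(mean = 57.43, sd = 44.45),
      nct_a = c(mean = 63.65, sd = 32.00),
      dst = c(mean = 24.51, sd = 11.59),
      age = c(mean = 57.00, sd = 9.98),
      education = c(mean = 7.95, sd = 4.26),
      child_pugh_probs = c(A = 8, B = 13, C = 16) / 37,
      p_male = 25 / 37
    ),
    nCHE = list(
      nh3 = c(mean = 21.36, sd = 12.13),
      nct_a = c(mean = 31.37, sd = 7.26),
      dst = c(mean = 38.53, sd = 9.18),
      age = c(mean = 53.22, sd = 8.99),
      education = c(mean = 9.89, sd = 3.03),
      child_pugh_probs = c(A = 21, B = 12, C = 3) / 36,
      p_male = 23 / 36
    )
  )
}

# per-stream seed from the master seed and a counter; linear-congruential
# style hash keeps every derived seed inside 32-bit integer range
.derive_seed <- function(master, counter) {
  as.integer(((as.numeric(master) %% 2147483647) * 69069 +
                as.numeric(counter) * 1013904223) %% 2147483647)
}

# separable periodic Gaussian smoothing; kernel truncated at 3 sigma
.smooth_field <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- ceiling(3 * sigma)
  dm <- dim(x)
  if (any(2 * r + 1 > dm)) {
    stop("volume of shape ", paste(dm, collapse = "x"),
         " is too small for a smoothing kernel of half-width ", r)
  }
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w <- w / sum(w)
  for (axis in 1:3) {
    n <- dm[axis]
    acc <- array(0, dm)
    for (t in (-r):r) {
      idx <- rep(list(quote(expr = )), 3)
      idx[[axis]] <- ((seq_len(n) - 1 + t) %% n) + 1L
      acc <- acc + w[t + r + 1] * do.call(`[`, c(list(x), idx, list(drop = FALSE)))
    }
    x <- acc
  }
  x
}

# theoretical sd of periodically smoothed unit white noise
.smoothed_sd <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- ceiling(3 * sigma)
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w <- w / sum(w)
  sqrt(sum(w^2))^3
}

#' Generate one synthetic ROI volume
#'
#' A Gaussian random field: unit white noise smoothed with an isotropic
#' Gaussian kernel, normalized back to unit pointwise variance, then placed
#' at the class-conditional mean and scale. Class effects (mean shift,
#' variance scaling, smoothing-length scaling) are applied only when
#' `roi_name` is in `config$effect_rois` and `class_label == "CHE"`.
#' Deterministic given (`config$seed`, `subject_seed`).
#'
#' @param class_label `"CHE"` or `"nCHE"`.
#' @param roi_name which ROI the volume belongs to.
#' @param config a [cohort_config()].
#' @param subject_seed per-subject stream counter.
#' @param subject_id recorded on the volume.
#' @return An `image_volume`.
#' @export
generate_roi_volume <- function(class_label, roi_name, config, subject_seed,
                                subject_id = paste0("subj", subject_seed)) {
  stopifnot(class_label %in% c("CHE", "nCHE"))
  affected <- class_label == "CHE" && roi_name %in% config$effect_rois
  mu <- config$baseline_mean + if (affected) config$intensity_shift else 0
  sd_v <- config$baseline_sd * if (affected) sqrt(config$variance_ratio) else 1
  sigma <- config$smooth_sigma * if (affected) config$smoothness_ratio else 1
  set.seed(.derive_seed(config$seed, subject_seed))
  z <- array(stats::rnorm(prod(config$roi_shape)), dim = config$roi_shape)
  z <- .smooth_field(z, sigma) / .smoothed_sd(sigma)
  image_volume(mu + sd_v * z, spacing = c(1, 1, 1), subject_id = subject_id)
}

#' Axis-aligned ellipsoid ROI mask inscribed in the volume grid
#'
#' Non-box geometry so run-length handling is exercised across oblique mask
#' boundaries. Semi-axes are 90% of the half-extent of each axis.
#'
#' @param shape voxel dimensions.
#' @param name mask name.
#' @return An `roi_mask`.
#' @export
ellipsoid_mask <- function(shape, name = "roi") {
  ctr <- (shape + 1) / 2
  semi <- pmax((shape - 1) / 2 * 0.9, 1)
  co <- arrayInd(seq_len(prod(shape)), shape)
  inside <- ((co[, 1] - ctr[1]) / semi[1])^2 +
    ((co[, 2] - ctr[2]) / semi[2])^2 +
    ((co[, 3] - ctr[3]) / semi[3])^2 <= 1
  roi_mask(array(as.integer(inside), dim = shape), name = name)
}

# truncated-normal draw (support > lower), degenerate at the mean when sd = 0
.rtruncnorm1 <- function(mean, sd, lower = 0) {
  if (sd == 0) return(mean)
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x > lower) return(x)
  }
}

#' Generate one subject's clinical record
#'
#' NH3 is drawn log-normal with moments matched to the configured mean/sd
#' (point mass at the mean when sd = 0); NCT-A, DST, age and education are
#' normal truncated at 0; Child-Pugh stage and sex are categorical draws from
#' the class-conditional probabilities. Deterministic given
#' (`config$seed`, `subject_seed`).
#'
#' @inheritParams generate_roi_volume
#' @return One-row data frame: subject_id, group, nh3, child_pugh, nct_a,
#'   dst, age, sex, education.
#' @export
generate_clinical <- function(class_label, config, subject_seed,
                              subject_id = paste0("subj", subject_seed)) {
  stopifnot(class_label %in% c("CHE", "nCHE"))
  p <- config$clinical_params[[class_label]]
  if (abs(sum(p$child_pugh_probs) - 1) > 1e-8)
    stop("child_pugh_probs do not sum to 1")
  set.seed(.derive_seed(config$seed, subject_seed))
  m <- p$nh3[["mean"]]; s <- p$nh3[["sd"]]
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  nh3 <- if (s == 0) m else stats::rlnorm(1, meanlog, sdlog)
  data.frame(
    subject_id = subject_id,
    group = class_label,
    nh3 = nh3,
    child_pugh = sample(c("A", "B", "C"), 1, prob = p$child_pugh_probs),
    nct_a = .rtruncnorm1(p$nct_a[["mean"]], p$nct_a[["sd"]]),
    dst = .rtruncnorm1(p$dst[["mean"]], p$dst[["sd"]]),
    age = .rtruncnorm1(p$age[["mean"]], p$age[["sd"]]),
    sex = if (stats::runif(1) < p$p_male) "M" else "F",
    education = .rtruncnorm1(p$education[["mean"]], p$education[["sd"]]),
    stringsAsFactors = FALSE
  )
}

#' Generate a full synthetic cohort on disk
#'
#' Writes one NIfTI volume/mask pair per (subject, ROI) under
#' `volumes/<subject>_<roi>.nii.gz` and `masks/<subject>_<roi>.nii.gz`
#' (1 mm isotropic spacing in the header) plus `clinical.csv` with one row
#' per subject. Per-subject streams are derived from the master seed by a
#' fixed counter scheme (subject index x 1000 + ROI index; clinical uses ROI
#' index 0), so subjects are independent yet the whole cohort regenerates
#' bit-identically under the same seed.
#'
#' @param config a [cohort_config()].
#' @param output_dir writable directory.
#' @param write_volumes set `FALSE` to write only `clinical.csv` (for
#'   analyses that never touch the imaging arm).
#' @return Invisibly, the clinical data frame.
#' @export
generate_cohort <- function(config, output_dir, write_volumes = TRUE) {
  dir.create(file.path(output_dir, "volumes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(output_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) stop("cannot create output directory: ", output_dir)
  groups <- c(rep("CHE", config$n_che), rep("nCHE", config$n_nche))
  ids <- c(sprintf("che%03d", seq_len(config$n_che)),
           sprintf("nche%03d", seq_len(config$n_nche)))
  clin <- do.call(rbind, lapply(seq_along(ids), function(i) {
    generate_clinical(groups[i], config, subject_seed = i * 1000L,
                      subject_id = ids[i])
  }))
  utils::write.csv(clin, file.path(output_dir, "clinical.csv"), row.names = FALSE)
  if (write_volumes) {
    mask <- ellipsoid_mask(config$roi_shape)
    for (i in seq_along(ids)) {
      for (j in seq_along(config$roi_names)) {
        rn <- config$roi_names[j]
        vol <- generate_roi_volume(groups[i], rn, config,
                                   subject_seed = i * 1000L + j,
                                   subject_id = ids[i])
        vp <- file.path(output_dir, "volumes", paste0(ids[i], "_", rn, ".nii.gz"))
        mp <- file.path(output_dir, "masks", paste0(ids[i], "_", rn, ".nii.gz"))
        tryCatch({
          write_volume(vol, vp)
          write_mask(roi_mask(mask$data, name = rn), mp)
        }, error = function(e) {
          stop("I/O failure writing ", vp, ": ", conditionMessage(e))
        })
      }
    }
  }
  invisible(clin)
}
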