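#' Extraction settings
#'
#' @param n_bins gray levels for discretization (equal-width over the per-ROI
#'   min-max).
#' @param distance co-occurrence lattice distance.
#' @return A list of extraction parameters.
#' @export
extraction_config <- function(n_bins = 32L, distance = 1L) {
  stopifnot(n_bins >= 2L, distance >= 1L)
  list(n_bins = as.integer(n_bins), distance = as.integer(distance))
}

# the 47 first-order + texture features of one masked image
.features_47 <- function(roi, config) {
  disc <- discretize(roi, config$n_bins)
  fi <- intensity_features(roi, config$n_bins)
  fc <- glcm_features(disc, distance = config$distance)
  fr <- glrlm_features(disc)
  names(fi) <- paste0("intensity_", names(fi))
  names(fc) <- paste0("glcm_", names(fc))
  names(fr) <- paste0("glrlm_", names(fr))
  c(fi, fc, fr)
}

#' Extract the 423 radiomic features of one ROI
#'
#' 47 features (14 intensity + 22 GLCM + 11 GLRLM) on the raw masked ROI,
#' plus the same 47 on each of the 8 stationary-Haar wavelet subbands:
#' 47 x (1 + 8) = 423. Feature names follow the grammar
#' `<roi>_<family>_<feature>[_<subband>]`, so the field's usual labels (e.g.
#' "right Lc1, Median, HLL") map 1:1 onto columns.
#'
#' @param volume an `image_volume`.
#' @param mask an `roi_mask` aligned to it.
#' @param config an [extraction_config()].
#' @param subbands optionally precomputed [wavelet_subbands()] of `volume`.
#' @return Named numeric vector of length 423.
#' @export
extract_roi_features <- function(volume, mask, config = extraction_config(),
                                 subbands = NULL) {
  roi <- apply_mask(volume, mask)
  out <- .features_47(roi, config)
  names(out) <- paste0(mask$name, "_", names(out))
  if (is.null(subbands)) subbands <- wavelet_subbands(volume)
  for (band in names(subbands)) {
    roi_b <- apply_mask(subbands[[band]], mask)
    f <- .features_47(roi_b, config)
    names(f) <- paste0(mask$name, "_", names(f), "_", band)
    out <- c(out, f)
  }
  if (anyDuplicated(names(out))) stop("duplicated feature names")
  if (!all(is.finite(out))) {
    bad <- names(out)[!is.finite(out)]
    stop("non-finite feature values: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  out
}

#' Extract features for one subject across all ROIs
#'
#' @param volumes named list of `image_volume`s, one per ROI (each ROI's
#'   masked patch arrives as its own aligned volume).
#' @param masks named list of `roi_mask`s, names matching `volumes`.
#' @inheritParams extract_roi_features
#' @return Named numeric vector, 423 x number of ROIs.
#' @export
extract_subject_features <- function(volumes, masks, config = extraction_config()) {
  stopifnot(identical(names(volumes), names(masks)))
  unlist(lapply(names(masks), function(rn) {
    extract_roi_features(volumes[[rn]], masks[[rn]], config)
  }))
}

#' Build the cohort feature table from volumes and masks on disk
#'
#' Reads each subject's per-ROI volume/mask NIfTI pairs (layout written by
#' [generate_cohort()]: `volumes/<subject>_<roi>.nii.gz` and
#' `masks/<subject>_<roi>.nii.gz`) and assembles the subjects x features
#' data frame, 423 columns per ROI, column order deterministic. A subject
#' whose ROI fails validation is flagged in the returned `failed` attribute,
#' never silently dropped.
#'
#' @param cohort_dir directory containing `volumes/`, `masks/` and
#'   `clinical.csv`.
#' @param config an [extraction_config()].
#' @param verbose print one line per subject.
#' @return A data frame with `subject_id`, `group`, then feature columns;
#'   attribute `failed` lists subjects whose extraction errored.
#' @export
extract_cohort_features <- function(cohort_dir, config = extraction_config(),
                                    verbose = FALSE) {
  clin <- utils::read.csv(file.path(cohort_dir, "clinical.csv"),
                          stringsAsFactors = FALSE)
  roi_names <- attr(read_cohort_rois(cohort_dir), "roi_names")
  rows <- list()
  failed <- character(0)
  for (sid in clin$subject_id) {
    res <- tryCatch({
      vols <- list(); msks <- list()
      for (rn in roi_names) {
        vols[[rn]] <- read_volume(file.path(cohort_dir, "volumes",
                                            paste0(sid, "_", rn, ".nii.gz")),
                                  subject_id = sid)
        msks[[rn]] <- read_mask(file.path(cohort_dir, "masks",
                                          paste0(sid, "_", rn, ".nii.gz")),
                                name = rn)
      }
      extract_subject_features(vols, msks, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sid)
      warning("subject ", sid, " failed extraction: ", conditionMessage(res))
    } else {
      rows[[sid]] <- res
    }
    if (verbose) message("extracted ", sid, " (", length(res), " features)")
  }
  feat <- as.data.frame(do.call(rbind, rows))
  feat <- cbind(
    clin[match(rownames(feat), clin$subject_id), c("subject_id", "group")],
    feat
  )
  rownames(feat) <- NULL
  attr(feat, "failed") <- failed
  feat
}

# roi names present in a cohort directory, inferred from the mask files of
# the first subject listed in clinical.csv
read_cohort_rois <- function(cohort_dir) {
  clin <- utils::read.csv(file.path(cohort_dir, "clinical.csv"),
                          stringsAsFactors = FALSE)
  sid <- clin$subject_id[1]
  files <- list.files(file.path(cohort_dir, "masks"),
                      pattern = paste0("^", sid, "_.*\\.nii\\.gz$"))
  rois <- sub(paste0("^", sid, "_"), "", sub("\\.nii\\.gz$", "", files))
  structure(list(), roi_names = sort(rois))
}
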