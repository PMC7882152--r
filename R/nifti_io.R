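#' Image volume and ROI mask containers
#'
#' An `image_volume` is a 3D scalar grid (normalized T1 intensities) with its
#' voxel spacing in mm and the subject it belongs to. An `roi_mask` is a binary
#' grid on the same lattice, named after the anatomical region it delineates
#' (e.g. `right_Lc1`). Volumes and masks must arrive on a common grid:
#' registration and atlas reslicing are upstream of this package.
#'
#' @param data 3D numeric array, all values finite.
#' @param spacing numeric length-3, mm per axis, all > 0.
#' @param subject_id character scalar.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), subject_id = "subject") {
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1")
  if (!all(is.finite(data))) stop("volume contains non-finite voxels")
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values (mm)")
  structure(
    list(data = data, spacing = as.numeric(spacing), subject_id = subject_id),
    class = "image_volume"
  )
}

# texture statistics need a minimal neighbourhood; below this the matrices
# are too sparse to be meaningful
MIN_ROI_VOXELS <- 27L

#' @param name ROI name, e.g. `"right_Lc1"`.
#' @rdname image_volume
#' @export
roi_mask <- function(data, name = "roi") {
  if (length(dim(data)) != 3L) stop("mask data must be a 3D array")
  bin <- array(as.integer(data > 0.5), dim = dim(data))
  n_set <- sum(bin)
  if (n_set == 0L) stop("mask '", name, "' is empty (no voxels set)")
  if (n_set < MIN_ROI_VOXELS) {
    stop("mask '", name, "' has ", n_set, " voxels; at least ",
         MIN_ROI_VOXELS, " are required for texture statistics")
  }
  structure(list(data = bin, name = name), class = "roi_mask")
}

#' Read a NIfTI volume or mask
#'
#' Thin wrappers over RNifti that validate on the way in: volumes must be
#' finite everywhere, masks are coerced to {0,1} (any value > 0.5 is set) and
#' must carry at least 27 voxels.
#'
#' @param path path to a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param subject_id subject identifier recorded on the volume.
#' @return `read_volume()` an `image_volume`; `read_mask()` an `roi_mask`.
#' @export
read_volume <- function(path, subject_id = sub("\\.nii(\\.gz)?$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  image_volume(array(as.numeric(img), dim = dim(img)), spacing = spacing,
               subject_id = subject_id)
}

#' @param name ROI name; defaults to the file stem.
#' @rdname read_volume
#' @export
read_mask <- function(path, name = sub("\\.nii(\\.gz)?$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  roi_mask(array(as.numeric(img), dim = dim(img)), name = name)
}

#' @param volume an `image_volume` to write.
#' @param mask an `roi_mask` to write.
#' @param spacing voxel spacing recorded in the header, mm.
#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data, reference = NULL)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
write_mask <- function(mask, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.numeric(mask$data), dim = dim(mask$data)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Extract the ROI voxel set from a volume under a mask
#'
#' The masking step keeps the volume intensities at set mask voxels and flags
#' everything else absent (`NA` inside the tight bounding box). Background
#' voxels are *excluded* from all downstream statistics, not treated as
#' zero intensity, so histogram features see only in-mask tissue.
#'
#' @param volume an `image_volume`.
#' @param mask an `roi_mask` on the same grid.
#' @return An `roi_voxels` object: `values` (in-mask intensities), `grid`
#'   (bounding-box array, `NA` where absent), `bounding_box` (index ranges),
#'   `n_voxels`, and the originating `roi_name`/`subject_id`.
#' @export
apply_mask <- function(volume, mask) {
  if (!identical(dim(volume$data), dim(mask$data))) {
    stop("mask '", mask$name, "' shape (", paste(dim(mask$data), collapse = "x"),
         ") does not match volume '", volume$subject_id, "' shape (",
         paste(dim(volume$data), collapse = "x"), ")")
  }
  set <- mask$data == 1L
  if (!any(set)) stop("empty intersection between volume and mask '", mask$name, "'")
  idx <- which(set, arr.ind = TRUE)
  bb <- apply(idx, 2, range)  # 2 x 3: tight bounding box
  dimnames(bb) <- NULL
  grid <- volume$data[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3], drop = FALSE]
  inmask <- set[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3], drop = FALSE]
  grid[!inmask] <- NA_real_
  structure(
    list(
      values = volume$data[set],
      grid = grid,
      bounding_box = bb,
      n_voxels = sum(set),
      roi_name = mask$name,
      subject_id = volume$subject_id
    ),
    class = "roi_voxels"
  )
}
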