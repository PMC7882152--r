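# one small volume/mask pair shared by the extraction tests
vol <- generate_roi_volume("nCHE", "right_Lc1", tiny_cohort(), 1, subject_id = "s1")
msk <- ellipsoid_mask(c(16, 16, 16), "right_Lc1")

test_that("each ROI yields exactly 423 uniquely named finite features", {
  f <- extract_roi_features(vol, msk)
  expect_length(f, 423)
  expect_equal(anyDuplicated(names(f)), 0L)
  expect_true(all(is.finite(f)))
  # family breakdown: 14 + 22 + 11 on the raw ROI and on each of 8 subbands
  raw <- names(f)[!grepl("_(L|H){3}$", names(f))]
  wav <- names(f)[grepl("_(L|H){3}$", names(f))]
  expect_length(raw, 47)
  expect_length(wav, 376)
  expect_equal(sum(grepl("_intensity_", raw)), 14)
  expect_equal(sum(grepl("_glcm_", raw)), 22)
  expect_equal(sum(grepl("_glrlm_", raw)), 11)
  expect_true(all(grepl("^right_Lc1_", names(f))))
  # the field's signature feature labels map onto columns
  expect_true("right_Lc1_intensity_Median_HLL" %in% names(f))
  expect_true("right_Lc1_glrlm_GrayLevelNonuniformity_LLL" %in% names(f))
  expect_true("right_Lc1_glcm_IMC1_LLL" %in% names(f))
})

test_that("extraction is deterministic and scales to 423 columns per ROI", {
  f1 <- extract_roi_features(vol, msk)
  f2 <- extract_roi_features(vol, msk)
  expect_identical(f1, f2)
  # two ROIs on the same subject: 846 columns, distinct prefixes
  vols <- list(right_Lc1 = vol, left_PC = vol)
  msks <- list(right_Lc1 = msk,
               left_PC = ellipsoid_mask(c(16, 16, 16), "left_PC"))
  fs <- extract_subject_features(vols, msks)
  expect_length(fs, 2 * 423)
  expect_equal(sum(grepl("^left_PC_", names(fs))), 423)
})

test_that("discretization-based features are invariant under positive affine rescaling", {
  f0 <- extract_roi_features(vol, msk)
  vol2 <- image_volume(vol$data * 2.5 + 40, subject_id = vol$subject_id)
  f1 <- extract_roi_features(vol2, msk)
  tex <- grepl("_(glcm|glrlm)_", names(f0)) & !grepl("_(L|H){3}$", names(f0))
  expect_equal(f1[tex], f0[tex], tolerance = 1e-10)
  expect_equal(unname(f1["right_Lc1_intensity_Median"]),
               unname(f0["right_Lc1_intensity_Median"]) * 2.5 + 40)
  expect_equal(unname(f1["right_Lc1_intensity_Variance"]),
               unname(f0["right_Lc1_intensity_Variance"]) * 2.5^2)
})

test_that("smoother fields score higher on co-occurrence homogeneity", {
  idm <- function(sm_ratio, seed) {
    cfg <- cohort_config(n_che = 2, n_nche = 2, roi_names = "right_Lc1",
                         effect_rois = "right_Lc1", roi_shape = c(16, 16, 16),
                         smoothness_ratio = sm_ratio, smooth_sigma = 1,
                         intensity_shift = 0, variance_ratio = 1, seed = seed)
    v <- generate_roi_volume("CHE", "right_Lc1", cfg, 1)
    d <- discretize(apply_mask(v, ellipsoid_mask(c(16, 16, 16))), 32)
    unname(glcm_features(d)["InverseDifferenceMoment"])
  }
  seeds <- 1:20
  lo <- vapply(seeds, function(s) idm(1, s), numeric(1))
  hi <- vapply(seeds, function(s) idm(2, s), numeric(1))
  expect_gt(mean(hi), mean(lo))
})
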