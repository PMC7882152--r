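test_that("volume generation is deterministic and class effects hit the mean", {
  cfg <- tiny_cohort()
  v1 <- generate_roi_volume("CHE", "right_Lc1", cfg, 42)
  v2 <- generate_roi_volume("CHE", "right_Lc1", cfg, 42)
  expect_identical(v1$data, v2$data)
  v3 <- generate_roi_volume("CHE", "right_Lc1", cfg, 43)
  expect_false(identical(v1$data, v3$data))
  # planted mean shift recovered within Monte-Carlo error over 100 draws
  cfg50 <- cohort_config(n_che = 2, n_nche = 2, roi_names = "right_Lc1",
                         effect_rois = "right_Lc1", roi_shape = c(12, 12, 12),
                         intensity_shift = 50, variance_ratio = 1,
                         smoothness_ratio = 1, smooth_sigma = 1, seed = 3)
  d <- vapply(1:100, function(s) {
    mean(generate_roi_volume("CHE", "right_Lc1", cfg50, s)$data) -
      mean(generate_roi_volume("nCHE", "right_Lc1", cfg50, s + 5000)$data)
  }, numeric(1))
  # smoothing correlates voxels, so the volume-mean se is well above sd/sqrt(V);
  # the empirical se of the 100 paired differences bounds the check instead
  expect_lt(abs(mean(d) - 50), 4 * stats::sd(d) / sqrt(length(d)))
})

test_that("null configuration makes the classes exchangeable", {
  cfg0 <- cohort_config(n_che = 2, n_nche = 2, roi_names = "right_Lc1",
                        effect_rois = "right_Lc1", roi_shape = c(12, 12, 12),
                        intensity_shift = 0, variance_ratio = 1,
                        smoothness_ratio = 1, smooth_sigma = 1, seed = 9)
  a <- generate_roi_volume("CHE", "right_Lc1", cfg0, 7)
  b <- generate_roi_volume("nCHE", "right_Lc1", cfg0, 7)
  expect_identical(a$data, b$data)  # identical distribution, same stream
})

test_that("clinical draws match the configured class-conditional distributions", {
  cfg <- cohort_config(seed = 21)
  che <- do.call(rbind, lapply(1:10000, function(i)
    generate_clinical("CHE", cfg, i)))
  expect_true(all(che$nh3 > 0))
  expect_lt(abs(mean(che$nh3) - 57.43) / 57.43, 0.05)
  nche <- do.call(rbind, lapply(1:10000, function(i)
    generate_clinical("nCHE", cfg, i + 20000)))
  expect_lt(abs(mean(nche$child_pugh == "A") - 21 / 36), 0.03)
  expect_true(all(nche$nct_a > 0) && all(nche$dst >= 0))
})

test_that("zero-scale clinical configs degenerate to point masses", {
  cfg <- cohort_config()
  cfg$clinical_params$CHE$nh3 <- c(mean = 57.43, sd = 0)
  x <- generate_clinical("CHE", cfg, 5)
  expect_equal(x$nh3, 57.43)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_che = 1), "at least 2")
  expect_error(cohort_config(effect_rois = "nonexistent"), "subset")
  expect_error(cohort_config(variance_ratio = 0), "> 0")
  bad <- default_clinical_params()
  bad$CHE$child_pugh_probs <- c(A = 0.5, B = 0.5, C = 0.5)
  expect_error(cohort_config(clinical_params = bad), "sum to 1")
})

test_that("cohort generation writes the expected files exactly once per subject", {
  dir0 <- file.path(tempdir(), "coh_clin")
  cfg <- cohort_config(seed = 2)  # full 54 + 52 study conditions
  clin <- generate_cohort(cfg, dir0, write_volumes = FALSE)
  csv <- read.csv(file.path(dir0, "clinical.csv"))
  expect_equal(nrow(csv), 106)
  expect_equal(sum(csv$group == "CHE"), 54)
  expect_equal(anyDuplicated(csv$subject_id), 0L)
  expect_identical(colnames(csv),
                   c("subject_id", "group", "nh3", "child_pugh", "nct_a",
                     "dst", "age", "sex", "education"))
  # byte-identical regeneration under the same seed
  dir1 <- file.path(tempdir(), "coh_clin2")
  generate_cohort(cfg, dir1, write_volumes = FALSE)
  expect_identical(readLines(file.path(dir0, "clinical.csv")),
                   readLines(file.path(dir1, "clinical.csv")))
  # tiny imaging cohort: one volume+mask pair per (subject, ROI)
  dir2 <- file.path(tempdir(), "coh_img")
  cfg2 <- cohort_config(n_che = 2, n_nche = 2, roi_names = precuneus_rois(),
                        effect_rois = "right_Lc1", roi_shape = c(10, 10, 10),
                        smooth_sigma = 0.8, smoothness_ratio = 1, seed = 4)
  generate_cohort(cfg2, dir2)
  vols <- list.files(file.path(dir2, "volumes"))
  msks <- list.files(file.path(dir2, "masks"))
  expect_length(vols, 4 * 10)
  expect_equal(sum(grepl("^che001_", msks)), 10)  # 10 mask files per subject
  cfg3 <- cohort_config(n_che = 2, n_nche = 2, roi_names = "right_PC",
                        effect_rois = character(0), roi_shape = c(10, 10, 10),
                        smooth_sigma = 0.8, seed = 4)
  dir3 <- file.path(tempdir(), "coh_img1")
  generate_cohort(cfg3, dir3)
  expect_length(list.files(file.path(dir3, "volumes")), 4)
})
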