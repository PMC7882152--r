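#!/usr/bin/env Rscript
# Extract the radiomic feature space: 423 features per ROI (14 intensity +
# 22 GLCM + 11 GLRLM on the raw ROI and on each of 8 stationary-Haar
# subbands), 4,230 columns over the 10 precuneus ROIs.
source("analysis/00_config.R")

cfg <- analysis_config()
feat <- run_stage("extract", cfg, verbose = TRUE)

counts <- data.frame(
  subjects = nrow(feat),
  rois = length(cfg$cohort$roi_names),
  features_per_roi = (ncol(feat) - 2L) / length(cfg$cohort$roi_names),
  features_total = ncol(feat) - 2L,
  failed_subjects = length(attr(feat, "failed"))
)
write.csv(counts, file.path(results_dir(), "feature_space.csv"), row.names = FALSE)
message("feature space: ", counts$features_per_roi, " per ROI, ",
        counts$features_total, " total")
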