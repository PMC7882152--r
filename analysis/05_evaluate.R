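#!/usr/bin/env Rscript
# Nomogram for the better (R-C) model, calibration curves with the
# Hosmer-Lemeshow test on both sets, and Spearman correlations between the
# signature features (+ Radscore) and the clinical/cognitive variables.
source("analysis/00_config.R")

cfg <- analysis_config()
ev <- run_stage("evaluate", cfg)

write.csv(ev$nomogram_table, file.path(results_dir(), "nomogram_points.csv"),
          row.names = FALSE)
file.copy(file.path(cfg$output_dir, "calibration.csv"),
          file.path(results_dir(), "calibration.csv"), overwrite = TRUE)
corr <- ev$correlation_table
write.csv(corr, file.path(results_dir(), "correlations_signature.csv"),
          row.names = FALSE)

message("Hosmer-Lemeshow: train p = ", round(ev$hl$train$hl_p, 3),
        ", test p = ", round(ev$hl$test$hl_p, 3))
key <- corr[corr$clinical %in% c("dst", "nct_a") &
              corr$feature != "Radscore", ]
message("signature vs cognition (Spearman rho):")
print(key[order(key$clinical, -abs(key$rho)), ], digits = 2, row.names = FALSE)
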