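#!/usr/bin/env Rscript
# Concatenate the stage artifacts into one machine-readable report
# (selection counts, model card, nomogram, calibration, correlations) and
# copy it into results/. The reporter only collates; nothing is recomputed.
source("analysis/00_config.R")

cfg <- analysis_config()
rep <- run_stage("report", cfg)
message("selection: ", paste(unlist(rep$selection$counts), collapse = " -> "))
message("R test AUC = ", round(rep$model_card$R$test$auc, 3),
        "; R-C test AUC = ", round(rep$model_card$`R-C`$test$auc, 3),
        "; DeLong test p = ", signif(rep$model_card$delong_p$test, 3))
message("full report: ", file.path(cfg$output_dir, "report.json"))
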