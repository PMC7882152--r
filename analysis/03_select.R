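#!/usr/bin/env Rscript
# Stratified 7:3 split, then the three-stage cascade on the training set:
# Shapiro-Wilk-gated t / Mann-Whitney filter at p < .05, Spearman redundancy
# pruning at |rho| > 0.9, and LASSO signature discovery at the 10-fold
# cross-validated minimum-error lambda.
source("analysis/00_config.R")

cfg <- analysis_config()
sel <- run_stage("select", cfg)

counts <- data.frame(stage = names(sel$counts), features = as.vector(sel$counts))
write.csv(counts, file.path(results_dir(), "selection_counts.csv"), row.names = FALSE)
sig <- data.frame(feature = names(sel$lasso_fit$beta[sel$selected_names]),
                  coefficient = as.vector(sel$lasso_fit$beta[sel$selected_names]))
write.csv(sig, file.path(results_dir(), "signature.csv"), row.names = FALSE)
message("cascade: ", paste(sel$counts, collapse = " -> "),
        "; signature features:")
print(sig, digits = 4, row.names = FALSE)
side <- ifelse(grepl("^right_", sel$selected_names), "right", "left")
message("signature by hemisphere: ", sum(side == "right"), " right / ",
        sum(side == "left"), " left")
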