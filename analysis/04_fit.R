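#!/usr/bin/env Rscript
# Fit the two classifiers on the training set and evaluate both sets:
# R model  - unpenalized logistic regression on the signature features;
# R-C model - logistic regression on Radscore + NH3 + Child-Pugh stage.
# Operating point: Youden threshold on training, applied unchanged to
# testing; paired DeLong comparison per set.
source("analysis/00_config.R")

cfg <- analysis_config()
models <- run_stage("fit", cfg)

row_for <- function(kind, set) {
  rr <- models$roc[[kind]][[set]]
  data.frame(model = kind, set = set, auc = rr$auc,
             ci_lo = rr$auc_ci_95[1], ci_hi = rr$auc_ci_95[2],
             acc = rr$acc, sen = rr$sen, spe = rr$spe,
             threshold = rr$operating_threshold)
}
perf <- rbind(row_for("R", "train"), row_for("R", "test"),
              row_for("R-C", "train"), row_for("R-C", "test"))
perf$delong_p <- rep(c(models$delong$train$p_value,
                       models$delong$test$p_value), 2)
write.csv(perf, file.path(results_dir(), "model_performance.csv"),
          row.names = FALSE)
message("model performance (CHE = positive class):")
print(perf, digits = 3, row.names = FALSE)
message("Radscore intercept beta0 = ",
        round(models$signature$beta0, 3), "; coefficients:")
print(round(models$signature$betas, 4))
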