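# shared configuration for the numbered analysis scripts: a full-size
# synthetic CHE/nCHE cohort (54 + 52 subjects, 10 precuneus ROIs) analysed
# end-to-end. Stage artifacts live under scratch/ (large, regenerable);
# summary tables land in results/.
library(cheradiomics)

analysis_config <- function() {
  pipeline_config(
    output_dir = "scratch/pipeline",
    cohort = cohort_config(),        # the study conditions: 54/52, 10 ROIs
    master_seed = 20201124L
  )
}

results_dir <- function() {
  dir.create("results", showWarnings = FALSE)
  "results"
}
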