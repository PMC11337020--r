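#!/usr/bin/env Rscript
# Stage 1: generate the synthetic 7-patient lesion cohort (the desk-scale
# stand-in for controlled-access patient data) and write it to disk in the
# 10x-style formats the rest of the workflow reads, together with its truth
# tables. Downstream stages read results/cohort/ and never see the truth
# except where a script explicitly evaluates recovery.
library(lymphclone)

seed <- as.integer(Sys.getenv("COHORT_SEED", "11"))
dir.create("results", showWarnings = FALSE)

cohort <- emulate_lesion_cohort(seed)
write_cohort(cohort, "results/cohort")

truth <- cohort$truth$cells
summ <- do.call(rbind, lapply(split(truth, truth$sample), function(d)
  data.frame(sample = d$sample[1], n_cells = nrow(d), n_t = sum(d$is_t),
             n_malignant = sum(d$is_malignant),
             malignant_fraction_truth = mean(d$is_malignant[d$is_t]),
             regime = cohort$config$dynamics_regime[
               as.integer(sub("P", "", d$sample[1]))])))
write_table(summ, "results/01_cohort_truth_summary.csv", "csv")

cat(sprintf("Simulated %d patients / %d cells / %d genes (seed %d).\n",
            length(cohort$samples), nrow(truth), cohort$config$n_genes, seed))
cat(sprintf("Truth malignant fractions span %.2f-%.2f; %d signature genes planted in >=4 patients; patient %d carries a non-productive clone.\n",
            min(summ$malignant_fraction_truth), max(summ$malignant_fraction_truth),
            sum(cohort$truth$genes$is_signature),
            which(!vapply(cohort$config$plan$malignant_clones, `[[`, TRUE, "productive"))))
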