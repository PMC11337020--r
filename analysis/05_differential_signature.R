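#!/usr/bin/env Rscript
# Stage 5: malignant-vs-reactive Wilcoxon differential expression
# (|lnFC| > 0.25, Bonferroni p < 0.05), pooled and per patient, and the
# >=4-of-7-patient recurrence signature.
suppressPackageStartupMessages({
  library(Matrix)
  library(lymphclone)
})

res <- readRDS("results/pipeline_run.rds")
pooled <- res$de$pooled
write_table(volcano_data(pooled), "results/05_volcano_pooled.csv", "csv")
for (sid in names(res$de$per_patient))
  write_table(res$de$per_patient[[sid]],
              sprintf("results/05_de_%s.csv", sid), "csv")
sig <- res$de$signature
write_table(sig, "results/05_signature.csv", "csv")
cat(sprintf("Pooled DE: %d significant genes of %d tested.\n",
            sum(pooled$significant), nrow(pooled)))
cat(sprintf("Recurrence signature (up in >=4 patients): %d genes:\n  %s\n",
            sum(sig$member), paste(sig$gene[sig$member], collapse = ", ")))
# reporting view: exhaustion-marker dot-plot data per patient's malignant cells
groups <- lapply(split(res$labels, res$labels$sample), function(l)
  l$barcode[l$label == "malignant"])
dots <- marker_dotplot_data(res$norm, groups,
                            c("PDCD1", "CTLA4", "LAG3", "TIGIT", "HAVCR2", "CD160"))
write_table(dots, "results/05_exhaustion_dotplot.csv", "csv")
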