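#!/usr/bin/env Rscript
# Generate the synthetic model-establishment cohort: 501 subjects
# (152 HC, 149 T2DM, 39 grey-zone, 106 early DKD, 55 overt DKD),
# 227 metabolite + 206 peptide features, 3 technical replicates, two
# batches, pooled QC injections, and 10 + 6 planted stepwise-regulated
# biomarkers. Writes the replicate-level feature matrix, metadata and
# planted truth under results/cohort/.

library(uromics)

seed <- 1L
cfg <- cohort_config(seed = seed)
cohort <- generate_cohort(cfg)
print(cohort)

paths <- write_cohort(cohort, file.path("results", "cohort"))
cat("written:\n"); cat(paste(" -", paths), sep = "\n")

cat(sprintf("\nplanted stepwise features (%d):\n", length(cohort$truth)))
reg <- cohort$features$regulation[match(cohort$truth,
                                        cohort$features$feature_id)]
print(data.frame(feature_id = cohort$truth, regulation = reg))
cat("\ninternal standards:",
    paste(cohort$internal_standard_ids, collapse = ", "), "\n")
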