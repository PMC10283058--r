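#!/usr/bin/env Rscript
# Seven-algorithm pairwise prediction bench (SVM, DT, NB, Logi, LDA,
# KNN, LASSO) over metabolite markers alone, peptide markers alone,
# and their per-block standardized combination, for the three stage
# contrasts, on a stratified 2:1 discovery/validation split.

library(uromics)

cohort <- generate_cohort(cohort_config(seed = 1L))
pp <- preprocess_cohort(cohort)
groups <- pp$groups

# marker screen: stepwise features from the discovery portion only
contrasts <- combn(c("HC", "T2DM", "EARLY_DKD", "OVERT_DKD"), 2)
pairs <- list(c("T2DM", "EARLY_DKD"), c("EARLY_DKD", "OVERT_DKD"),
              c("T2DM", "OVERT_DKD"))

all_rows <- list()
for (pr in pairs) {
  sel <- names(groups)[groups %in% pr]
  y <- factor(groups[sel], levels = pr)
  plan <- split_discovery_validation(sel, y, seed = 5L)
  d <- ttest_features(pp$matrix[plan$discovery, ],
                      plan$discovery[groups[plan$discovery] == pr[1]],
                      plan$discovery[groups[plan$discovery] == pr[2]])
  markers <- d$feature_id[d$q < 0.05]
  mods <- cohort$features$modality[match(markers,
                                         cohort$features$feature_id)]
  met_ids <- markers[mods == "met"]; pep_ids <- markers[mods == "pep"]
  if (length(met_ids) < 2 || length(pep_ids) < 2) {
    cat(sprintf("%s vs %s: too few markers per modality, skipped\n",
                pr[1], pr[2]))
    next
  }
  cmp <- suppressWarnings(compare_single_vs_multiomics(
    log2(pp$matrix[sel, met_ids, drop = FALSE]),
    log2(pp$matrix[sel, pep_ids, drop = FALSE]),
    y, split = plan, seed = 5L))
  cat(sprintf("%s vs %s (markers: %d met, %d pep): mean accuracy met %.3f, pep %.3f, combined %.3f\n",
              pr[1], pr[2], length(met_ids), length(pep_ids),
              cmp$mean_accuracy[["met"]], cmp$mean_accuracy[["pep"]],
              cmp$mean_accuracy[["combined"]]))
  cmp$metrics$contrast <- paste(pr, collapse = " vs ")
  all_rows[[paste(pr, collapse = "_")]] <- cmp$metrics
}

write.csv(do.call(rbind, all_rows), "results/ml_comparison.csv",
          row.names = FALSE)
cat("-> results/ml_comparison.csv\n")
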