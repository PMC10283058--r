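#!/usr/bin/env Rscript
# Unsupervised and supervised projections: PCA of the full cohort and
# pairwise O-PLS discriminant models with 7-fold cross-validated Q2
# for the three informative stage contrasts.

library(uromics)

cohort <- generate_cohort(cohort_config(seed = 1L))
pp <- preprocess_cohort(cohort)
groups <- pp$groups
lx <- log2(pp$matrix)

pca <- fit_pca(lx, 2)
cat(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance\n",
            100 * pca$explained_variance_ratio[1],
            100 * pca$explained_variance_ratio[2]))
write.csv(data.frame(sample_id = rownames(pp$matrix),
                     group = groups, pca$scores),
          "results/pca_scores.csv", row.names = FALSE)

pairs <- list(c("T2DM", "EARLY_DKD"), c("EARLY_DKD", "OVERT_DKD"),
              c("T2DM", "OVERT_DKD"))
summ <- lapply(pairs, function(pr) {
  sel <- names(groups)[groups %in% pr]
  y <- factor(groups[sel], levels = pr)
  m <- fit_oplsda(lx[sel, ], y, n_orthogonal = 1)
  q2 <- oplsda_q2(lx[sel, ], y, n_orthogonal = 1, seed = 4L)
  cat(sprintf("O-PLS %s vs %s: R2X(pred) %.3f, R2Y %.3f, Q2 %.3f\n",
              pr[1], pr[2], m$r2x[["predictive"]], m$r2y, q2))
  data.frame(contrast = paste(pr, collapse = " vs "),
             r2x_predictive = m$r2x[["predictive"]],
             r2y = m$r2y, q2 = q2)
})
write.csv(do.call(rbind, summ), "results/oplsda_summary.csv",
          row.names = FALSE)
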