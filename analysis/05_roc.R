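#!/usr/bin/env Rscript
# Multivariate ROC biomarker evaluation: RF, SVM and PLS-DA MCCV models on
# the recovered differential panel, plus nested feature-subset models
# (3-analyte and full panel). Reads outputs of 03/04.

library(cilFAHFA)

seed <- 1
mat <- read_tsv("results/abundance_matrix.tsv")
samples <- read_tsv("results/samples.tsv")
venn <- read_tsv("results/differential_set.tsv")
values <- as.matrix(mat[, -1])
rownames(values) <- mat$analyte_id
ab <- abundance_matrix(values, samples)
z <- preprocess(ab)$z
panel <- venn$analyte_id

rows <- lapply(c("RF", "SVM", "PLSDA"), function(method) {
  r <- mccv_auc(z, ab$samples$group, method, features = panel, seed = seed)
  print(r)
  data.frame(method = method, auc = r$auc, ci_lo = r$auc_ci[1],
             ci_hi = r$auc_ci[2], n_features = length(panel),
             n_repeats = r$n_repeats)
})
roc_tab <- do.call(rbind, rows)

subsets <- feature_subset_models(z, ab$samples$group,
                                 sizes = c(3, length(panel)),
                                 method = "RF", seed = seed)
for (nm in names(subsets)) {
  cat(sprintf("nested top-%s RF model: AUC %.3f [%.3f, %.3f]\n", nm,
              subsets[[nm]]$auc, subsets[[nm]]$auc_ci[1],
              subsets[[nm]]$auc_ci[2]))
}

write_tsv(roc_tab, "results/roc_models.tsv")
cat("wrote results/roc_models.tsv\n")
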