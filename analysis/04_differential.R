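#!/usr/bin/env Rscript
# Differential analysis of the quantified study: paired t-tests with BH
# FDR, fold changes, volcano filter, OPLS-DA with VIP and a 200-round
# permutation test, and the Venn intersection defining the differential
# FAHFA set. Reads the matrix written by 03_quantify.R.

library(cilFAHFA)

seed <- 1
mat <- read_tsv("results/abundance_matrix.tsv")
samples <- read_tsv("results/samples.tsv")
values <- as.matrix(mat[, -1])
rownames(values) <- mat$analyte_id
ab <- abundance_matrix(values, samples)

d <- run_differential(ab, seed = seed)
m <- d$model
cat(sprintf("OPLS-DA: R2Y = %.3f, Q2 = %.3f\n", m$r2y, m$q2))
perm <- permutation_test(m, preprocess(ab)$z, ab$samples$group,
                         n_perm = 200, seed = seed)
cat(sprintf("permutation test (n = 200): %s (max permuted R2Y %.3f, Q2 %.3f)\n",
            ifelse(perm$pass, "PASS", "FAIL"),
            max(perm$r2y_perm), max(perm$q2_perm)))

venn <- d$venn
cat(sprintf("differential set: %d analytes (%d up, %d down)\n",
            nrow(venn), sum(venn$regulation == "UP"),
            sum(venn$regulation == "DOWN")))
rec <- d$records[d$records$in_venn_set, ]
rec <- rec[order(-sign(rec$log2_fc), rec$p_value), ]
print(rec[, c("analyte_id", "vip", "fc", "log2_fc", "p_value", "fdr",
              "regulation")], digits = 3, row.names = FALSE)

write_tsv(d$records, "results/differential_records.tsv")
write_tsv(venn, "results/differential_set.tsv")
cat("wrote results/differential_records.tsv\n")
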