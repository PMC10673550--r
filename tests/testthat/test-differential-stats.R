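two_group_ab <- function(tumor, normal, ids = letters[seq_len(nrow(tumor))]) {
  n <- ncol(tumor)
  samples <- data.frame(
    sample_id = c(paste0("T", 1:n), paste0("N", 1:n)),
    group = rep(c("TUMOR", "NORMAL"), each = n),
    pair_id = rep(1:n, 2))
  abundance_matrix(matrix(c(tumor, normal), nrow = nrow(tumor),
                          dimnames = list(ids, samples$sample_id)),
                   samples)
}

test_that("preprocess log-transforms and z-scores by population SD", {
  ab <- two_group_ab(matrix(c(1, 10), 1), matrix(c(100, 10), 1), "a")
  pp <- preprocess(ab)
  expect_equal(as.numeric(pp$log10), c(0, 1, 2, 1))
  # {1, 10, 100} pattern: z is centered and population-scaled
  vals <- c(0, 1, 2)
  z <- (vals - mean(vals)) / sqrt(mean((vals - mean(vals))^2))
  expect_equal(z, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(unname(rowMeans(pp$z)), 0)
  expect_equal(unname(sqrt(rowMeans(pp$z^2))), 1)
  # constant analytes are flagged and excluded from the z matrix
  ab2 <- two_group_ab(matrix(c(5, 5, 2, 3), 2, byrow = TRUE),
                      matrix(c(5, 5, 4, 5), 2, byrow = TRUE), c("flat", "ok"))
  pp2 <- preprocess(ab2)
  expect_equal(pp2$constant, "flat")
  expect_equal(rownames(pp2$z), "ok")
})

test_that("fold change is the raw-scale mean ratio and inverts under swap", {
  ab <- two_group_ab(matrix(c(4, 4), 1), matrix(c(2, 2), 1), "a")
  fc <- fold_change(ab)
  expect_equal(fc$fc, 2.0)
  expect_equal(fc$log2_fc, 1.0)
  same <- two_group_ab(matrix(c(3, 7), 1), matrix(c(3, 7), 1), "a")
  expect_equal(fold_change(same)$fc, 1.0)
  expect_equal(fold_change(same)$log2_fc, 0.0)
  # FC 0.5 <-> log2 FC -1 (the down-regulated biomarker convention)
  half <- two_group_ab(matrix(c(1, 1), 1), matrix(c(2, 2), 1), "a")
  expect_equal(fold_change(half)$log2_fc, -1.0)
  # swap invariance: FC -> 1/FC, p unchanged
  ab3 <- make_study(seed = 21)
  swapped <- ab3
  swapped$samples$group <- ifelse(ab3$samples$group == "TUMOR",
                                  "NORMAL", "TUMOR")
  expect_equal(fold_change(swapped)$fc, 1 / fold_change(ab3)$fc)
  expect_equal(paired_t_test(swapped)$p_value, paired_t_test(ab3)$p_value)
})

test_that("vectorized paired t agrees with the stats::t.test oracle", {
  ab <- make_study(seed = 22)
  mine <- paired_t_test(ab)
  lg <- log10(ab$values)
  tum <- ab$samples$group == "TUMOR"
  for (i in c(1, 7, 13, 40, 72)) {
    oracle <- t.test(lg[i, tum][order(ab$samples$pair_id[tum])],
                     lg[i, !tum][order(ab$samples$pair_id[!tum])],
                     paired = TRUE)
    expect_equal(mine$p_value[i], oracle$p.value)
    expect_equal(mine$t[i], unname(oracle$statistic))
  }
  # unpaired Welch option
  welch <- paired_t_test(ab, paired = FALSE)
  oracle_w <- t.test(lg[1, tum], lg[1, !tum])
  expect_equal(welch$p_value[1], oracle_w$p.value)
})

test_that("degenerate difference patterns follow the stated conventions", {
  ab <- two_group_ab(matrix(c(2, 2, 2), 1), matrix(c(1, 1, 1), 1), "a")
  expect_message(res <- paired_t_test(ab), "zero-variance")
  expect_equal(res$p_value, .Machine$double.xmin)
  ab0 <- two_group_ab(matrix(c(1, 2, 3), 1), matrix(c(1, 2, 3), 1), "a")
  expect_message(res0 <- paired_t_test(ab0), "all-zero")
  expect_equal(res0$p_value, 1)
})

test_that("type-I error of the paired t is calibrated under the null", {
  design <- study_design(24, seed = 30)
  eff <- effect_spec(paste0("n", 1:10000), 0, 0.15)
  ab <- generate_abundance_study(design, eff, seed = 30)
  p <- paired_t_test(ab)$p_value
  expect_gte(mean(p < 0.05), 0.04)
  expect_lte(mean(p < 0.05), 0.06)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(5:100, 1))
    expect_equal(fdr_adjust(p), oracle_bh(p))
    expect_true(all(fdr_adjust(p) >= p))
  }
  # NAs are excluded from the test count and passed through
  p <- c(0.01, NA, 0.04)
  adj <- fdr_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], oracle_bh(p[c(1, 3)]))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("false discoveries under the global null stay FDR-controlled", {
  set.seed(32)
  fd <- vapply(1:200, function(i) {
    p <- runif(72)
    sum(fdr_adjust(p) < 0.05)
  }, 0)
  expect_lte(mean(fd), 0.05 * 72)
})

test_that("volcano selection applies both thresholds with direction", {
  v <- volcano_select(fc = c(1.4, 0.5, 3.0, 2.0),
                      p = c(0.001, 0.01, 0.2, 0.03))
  expect_equal(v$selected, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(v$direction, c("NS", "DOWN", "NS", "UP"))
})

test_that("venn intersection combines the two selections with regulation", {
  fc <- c(a = 2, b = 0.5, c = 3)
  expect_equal(nrow(venn_intersect(c("a", "b"), c("c"), fc)), 0)
  out <- venn_intersect(c("a", "b"), c("a", "b"), fc)
  expect_equal(out$analyte_id, c("a", "b"))
  expect_equal(out$regulation, c("UP", "DOWN"))
})

test_that("planted fold changes are recovered within 15% in the median", {
  est <- vapply(1:30, function(s) {
    design <- study_design(24, seed = s)
    eff <- effect_spec("9-OAHSA", 1.7 * log10(2),
                       calibrate_sd_from_p(1.7 * log10(2), 3.2e-8, 24))
    fold_change(generate_abundance_study(design, eff, seed = 400 + s))$fc
  }, 0)
  expect_lt(abs(median(est) - 2 ^ 1.7) / 2 ^ 1.7, 0.15)
})

test_that("the full differential workflow produces a coherent report", {
  ab <- make_study(seed = 23)
  d <- run_differential(ab, cv = FALSE, seed = 23)
  r <- d$records
  expect_setequal(names(r), c("analyte_id", "vip", "fc", "log2_fc", "p_value",
                              "fdr", "in_vip_set", "in_volcano_set",
                              "in_venn_set", "regulation"))
  expect_true(all(r$fdr >= r$p_value, na.rm = TRUE))
  expect_true(all(r$in_venn_set == (r$in_vip_set & r$in_volcano_set)))
  expect_true(all(r$regulation[r$in_venn_set & r$fc > 1] == "UP"))
  expect_true(all(r$regulation[r$in_venn_set & r$fc < 1] == "DOWN"))
  # the recovered set is dominated by planted analytes
  expect_gt(mean(d$venn$analyte_id %in% bc_effect_panel()$analyte_id), 0.99)
})
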