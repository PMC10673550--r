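test_that("calibrate_sd_from_p inverts the paired t-test", {
  # at the calibrated sd, the noiseless effect reproduces the t quantile
  sd1 <- calibrate_sd_from_p(log10(3.2), 3.2e-8, 24)
  expect_equal(log10(3.2) / (sd1 / sqrt(24)), qt(1 - 1.6e-8, df = 23))
  # monotone: larger p => larger sd at fixed effect
  ps <- c(1e-6, 1e-4, 1e-2, 0.5)
  sds <- vapply(ps, function(p) calibrate_sd_from_p(0.3, p, 24), 0)
  expect_true(all(diff(sds) > 0))
  # p -> 0 drives sd -> 0
  expect_lt(calibrate_sd_from_p(0.505, 1e-300, 24), 1e-3)
  expect_error(calibrate_sd_from_p(0.3, 1.5, 24), "p must be")
  expect_error(calibrate_sd_from_p(0.3, 0.01, 2), "n_pairs")
  expect_error(calibrate_sd_from_p(0, 0.01, 24), "non-zero")
})

test_that("abundance generator reproduces the requested paired structure", {
  design <- study_design(24, seed = 7)
  eff <- study_effects(24)
  ab <- generate_abundance_study(design, eff, seed = 7)
  expect_s3_class(ab, "abundance_matrix")
  expect_equal(dim(ab$values), c(72, 48))
  expect_true(all(ab$values > 0))
  # same seed bit-identical; different seed different noise, same truth
  ab2 <- generate_abundance_study(design, eff, seed = 7)
  expect_identical(ab$values, ab2$values)
  ab3 <- generate_abundance_study(design, eff, seed = 8)
  expect_false(identical(ab$values, ab3$values))
  expect_identical(ab$analytes, ab3$analytes)
})

test_that("near-zero noise collapses tumor and normal to the planted shift", {
  design <- study_design(10, seed = 1)
  eff <- effect_spec(c("a", "b"), c(0, 0), c(1e-12, 1e-12))
  ab <- generate_abundance_study(design, eff, patient_sd = 0, seed = 1)
  tum <- ab$samples$group == "TUMOR"
  expect_equal(ab$values[, tum], ab$values[, !tum],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("sample mean ratio converges to the planted fold change", {
  # Monte-Carlo oracle at large n: mean(tumor)/mean(normal) -> 10^delta = 2
  design <- study_design(20000, seed = 3)
  eff <- effect_spec("a", log10(2), 0.15)
  ab <- generate_abundance_study(design, eff, seed = 3)
  fc <- fold_change(ab)
  expect_equal(fc$fc, 2.0, tolerance = 0.03)
})

test_that("empirical paired-difference SD matches the request within 3%", {
  design <- study_design(10000, seed = 5)
  s_req <- 0.22
  ab <- generate_abundance_study(design, effect_spec("a", 0.1, s_req), seed = 5)
  lg <- log10(ab$values)
  tum <- ab$samples$group == "TUMOR"
  d <- lg[1, tum][order(ab$samples$pair_id[tum])] -
    lg[1, !tum][order(ab$samples$pair_id[!tum])]
  expect_equal(sd(d), s_req, tolerance = 0.03)
})

test_that("p-values on calibrated data sit near the printed target", {
  # median p across seeds within one order of magnitude of the target
  design <- study_design(24, seed = 1)
  eff <- effect_spec("9-OAHSA", 1.7 * log10(2),
                     calibrate_sd_from_p(1.7 * log10(2), 3.2e-8, 24))
  ps <- vapply(1:100, function(s) {
    ab <- generate_abundance_study(design, eff, seed = 100 + s)
    paired_t_test(ab)$p_value
  }, 0)
  expect_lt(abs(log10(median(ps)) - log10(3.2e-8)), 1)
})

test_that("HFA generator separates DOWN from NS analytes", {
  design <- study_design(24, seed = 1)
  hits <- vapply(1:100, function(s) {
    hfa <- generate_hfa_table(design, seed = 200 + s)
    p <- paired_t_test(hfa)$p_value
    names(p) <- rownames(hfa$values)
    c(p[["9-HSA"]] < 0.05, p[["11-HSA"]] >= 0.05, p[["12-HPA"]] < 0.05)
  }, logical(3))
  expect_gte(mean(hits[1, ]), 0.9)  # DOWN flagged
  expect_gte(mean(hits[2, ]), 0.9)  # NS not flagged
  expect_gte(mean(hits[3, ]), 0.9)
  # all-NS: nothing flagged beyond alpha, huge effect at n=3 flagged
  ns <- generate_hfa_table(design, directions = c("9-HSA" = "NS"), seed = 9)
  expect_gte(paired_t_test(ns)$p_value, 0.0)
  tiny <- generate_hfa_table(study_design(3, seed = 2),
                             directions = c("12-HPA" = "DOWN"),
                             delta_down = -2, within_pair_sd = 0.05, seed = 2)
  expect_lt(paired_t_test(tiny)$p_value, 0.05)
})

test_that("chromatographic fixture plants one pair per species plus decoys", {
  spec <- chrom_fixture_spec(n_decoys = 100, seed = 1)
  fx <- generate_chrom_fixture(spec)
  expect_equal(nrow(fx$light) + nrow(fx$heavy), 72 * 2 + 100)
  expect_equal(nrow(fx$truth), 72)
  # reproducibility
  fx2 <- generate_chrom_fixture(spec)
  expect_identical(fx$light, fx2$light)
  expect_identical(fx$heavy, fx2$heavy)
  # decoys never sit within pairing tolerance of an opposite-table peak
  dec_l <- fx$light[fx$light$is_decoy, ]
  for (i in seq_len(nrow(dec_l))) {
    offs <- fx$heavy$precursor_mz - dec_l$precursor_mz[i]
    expect_false(any(abs(offs - 4.02511) <= 0.3 &
                       abs(fx$heavy$rt - dec_l$rt[i]) <= 0.05))
  }
})
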