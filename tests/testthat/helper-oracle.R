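# Independent formula-summation mass oracle: its own atomic constants and
# its own composition rules, kept separate from the package's mass path.
oracle_mass <- function(C = 0, H = 0, O = 0, N = 0, D = 0) {
  C * 12 + H * 1.007825032 + O * 15.994914620 + N * 14.003074005 +
    D * 2.014101778
}

oracle_acyl <- function(carbons, db, oh) {
  oracle_mass(C = carbons, H = 2 * carbons - 2 * db, O = if (oh) 3 else 2)
}

# Brute-force Benjamini-Hochberg step-up from the definition:
# p_(i) * m / i, cumulative minimum from the largest rank down, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Small calibrated paired study used across tests.
make_study <- function(seed = 1, n_pairs = 24) {
  design <- study_design(n_pairs, seed = seed)
  generate_abundance_study(design, study_effects(n_pairs), seed = seed)
}
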