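test_that("acyl masses match the independent formula-summation oracle", {
  expect_equal(acyl_mass(18, 1, FALSE), 282.2559, tolerance = 1e-4)
  expect_equal(acyl_mass(18, 0, TRUE), 300.2664, tolerance = 1e-4)
  expect_equal(acyl_mass(2, 0, FALSE), 60.0211, tolerance = 1e-4)
  # oracle agreement to 1e-4 Da over the whole panel (>= 20 species)
  panel <- fahfa_panel()
  expect_gte(nrow(panel), 20)
  for (i in seq_len(nrow(panel))) {
    sp <- panel_species(panel[i, ])
    expect_equal(sp$fa$mass,
                 oracle_acyl(sp$fa$carbons, sp$fa$double_bonds, FALSE),
                 tolerance = 1e-4)
    expect_equal(sp$neutral_mass,
                 oracle_acyl(sp$fa$carbons, sp$fa$double_bonds, FALSE) +
                   oracle_acyl(sp$hfa$carbons, 0, TRUE) -
                   oracle_mass(H = 2, O = 1),
                 tolerance = 1e-4)
  }
})

test_that("acyl_mass rejects impossible chains", {
  expect_error(acyl_mass(1, 0), "carbons")
  expect_error(acyl_mass(18, -1), "double_bonds")
  expect_error(acyl_mass(18, 10), "double_bonds")
})

test_that("FAHFA neutral mass is fa + hfa minus one water", {
  oahsa <- fahfa_species("OAHSA", fatty_acyl(18, 1), fatty_acyl(18, 0, TRUE))
  expect_equal(fahfa_neutral_mass(oahsa), 564.5118, tolerance = 1e-4)
  expect_equal(fahfa_neutral_mass(oahsa),
               oahsa$fa$mass + oahsa$hfa$mass - 18.0106, tolerance = 1e-4)
  pahpa <- fahfa_species("PAHPA", fatty_acyl(16, 0), fatty_acyl(16, 0, TRUE))
  # oracle value for C32H62O4 (PA + HPA - H2O)
  expect_equal(fahfa_neutral_mass(pahpa), 510.4648, tolerance = 1e-4)
  expect_error(fahfa_species("X", fatty_acyl(16, 0), fatty_acyl(16, 0, FALSE)),
               "hydroxylated")
})

test_that("ester-bond position is constrained to the HFA backbone", {
  fa <- fatty_acyl(18, 1); hfa <- fatty_acyl(18, 0, TRUE)
  expect_silent(fahfa_species("OAHSA", fa, hfa, 2))
  expect_silent(fahfa_species("OAHSA", fa, hfa, 17))
  expect_error(fahfa_species("OAHSA", fa, hfa, 1), "position")
  expect_error(fahfa_species("OAHSA", fa, hfa, 18), "position")
})

test_that("label arithmetic: shifts, 4 Da spacing, single derivatization", {
  expect_equal(label_shift("DMED"), 70.0894, tolerance = 1e-4)
  expect_equal(label_shift("d4-DMED") - label_shift("DMED"), 4.0251,
               tolerance = 1e-4)
  expect_equal(round(label_shift("d4-DMED") - label_shift("DMED")), 4)
  expect_error(label_tag("CMPI"))
  sp <- fahfa_species("OAHSA", fatty_acyl(18, 1), fatty_acyl(18, 0, TRUE))
  once <- apply_label(sp, "DMED")
  expect_equal(once$labeled_mass, sp$neutral_mass + 70.0894, tolerance = 1e-4)
  expect_error(apply_label(once, "DMED"), "already labeled")
})

test_that("OAHSA transitions reproduce the derived and printed channels", {
  sp <- fahfa_species("OAHSA", fatty_acyl(18, 1), fatty_acyl(18, 0, TRUE))
  tr <- build_transitions(sp, tags = "DMED",
                          channels = c("LOSS_FA", "LOSS_FA_45", "LOSS_FA_63"))
  fa_row <- tr[tr$channel_kind == "LOSS_FA", ]
  expect_equal(fa_row$precursor_mz, 635.6085, tolerance = 1e-4)
  expect_equal(fa_row$product_mz, 353.3526, tolerance = 1e-4)
  expect_equal(tr$product_mz[tr$channel_kind == "LOSS_FA_45"], 308.2948,
               tolerance = 1e-4)
  expect_equal(tr$product_mz[tr$channel_kind == "LOSS_FA_63"], 290.2842,
               tolerance = 1e-4)
  # printed unit-resolution instrument channels match within +/- 0.3 Da
  expect_true(matches_printed_channel(fa_row$precursor_mz, 635.5))
  expect_true(matches_printed_channel(fa_row$product_mz, 353.5))
  expect_true(matches_printed_channel(308.2948, 308.5))
  expect_error(build_transitions(sp, tags = character(0)), "tags")
  expect_error(build_transitions(sp, channels = character(0)), "channels")
})

test_that("transition tables obey the label-pair invariants across the panel", {
  tr <- panel_transitions(fahfa_panel())
  light <- tr[tr$label == "DMED", ]
  heavy <- tr[tr$label == "d4-DMED", ]
  # heavy - light precursor difference is the 4.0251 Da label spacing
  expect_equal(heavy$precursor_mz - light$precursor_mz,
               rep(4.0251, nrow(light)), tolerance = 1e-4)
  expect_true(all(round(heavy$precursor_mz - light$precursor_mz) == 4))
  # precursor - product(LOSS_FA_63) - fa mass = combined neutral loss
  panel <- fahfa_panel()
  fa_mass <- vapply(seq_len(nrow(panel)), function(i) {
    panel_species(panel[i, ])$fa$mass
  }, 0)
  l63 <- light[light$channel_kind == "LOSS_FA_63", ]
  h63 <- heavy[heavy$channel_kind == "LOSS_FA_63", ]
  nl_l <- l63$precursor_mz - l63$product_mz - fa_mass
  nl_h <- h63$precursor_mz - h63$product_mz - fa_mass
  expect_equal(nl_l, rep(label_tag("DMED")$combined_neutral_loss, nrow(l63)),
               tolerance = 2e-4)
  expect_true(all(round(nl_l) == 63))
  expect_true(all(round(nl_h) == 67))
  # heavy table equals the light table after removing the label spacing
  expect_equal(heavy$precursor_mz - 4.02511, light$precursor_mz,
               tolerance = 1e-4)
  expect_true(all(tr$product_mz < tr$precursor_mz))
})
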