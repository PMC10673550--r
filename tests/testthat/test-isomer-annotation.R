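test_that("rt_to_ri interpolates the ladder and flags extrapolation", {
  lad <- ri_ladder(rt = c(5, 10, 20), ri = c(2800, 3000, 3400))
  # calibrant identity
  expect_equal(as.numeric(rt_to_ri(10, lad)), 3000)
  # midway between calibrants at ri 2800 and 3000 -> 2900
  expect_equal(as.numeric(rt_to_ri(7.5, lad)), 2900)
  # beyond the ladder: line through the last two calibrants, flagged
  expect_warning(out <- rt_to_ri(25, lad), "extrapolated")
  expect_equal(as.numeric(out), 3400 + 5 * (3400 - 3000) / 10)
  expect_true(attr(out, "extrapolated"))
  # monotone over any grid
  grid <- seq(4, 22, by = 0.1)
  expect_true(all(diff(as.numeric(suppressWarnings(rt_to_ri(grid, lad)))) >= 0))
  expect_error(ri_ladder(rt = c(5, 4), ri = c(2800, 3000)), "increasing")
  expect_error(ri_ladder(rt = 5, ri = 2800), "length")
})

test_that("ri_to_rt is the exact inverse of rt_to_ri on the default ladder", {
  lad <- default_ri_ladder()
  ri <- c(2050, 2500, 3111, 3599)
  expect_equal(as.numeric(rt_to_ri(ri_to_rt(ri, lad), lad)), ri)
})

test_that("position-curve fit recovers the printed calibration exactly", {
  pos <- c(13, 12, 10, 9, 5)
  std <- data.frame(position = pos, ri = 10 ^ (3.50 - 0.0036 * pos))
  curve <- fit_position_curve(std, "OAHSA")
  expect_equal(curve$intercept, 3.50, tolerance = 1e-10)
  expect_equal(curve$slope, -0.0036, tolerance = 1e-10)
  expect_equal(curve$r2, 1, tolerance = 1e-10)
  expect_error(fit_position_curve(std[1:2, ]), ">= 3")
  expect_error(
    fit_position_curve(data.frame(position = c(9, 9, 9), ri = c(1, 2, 3))),
    "distinct")
})

test_that("noisy standards still recover the slope within 20%", {
  pos <- c(13, 12, 10, 9, 5)
  slopes <- vapply(1:50, function(s) {
    set.seed(s)
    std <- data.frame(position = pos,
                      ri = 10 ^ (3.50 - 0.0036 * pos + rnorm(5, 0, 0.001)))
    fit_position_curve(std, "OAHSA")$slope
  }, 0)
  expect_lt(abs(median(slopes) - (-0.0036)) / 0.0036, 0.2)
})

test_that("predict_position inverts the curve and rounds with confidence", {
  curve <- list(intercept = 3.50, slope = -0.0036)
  # the worked example: a query on the line at x = 11 is called position 11
  ann <- predict_position(curve, 10 ^ (3.50 - 0.0036 * 11))
  expect_equal(ann$position, 11L)
  expect_equal(ann$confidence, 0, tolerance = 1e-9)
  expect_false(ann$low_confidence)
  # on-line queries round-trip exactly for every position in range
  for (x in 2:17) {
    expect_equal(predict_position(curve, 10 ^ (3.50 - 0.0036 * x),
                                  max_position = 17)$position, x)
  }
  # x_hat = 0 is outside the valid backbone range
  expect_error(predict_position(curve, 10 ^ 3.50), "outside")
  expect_error(predict_position(curve, 10 ^ (3.50 - 0.0036 * 12),
                                max_position = 11), "outside")
  # off-grid query: position 9, confidence 0.4, flagged low confidence
  ann2 <- predict_position(curve, 10 ^ (3.50 - 0.0036 * 9.4))
  expect_equal(ann2$position, 9L)
  expect_equal(ann2$confidence, 0.4, tolerance = 1e-9)
  expect_true(ann2$low_confidence)
  expect_error(predict_position(list(intercept = 3.5, slope = 0), 2800),
               "slope")
})

test_that("leave-one-out regression recovers each held-out standard", {
  pos <- c(13, 12, 10, 9, 5)
  std <- data.frame(position = pos, ri = 10 ^ (3.50 - 0.0036 * pos))
  for (i in seq_along(pos)) {
    curve <- fit_position_curve(std[-i, ], "OAHSA")
    expect_equal(predict_position(curve, std$ri[i])$position, pos[i])
  }
})

test_that("standard matching picks the nearest same-family standard", {
  std <- data.frame(family = c("OAHSA", "OAHSA", "PAHPA"),
                    position = c(9, 10, 9),
                    rt = c(20.00, 20.50, 20.01))
  m <- match_standard("OAHSA", 20.02, std, rt_match_tol = 0.05)
  expect_equal(m$position, 9)
  expect_equal(m$method, "STANDARD_MATCH")
  # nothing within tolerance -> no match (caller falls back to regression)
  expect_null(match_standard("OAHSA", 20.2, std, rt_match_tol = 0.1))
  # equidistant candidates are ambiguous, never guessed
  std2 <- data.frame(family = "OAHSA", position = c(9, 10),
                     rt = c(19.95, 20.05))
  expect_error(match_standard("OAHSA", 20.00, std2, rt_match_tol = 0.1),
               "ambiguous")
})

test_that("fixture pairs annotate to their true positions end to end", {
  fx <- generate_chrom_fixture(chrom_fixture_spec(n_decoys = 0, seed = 5))
  res <- pair_peaks(fx$light, fx$heavy)
  tr <- panel_transitions(fahfa_panel(), channels = "LOSS_FA_63")
  ann <- annotate_pairs(assign_families(res$pairs, tr), fahfa_standards())
  truth <- fx$truth$species_id[match(ann$light_id, fx$truth$light_id)]
  truth_pos <- as.integer(sub("-.*", "", truth))
  got <- !is.na(ann$position)
  expect_gt(mean(got), 0.4)  # families with < 3 standards stay unannotated
  expect_equal(ann$position[got], truth_pos[got])
})
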