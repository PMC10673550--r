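# Family definitions: esterified fatty acid (FA) + hydroxy fatty acid (HFA)
# backbone. Names follow the field's convention, e.g. OAHSA = oleic acid
# ester of hydroxystearic acid.
.FAMILY_DEFS <- list(
  OAHSA  = list(fa = c(18, 1), hfa = 18),  # oleic       + OH-stearic
  POHSA  = list(fa = c(16, 1), hfa = 18),  # palmitoleic + OH-stearic
  PAHSA  = list(fa = c(16, 0), hfa = 18),  # palmitic    + OH-stearic
  SAHSA  = list(fa = c(18, 0), hfa = 18),  # stearic     + OH-stearic
  SAHMA  = list(fa = c(18, 0), hfa = 14),  # stearic     + OH-myristic
  PDAHPA = list(fa = c(15, 0), hfa = 16),  # pentadecanoic + OH-palmitic
  PAHPA  = list(fa = c(16, 0), hfa = 16),  # palmitic    + OH-palmitic
  OAHPA  = list(fa = c(18, 1), hfa = 16),  # oleic       + OH-palmitic
  PAHMA  = list(fa = c(16, 0), hfa = 14)   # palmitic    + OH-myristic
)

# Ester-bond positions per family (8 each, 72 total) and the positions for
# which an authentic standard is available. This enumeration is a synthetic
# reconstruction: it covers every named family and every differential isomer
# of the emulated breast-tissue study, but the full isomer list of that study
# is not public, so positions without standards are putative by construction.
.FAMILY_POSITIONS <- list(
  OAHSA  = list(pos = c(5, 7, 8, 9, 10, 11, 12, 13), std = c(5, 9, 10, 12, 13)),
  POHSA  = list(pos = c(5, 7, 8, 9, 10, 11, 12, 13), std = c(9, 12)),
  PAHSA  = list(pos = c(2, 5, 7, 8, 9, 10, 12, 13),  std = c(5, 9, 13)),
  SAHSA  = list(pos = c(5, 6, 7, 8, 9, 10, 12, 13),  std = c(6, 9, 12)),
  SAHMA  = list(pos = c(2, 3, 5, 6, 7, 8, 9, 10),    std = c(5, 9)),
  PDAHPA = list(pos = c(5, 6, 7, 8, 9, 11, 12, 13),  std = c(7, 12)),
  PAHPA  = list(pos = c(3, 5, 6, 7, 8, 9, 12, 13),   std = c(5, 9)),
  OAHPA  = list(pos = c(5, 6, 7, 8, 9, 10, 12, 13),  std = c(9)),
  PAHMA  = list(pos = c(2, 3, 5, 6, 7, 8, 9, 10),    std = c(5))
)

# Family-wise log10(RI) = a - b * position retention model used by the
# synthetic fixtures. OAHSA carries the authentic calibration
# (y = 3.50 - 0.0036 x); the other families' lines are plausible synthetic
# analogues in the same RI window.
.FAMILY_RI_MODEL <- data.frame(
  family = names(.FAMILY_DEFS),
  ri_intercept = c(3.50, 3.47, 3.46, 3.52, 3.40, 3.43, 3.44, 3.48, 3.41),
  ri_slope = c(0.0036, 0.0034, 0.0035, 0.0037, 0.0040, 0.0038,
               0.0036, 0.0035, 0.0039),
  stringsAsFactors = FALSE
)

#' Built-in FAHFA isomer panel (9 families, 72 isomers)
#'
#' Enumerates the species panel the synthetic fixtures and transition tables
#' are built from: 9 FAHFA families with 8 ester-bond positions each. The
#' exact isomer list of the emulated tissue study is not public; this panel
#' is a synthetic reconstruction covering all named families and every
#' differential isomer, with `has_standard` flagging positions backed by an
#' authentic standard.
#'
#' @return A data.frame with columns `species_id`, `family`, `position`,
#'   `fa_carbons`, `fa_double_bonds`, `hfa_carbons`, `neutral_mass`,
#'   `has_standard`.
#' @export
fahfa_panel <- function() {
  rows <- lapply(names(.FAMILY_DEFS), function(fam) {
    def <- .FAMILY_DEFS[[fam]]
    pp <- .FAMILY_POSITIONS[[fam]]
    fa <- fatty_acyl(def$fa[1], def$fa[2])
    hfa <- fatty_acyl(def$hfa, 0, hydroxylated = TRUE)
    data.frame(
      species_id = paste0(pp$pos, "-", fam),
      family = fam,
      position = pp$pos,
      fa_carbons = def$fa[1],
      fa_double_bonds = def$fa[2],
      hfa_carbons = def$hfa,
      neutral_mass = fa$mass + hfa$mass - WATER_MASS,
      has_standard = pp$pos %in% pp$std,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Reconstruct a [fahfa_species()] from a panel row
#'
#' @param row one-row data.frame as returned by [fahfa_panel()].
#' @export
panel_species <- function(row) {
  fahfa_species(
    family = row$family,
    fa = fatty_acyl(row$fa_carbons, row$fa_double_bonds),
    hfa = fatty_acyl(row$hfa_carbons, 0, hydroxylated = TRUE),
    position = row$position
  )
}

#' Transition table for the whole built-in panel
#'
#' @inheritParams build_transitions
#' @param panel a panel data.frame, default [fahfa_panel()].
#' @return Row-bound transitions for every panel species.
#' @export
panel_transitions <- function(panel = fahfa_panel(),
                              tags = c("DMED", "d4-DMED"),
                              channels = c("LOSS_FA", "LOSS_FA_45", "LOSS_FA_63"),
                              nominal = FALSE) {
  out <- lapply(seq_len(nrow(panel)), function(i) {
    build_transitions(panel_species(panel[i, ]), tags = tags,
                      channels = channels, nominal = nominal)
  })
  do.call(rbind, out)
}

#' Family-wise synthetic retention model
#'
#' log10(RI) = `ri_intercept` - `ri_slope` * position, per family. The OAHSA
#' line is the authentic calibration used for position prediction; the other
#' families use synthetic analogues (the fixtures' ground truth).
#' @return data.frame with `family`, `ri_intercept`, `ri_slope`.
#' @export
family_ri_model <- function() .FAMILY_RI_MODEL

#' True retention index of a panel species under the synthetic model
#'
#' @param family family name.
#' @param position ester-bond position.
#' @export
species_ri <- function(family, position) {
  m <- .FAMILY_RI_MODEL[match(family, .FAMILY_RI_MODEL$family), ]
  if (any(is.na(m$family))) stop("unknown family")
  10 ^ (m$ri_intercept - m$ri_slope * position)
}

#' Authentic-standard table for the built-in panel
#'
#' One row per panel species with `has_standard = TRUE`, carrying its true
#' retention index and the retention time implied by `ladder`.
#'
#' @param ladder an [ri_ladder()]; default [default_ri_ladder()].
#' @return data.frame with `species_id`, `family`, `position`, `ri`, `rt`.
#' @export
fahfa_standards <- function(ladder = default_ri_ladder()) {
  p <- fahfa_panel()
  p <- p[p$has_standard, ]
  ri <- species_ri(p$family, p$position)
  data.frame(
    species_id = p$species_id,
    family = p$family,
    position = p$position,
    ri = ri,
    rt = ri_to_rt(ri, ladder),
    stringsAsFactors = FALSE
  )
}

#' Differential effect panel of the emulated tissue study
#'
#' The 13 FAHFA isomers reported as significantly altered between paired
#' breast tumor and adjacent normal tissue (24 patients), with their
#' reported log2 fold changes (tumor / normal) and paired-t p-values. These
#' are the planted effects the synthetic abundance study reproduces; the
#' log2FC column is used (higher precision than the rounded FC column).
#'
#' @return data.frame with `analyte_id`, `family`, `position`, `log2_fc`,
#'   `p_value`, `regulation`, and the implied `delta_log10`
#'   (`log2_fc * log10(2)`).
#' @export
bc_effect_panel <- function() {
  d <- data.frame(
    analyte_id = c("9-OAHSA", "11-OAHSA", "5-SAHMA", "13-OAHSA", "9-POHSA",
                   "6-SAHSA", "12-PDAHPA", "7-PDAHPA", "8-PDAHPA",
                   "13-PDAHPA", "6-PDAHPA", "11-PDAHPA", "3-PAHPA"),
    family = c("OAHSA", "OAHSA", "SAHMA", "OAHSA", "POHSA", "SAHSA",
               "PDAHPA", "PDAHPA", "PDAHPA", "PDAHPA", "PDAHPA", "PDAHPA",
               "PAHPA"),
    position = c(9L, 11L, 5L, 13L, 9L, 6L, 12L, 7L, 8L, 13L, 6L, 11L, 3L),
    log2_fc = c(1.7, 1.7, 1.4, 1.1, 1.0, 1.4, -1.0, -0.8, -0.9, -0.8,
                -0.7, -0.7, -0.6),
    p_value = c(3.2e-8, 1.7e-6, 1.1e-4, 1.2e-4, 5.6e-4, 8.8e-3, 1.2e-7,
                1.1e-6, 3.7e-6, 5.4e-6, 3.0e-4, 6.6e-4, 3.2e-3),
    stringsAsFactors = FALSE
  )
  d$regulation <- ifelse(d$log2_fc > 0, "up", "down")
  d$delta_log10 <- d$log2_fc * log10(2)
  d
}
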