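#' Monoisotopic mass of a (hydroxy) fatty acyl chain
#'
#' A plain fatty acid with `c` carbons and `d` double bonds has formula
#' C_c H_(2c-2d) O_2; its hydroxylated analogue carries one extra oxygen
#' (C_c H_(2c-2d) O_3).
#'
#' @param carbons integer chain length, >= 2.
#' @param double_bonds integer number of C=C double bonds.
#' @param hydroxylated logical; `TRUE` for a hydroxy fatty acid.
#' @return Monoisotopic mass in Da.
#' @examples
#' acyl_mass(18, 1, FALSE) # oleic acid, 282.2559
#' acyl_mass(18, 0, TRUE)  # hydroxystearic acid, 300.2664
#' @export
acyl_mass <- function(carbons, double_bonds = 0, hydroxylated = FALSE) {
  if (carbons < 2) stop("carbons must be >= 2")
  if (double_bonds < 0) stop("double_bonds must be >= 0")
  if (2 * double_bonds > carbons) {
    stop("double_bonds must be <= carbons/2")
  }
  formula_mass(c(
    C = carbons,
    H = 2 * carbons - 2 * double_bonds,
    O = if (hydroxylated) 3 else 2
  ))
}

#' Construct a fatty acyl component
#'
#' @inheritParams acyl_mass
#' @return A `fatty_acyl` object: carbons, double bonds, hydroxylation flag,
#'   elemental formula and monoisotopic mass.
#' @export
fatty_acyl <- function(carbons, double_bonds = 0, hydroxylated = FALSE) {
  mass <- acyl_mass(carbons, double_bonds, hydroxylated)
  structure(
    list(
      carbons = as.integer(carbons),
      double_bonds = as.integer(double_bonds),
      hydroxylated = isTRUE(hydroxylated),
      formula = c(
        C = carbons,
        H = 2 * carbons - 2 * double_bonds,
        O = if (hydroxylated) 3 else 2
      ),
      mass = mass
    ),
    class = "fatty_acyl"
  )
}

#' Construct a FAHFA species
#'
#' A FAHFA is a fatty acid (FA) esterified to the hydroxyl of a hydroxy
#' fatty acid (HFA); esterification releases one water, so the neutral mass
#' is `fa + hfa - H2O`. The ester-bond position is the HFA backbone carbon
#' carrying the ester; regioisomers differ only in this position.
#'
#' @param family short family name, e.g. `"OAHSA"`.
#' @param fa a [fatty_acyl()] (the esterified fatty acid).
#' @param hfa a hydroxylated [fatty_acyl()] (the backbone).
#' @param position integer ester-bond position, or `NA` if unknown. Known
#'   positions must lie in `[2, hfa$carbons - 1]`.
#' @return A `fahfa_species` object with `neutral_mass` in Da.
#' @examples
#' oahsa <- fahfa_species("OAHSA", fatty_acyl(18, 1), fatty_acyl(18, 0, TRUE), 9)
#' oahsa$neutral_mass # 564.5118
#' @export
fahfa_species <- function(family, fa, hfa, position = NA_integer_) {
  stopifnot(inherits(fa, "fatty_acyl"), inherits(hfa, "fatty_acyl"))
  if (!hfa$hydroxylated) stop("hfa must be hydroxylated")
  if (!is.na(position) && (position < 2 || position > hfa$carbons - 1)) {
    stop("position must be in [2, hfa$carbons - 1]")
  }
  structure(
    list(
      family = family,
      fa = fa,
      hfa = hfa,
      position = as.integer(position),
      neutral_mass = fa$mass + hfa$mass - WATER_MASS,
      label = NULL
    ),
    class = "fahfa_species"
  )
}

#' Neutral monoisotopic mass of a FAHFA
#'
#' @param species a [fahfa_species()].
#' @return `fa$mass + hfa$mass - mass(H2O)` in Da.
#' @export
fahfa_neutral_mass <- function(species) {
  stopifnot(inherits(species, "fahfa_species"))
  species$fa$mass + species$hfa$mass - WATER_MASS
}

# DMED = N,N-dimethylethylenediamine, C4H12N2; amide formation on the free
# carboxyl expels one water. The heavy reagent carries four deuteriums on the
# N,N-dimethyl end, i.e. on the fragment later lost as dimethylamine, so the
# combined neutral loss is 63 Da (light) and 67 Da (heavy) at unit resolution.
.DMED_MASS <- 4 * 12 + 12 * 1.00782503207 + 2 * 14.0030740048
.DIMETHYLAMINE_MASS <- 2 * 12 + 7 * 1.00782503207 + 14.0030740048
.D4_SHIFT <- 4 * (2.01410177785 - 1.00782503207)

#' Construct a carboxyl-labeling tag (DMED or d4-DMED)
#'
#' `mass_shift` is the derivatization mass added to the analyte (amide
#' formation: reagent minus water). `amine_loss` is the dimethylamine
#' fragment expelled on collision-induced dissociation;
#' `combined_neutral_loss` adds one water (nominal 63 Da light, 67 Da heavy).
#'
#' @param name `"DMED"` or `"d4-DMED"`.
#' @return A `label_tag` object.
#' @examples
#' label_tag("DMED")$combined_neutral_loss # 63.0684
#' @export
label_tag <- function(name = c("DMED", "d4-DMED")) {
  name <- match.arg(name)
  d <- if (name == "d4-DMED") .D4_SHIFT else 0
  amine <- .DIMETHYLAMINE_MASS + d
  structure(
    list(
      name = name,
      mass_shift = .DMED_MASS - WATER_MASS + d,
      amine_loss = amine,
      combined_neutral_loss = amine + WATER_MASS
    ),
    class = "label_tag"
  )
}

#' Derivatization mass shift of a labeling tag
#'
#' @param tag a [label_tag()] or a tag name.
#' @return Mass shift in Da (DMED +70.0895, d4-DMED +74.1146).
#' @export
label_shift <- function(tag) {
  if (is.character(tag)) tag <- label_tag(tag)
  stopifnot(inherits(tag, "label_tag"))
  tag$mass_shift
}

#' Apply a labeling tag to a species
#'
#' Each FAHFA has exactly one free carboxyl, so a species can carry at most
#' one label; labeling an already-labeled species is an error.
#'
#' @param species a [fahfa_species()].
#' @param tag a [label_tag()] or tag name.
#' @return The species with the label attached and `labeled_mass` set.
#' @export
apply_label <- function(species, tag) {
  stopifnot(inherits(species, "fahfa_species"))
  if (!is.null(species$label)) {
    stop("species is already labeled (one free carboxyl per FAHFA)")
  }
  if (is.character(tag)) tag <- label_tag(tag)
  species$label <- tag
  species$labeled_mass <- species$neutral_mass + tag$mass_shift
  species
}

#' Build MRM transitions for a labeled FAHFA
#'
#' The precursor is the protonated derivatized species,
#' `neutral + label_shift + 1.00728`. Product channels:
#' \describe{
#'   \item{LOSS_FA}{precursor minus the esterified fatty acid.}
#'   \item{LOSS_FA_45}{additionally loses dimethylamine (nominal 45 Da;
#'     49 Da for the heavy label).}
#'   \item{LOSS_FA_63}{additionally loses dimethylamine plus water
#'     (nominal 63 Da light / 67 Da heavy) — the screening daughter.}
#' }
#' m/z values are reported to 4 decimals. With `nominal = TRUE` the table
#' also carries unit-resolution channel values (1 decimal) for comparison
#' with printed instrument settings; such comparisons should use a
#' ±0.3 Da tolerance (see [matches_printed_channel()]) because printed
#' quadrupole channels sit slightly above exact monoisotopic values.
#'
#' @param species a [fahfa_species()] (position may be unknown; it does not
#'   affect masses).
#' @param tags character vector of tag names, subset of
#'   `c("DMED", "d4-DMED")`.
#' @param channels character vector, subset of
#'   `c("LOSS_FA", "LOSS_FA_45", "LOSS_FA_63")`.
#' @param collision_energy pass-through instrument setting.
#' @param nominal logical; add unit-resolution columns.
#' @return A data.frame with one row per tag x channel: `species_id`,
#'   `family`, `position`, `label`, `precursor_mz`, `product_mz`,
#'   `channel_kind`, `collision_energy`.
#' @examples
#' oahsa <- fahfa_species("OAHSA", fatty_acyl(18, 1), fatty_acyl(18, 0, TRUE))
#' build_transitions(oahsa, "DMED", "LOSS_FA") # 635.6085 > 353.3526
#' @export
build_transitions <- function(species,
                              tags = c("DMED", "d4-DMED"),
                              channels = c("LOSS_FA", "LOSS_FA_45", "LOSS_FA_63"),
                              collision_energy = NA_real_,
                              nominal = FALSE) {
  stopifnot(inherits(species, "fahfa_species"))
  if (length(tags) == 0) stop("tags must be non-empty")
  if (length(channels) == 0) stop("channels must be non-empty")
  channels <- match.arg(channels, c("LOSS_FA", "LOSS_FA_45", "LOSS_FA_63"),
                        several.ok = TRUE)
  grid <- expand.grid(label = tags, channel_kind = channels,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tag <- label_tag(grid$label[i])
    precursor <- species$neutral_mass + tag$mass_shift + PROTON_MASS
    extra_loss <- switch(grid$channel_kind[i],
      LOSS_FA = 0,
      LOSS_FA_45 = tag$amine_loss,
      LOSS_FA_63 = tag$combined_neutral_loss
    )
    product <- precursor - species$fa$mass - extra_loss
    data.frame(
      species_id = species_id(species),
      family = species$family,
      position = species$position,
      label = tag$name,
      precursor_mz = round(precursor, 4),
      product_mz = round(product, 4),
      channel_kind = grid$channel_kind[i],
      collision_energy = collision_energy,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (nominal) {
    out$precursor_nominal <- round(out$precursor_mz, 1)
    out$product_nominal <- round(out$product_mz, 1)
  }
  out
}

#' Identifier for a species: "<position>-<family>" or "<family>"
#' @param species a [fahfa_species()].
#' @export
species_id <- function(species) {
  if (is.na(species$position)) species$family
  else paste0(species$position, "-", species$family)
}

#' Compare an exact m/z against a printed unit-resolution channel
#'
#' Printed quadrupole channel settings typically sit 0.1-0.3 Da above the
#' exact monoisotopic value; matching uses an absolute tolerance.
#'
#' @param mz exact m/z (Da).
#' @param printed printed channel value (Da).
#' @param tol tolerance (Da), default 0.3.
#' @export
matches_printed_channel <- function(mz, printed, tol = 0.3) {
  abs(mz - printed) <= tol
}

#' Write a transition table as tab-separated text
#'
#' @param transitions data.frame from [build_transitions()] (possibly
#'   row-bound over a panel).
#' @param path output file.
#' @export
write_transition_table <- function(transitions, path) {
  write_tsv(transitions, path)
  invisible(path)
}
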