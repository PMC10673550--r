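# Monoisotopic atomic masses (Da), IUPAC/CODATA values.
.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  D = 2.01410177785,
  N = 14.0030740048,
  O = 15.9949146196
)

#' Monoisotopic mass of a proton, Da
#'
#' Used for the `[M+H]+` adduct in positive-ion ESI (proton mass, not the
#' mass of a hydrogen atom).
#' @export
PROTON_MASS <- 1.00727646688

#' Monoisotopic mass of water, Da
#' @export
WATER_MASS <- 2 * 1.00782503207 + 15.9949146196

#' Monoisotopic mass of an elemental formula
#'
#' Sums monoisotopic atomic masses over an element -> count map. Supported
#' elements: C, H, D (deuterium), N, O.
#'
#' @param formula named numeric vector of element counts,
#'   e.g. `c(C = 18, H = 34, O = 2)`.
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass(c(C = 18, H = 34, O = 2)) # oleic acid, 282.2559
#' @export
formula_mass <- function(formula) {
  stopifnot(is.numeric(formula), !is.null(names(formula)))
  unknown <- setdiff(names(formula), names(.ATOMIC_MASS))
  if (length(unknown) > 0) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  }
  if (any(formula < 0)) stop("negative element counts")
  sum(.ATOMIC_MASS[names(formula)] * formula)
}
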