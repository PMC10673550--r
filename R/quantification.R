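#' Analyte-by-sample relative-abundance matrix
#'
#' Container for unitless light/heavy peak-height ratios with paired-sample
#' metadata. Missing cells are `NA` (never zero); all observed abundances
#' must be positive.
#'
#' @param values numeric matrix, analytes in rows, samples in columns.
#' @param samples data.frame with `sample_id`, `group`
#'   (`"TUMOR"`/`"NORMAL"`) and `pair_id`; every pair must appear once in
#'   each group.
#' @param analytes optional analyte metadata data.frame (first column
#'   `analyte_id`).
#' @return An `abundance_matrix` object.
#' @export
abundance_matrix <- function(values, samples, analytes = NULL) {
  stopifnot(is.matrix(values), ncol(values) == nrow(samples),
            all(c("sample_id", "group", "pair_id") %in% names(samples)))
  if (any(values <= 0, na.rm = TRUE)) stop("abundances must be positive")
  tab <- table(samples$pair_id, samples$group)
  if (!all(tab == 1)) stop("every pair_id must appear exactly once per group")
  if (is.null(analytes)) {
    analytes <- data.frame(analyte_id = rownames(values),
                           stringsAsFactors = FALSE)
  }
  structure(list(values = values, samples = samples, analytes = analytes),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d analytes x %d samples (%d pairs), %d missing cells\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$pair_id)), sum(is.na(x$values))))
  invisible(x)
}

#' Relative abundance as a light/heavy peak-height ratio
#'
#' @param light_height analyte (DMED-labeled) peak height.
#' @param is_height internal-standard (d4-DMED-labeled) peak height.
#' @return `light_height / is_height`.
#' @export
abundance_ratio <- function(light_height, is_height) {
  if (any(light_height <= 0) || any(is_height <= 0)) {
    stop("peak heights must be positive")
  }
  light_height / is_height
}

#' Assign an internal standard to an analyte
#'
#' An exact family+position match uses the authentic standard itself
#' (surrogate = FALSE). Otherwise the same-family standard with the closest
#' ester-bond position serves as surrogate, ties broken toward the lower
#' position number (fixed, documented tie-break). No same-family standard
#' means the analyte is unquantifiable.
#'
#' @param family,position analyte family and ester-bond position.
#' @param standards data.frame with `family` and `position` of available
#'   standards.
#' @return A list: `standard_family`, `standard_position`, `surrogate`; or
#'   an error `"UNQUANTIFIABLE"` if no same-family standard exists.
#' @examples
#' std <- data.frame(family = "OAHSA", position = c(13, 12, 10, 9, 5))
#' assign_internal_standard("OAHSA", 11, std) # 10-OAHSA, surrogate
#' @export
assign_internal_standard <- function(family, position, standards) {
  if (nrow(standards) == 0) stop("standards list is empty")
  fam <- standards[standards$family == family, ]
  if (nrow(fam) == 0) {
    stop("UNQUANTIFIABLE: no same-family standard for ", family)
  }
  d <- abs(fam$position - position)
  cand <- fam$position[d == min(d)]
  best <- min(cand)  # tie -> lower position
  list(standard_family = family, standard_position = best,
       standard_id = paste0(best, "-", family),
       surrogate = best != position)
}

#' Build an abundance matrix from per-sample peak heights
#'
#' Takes a long table of annotated analyte peaks with their assigned
#' internal-standard peaks and computes light/heavy height ratios. An
#' absent IS peak makes the cell missing (`NA`, with a warning), never
#' zero; analytes missing in more than `max_missing` of samples are dropped
#' with a message.
#'
#' @param peaks long data.frame: `analyte_id`, `sample_id`, `light_height`,
#'   `is_height` (NA where a peak was not observed).
#' @param samples sample metadata (`sample_id`, `group`, `pair_id`).
#' @param analytes optional analyte metadata.
#' @param max_missing drop threshold, fraction of samples (default 0.5).
#' @return An `abundance_matrix`.
#' @export
build_abundance_matrix <- function(peaks, samples, analytes = NULL,
                                   max_missing = 0.5) {
  stopifnot(all(c("analyte_id", "sample_id", "light_height", "is_height")
                %in% names(peaks)))
  ids <- unique(peaks$analyte_id)
  values <- matrix(NA_real_, length(ids), nrow(samples),
                   dimnames = list(ids, samples$sample_id))
  ok <- !is.na(peaks$light_height) & !is.na(peaks$is_height)
  if (any(!ok)) {
    warning(sum(!ok), " cell(s) missing an analyte or IS peak; recorded as NA")
  }
  pk <- peaks[ok, ]
  values[cbind(match(pk$analyte_id, ids),
               match(pk$sample_id, samples$sample_id))] <-
    abundance_ratio(pk$light_height, pk$is_height)
  frac_missing <- rowMeans(is.na(values))
  drop <- frac_missing > max_missing
  if (any(drop)) {
    message("dropping ", sum(drop), " analyte(s) missing in > ",
            max_missing * 100, "% of samples: ",
            paste(ids[drop], collapse = ", "))
    values <- values[!drop, , drop = FALSE]
    if (!is.null(analytes)) analytes <- analytes[!drop, , drop = FALSE]
  }
  abundance_matrix(values, samples, analytes)
}

#' Simulate per-sample peak heights from an abundance study
#'
#' Bridges the abundance generator to the quantification stage: the heavy
#' internal-standard peak is spiked at a fixed height and the light analyte
#' peak height is `abundance * is_height`, so quantification should recover
#' the generated matrix exactly at zero noise.
#'
#' @param ab an `abundance_matrix` (ground truth).
#' @param is_height spiked IS peak height (default 1e4).
#' @param height_noise_sd lognormal (log10) measurement noise applied to
#'   both peaks of a cell; default 0 (noise-free).
#' @param seed RNG seed, used when `height_noise_sd > 0`.
#' @return Long peaks data.frame suitable for [build_abundance_matrix()].
#' @export
simulate_sample_heights <- function(ab, is_height = 1e4,
                                    height_noise_sd = 0, seed = 1) {
  stopifnot(inherits(ab, "abundance_matrix"))
  long <- expand.grid(analyte_id = rownames(ab$values),
                      sample_id = colnames(ab$values),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  abv <- ab$values[cbind(match(long$analyte_id, rownames(ab$values)),
                         match(long$sample_id, colnames(ab$values)))]
  long$is_height <- is_height
  long$light_height <- abv * is_height
  if (height_noise_sd > 0) {
    local_seed(seed, {
      long$light_height <- long$light_height *
        10 ^ stats::rnorm(nrow(long), 0, height_noise_sd)
      long$is_height <- long$is_height *
        10 ^ stats::rnorm(nrow(long), 0, height_noise_sd)
    })
  }
  long
}
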