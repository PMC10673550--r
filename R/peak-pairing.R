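# Light/heavy label mass difference: 4 x (m(2H) - m(1H)).
LABEL_MASS_DELTA <- 4 * (2.01410177785 - 1.00782503207)

#' Pair co-eluting light/heavy labeled peaks
#'
#' A light and a heavy peak form a candidate pair when all three criteria
#' hold: precursor offset within `mz_tol` of the 4.0251 Da label difference,
#' retention times within `rt_tol`, and |log2(light/heavy height)| within
#' `max_log2_ratio` (1:1 mixing of the labeled aliquots makes true pairs
#' near-equal in intensity). Candidates are resolved greedily by smallest
#' |delta RT|, ties by smallest |log2 ratio|; each peak joins at most one
#' pair. Unpaired peaks are returned separately.
#'
#' @param light,heavy peak tables with `peak_id`, `precursor_mz`, `rt`,
#'   `height` (and optionally `product_mz`, carried through).
#' @param mz_tol precursor tolerance, Da (default 0.3).
#' @param rt_tol co-elution tolerance, minutes (default 0.05).
#' @param max_log2_ratio intensity band, |log2(light/heavy)| (default
#'   0.585, i.e. ratio within \[2/3, 3/2\]).
#' @param label_delta expected heavy-minus-light precursor offset
#'   (default +4.0251 Da; negate to swap table roles).
#' @return A list: `pairs` (one row per pair with `delta_rt`,
#'   `height_ratio` = light/heavy and both peaks' fields) and `unpaired`
#'   (peaks with the table they came from).
#' @export
pair_peaks <- function(light, heavy, mz_tol = 0.3, rt_tol = 0.05,
                       max_log2_ratio = 0.585,
                       label_delta = LABEL_MASS_DELTA) {
  stopifnot(nrow(light) > 0, nrow(heavy) > 0)
  if (mz_tol <= 0 || rt_tol <= 0 || max_log2_ratio <= 0) {
    warning("degenerate (non-positive) tolerance: no pairs can form")
  }
  cand <- expand.grid(li = seq_len(nrow(light)), hi = seq_len(nrow(heavy)),
                      KEEP.OUT.ATTRS = FALSE)
  dmz <- heavy$precursor_mz[cand$hi] - light$precursor_mz[cand$li] - label_delta
  drt <- heavy$rt[cand$hi] - light$rt[cand$li]
  lratio <- log2(light$height[cand$li] / heavy$height[cand$hi])
  keep <- abs(dmz) <= mz_tol & abs(drt) <= rt_tol & abs(lratio) <= max_log2_ratio
  cand <- cand[keep, , drop = FALSE]
  drt <- drt[keep]; lratio <- lratio[keep]
  ord <- order(abs(drt), abs(lratio))
  cand <- cand[ord, , drop = FALSE]
  drt <- drt[ord]; lratio <- lratio[ord]
  used_l <- logical(nrow(light)); used_h <- logical(nrow(heavy))
  take <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!used_l[cand$li[i]] && !used_h[cand$hi[i]]) {
      take[i] <- TRUE
      used_l[cand$li[i]] <- TRUE
      used_h[cand$hi[i]] <- TRUE
    }
  }
  sel <- cand[take, , drop = FALSE]
  pairs <- data.frame(
    light_id = light$peak_id[sel$li],
    heavy_id = heavy$peak_id[sel$hi],
    light_mz = light$precursor_mz[sel$li],
    heavy_mz = heavy$precursor_mz[sel$hi],
    light_product_mz = if ("product_mz" %in% names(light))
      light$product_mz[sel$li] else NA_real_,
    rt = light$rt[sel$li],
    delta_rt = drt[take],
    height_ratio = 2 ^ lratio[take],
    light_height = light$height[sel$li],
    heavy_height = heavy$height[sel$hi],
    stringsAsFactors = FALSE
  )
  unpaired <- data.frame(
    table = c(rep("light", sum(!used_l)), rep("heavy", sum(!used_h))),
    peak_id = c(light$peak_id[!used_l], heavy$peak_id[!used_h]),
    stringsAsFactors = FALSE
  )
  list(pairs = pairs, unpaired = unpaired)
}

#' Assign FAHFA families to peak pairs from their MRM channel
#'
#' Matches each pair's light precursor and product m/z against the panel's
#' light transitions within `tol` on both. Regioisomers of one family share
#' a channel, so a unique family with several candidate positions is the
#' normal outcome; matches to more than one family are returned as
#' ambiguous (never silently chosen), and no match yields `"UNASSIGNED"`.
#'
#' @param pairs pair table from [pair_peaks()] (needs `light_mz`,
#'   `light_product_mz`).
#' @param transitions light transition table
#'   ([panel_transitions()] output, one channel).
#' @param tol m/z tolerance, Da (default 0.3, unit-resolution convention).
#' @return `pairs` with added `family` (`"UNASSIGNED"` / `"AMBIGUOUS"` on
#'   no/multiple family matches) and `candidate_positions` (comma-joined).
#' @export
assign_families <- function(pairs, transitions, tol = 0.3) {
  tr <- transitions[transitions$label == "DMED", ]
  fam <- character(nrow(pairs))
  cand <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    hit <- abs(tr$precursor_mz - pairs$light_mz[i]) <= tol &
      abs(tr$product_mz - pairs$light_product_mz[i]) <= tol
    fams <- unique(tr$family[hit])
    if (length(fams) == 0) {
      fam[i] <- "UNASSIGNED"; cand[i] <- ""
    } else if (length(fams) > 1) {
      fam[i] <- "AMBIGUOUS"
      cand[i] <- paste(sort(fams), collapse = ",")
    } else {
      fam[i] <- fams
      cand[i] <- paste(sort(unique(tr$position[hit])), collapse = ",")
    }
  }
  pairs$family <- fam
  pairs$candidate_positions <- cand
  pairs
}

#' Score detected pairs against a ground-truth sidecar
#'
#' @param pairs pair table from [pair_peaks()].
#' @param truth sidecar from [generate_chrom_fixture()].
#' @return A list: `recall`, `precision`, `n_true_recovered`,
#'   `n_decoy_pairs`.
#' @export
score_pairs <- function(pairs, truth) {
  key <- paste(pairs$light_id, pairs$heavy_id)
  true_key <- paste(truth$light_id, truth$heavy_id)
  n_true <- sum(key %in% true_key)
  list(
    recall = n_true / nrow(truth),
    precision = if (nrow(pairs) > 0) n_true / nrow(pairs) else NA_real_,
    n_true_recovered = n_true,
    n_decoy_pairs = nrow(pairs) - n_true
  )
}
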