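#' Transform an abundance matrix for statistics
#'
#' Returns the log10 matrix (used by the paired tests) and the per-analyte
#' z-scored log10 matrix (used by the multivariate step and heatmaps).
#' Fold changes are always computed from the untransformed matrix.
#' Zero-variance analytes cannot be z-scored; they are flagged `CONSTANT`
#' and excluded from the z matrix. z-scoring divides by the population SD
#' (root mean squared deviation), so a row like log10 {0, 1, 2} maps to
#' {-1.2247, 0, 1.2247}.
#'
#' @param ab an `abundance_matrix`.
#' @return A list: `log10` (all analytes), `z` (non-constant analytes,
#'   rows with mean 0 / population sd 1), `constant` (flagged analyte ids).
#' @export
preprocess <- function(ab) {
  stopifnot(inherits(ab, "abundance_matrix"))
  lg <- log10(ab$values)
  mu <- rowMeans(lg, na.rm = TRUE)
  pop_sd <- sqrt(rowMeans((lg - mu)^2, na.rm = TRUE))
  constant <- rownames(lg)[is.na(pop_sd) | pop_sd == 0]
  keep <- !(rownames(lg) %in% constant)
  z <- (lg[keep, , drop = FALSE] - mu[keep]) / pop_sd[keep]
  list(log10 = lg, z = z, constant = constant)
}

#' Per-analyte fold change, tumor over normal
#'
#' `fc = mean(tumor) / mean(normal)` on the untransformed abundance scale,
#' with `log2_fc = log2(fc)`. Missing cells are excluded per analyte.
#'
#' @param ab an `abundance_matrix`.
#' @return data.frame with `analyte_id`, `fc`, `log2_fc`.
#' @export
fold_change <- function(ab) {
  stopifnot(inherits(ab, "abundance_matrix"))
  tum <- ab$samples$group == "TUMOR"
  if (!any(tum) || all(tum)) stop("both groups must be non-empty")
  fc <- rowMeans(ab$values[, tum, drop = FALSE], na.rm = TRUE) /
    rowMeans(ab$values[, !tum, drop = FALSE], na.rm = TRUE)
  data.frame(analyte_id = rownames(ab$values), fc = unname(fc),
             log2_fc = unname(log2(fc)), stringsAsFactors = FALSE)
}

#' Paired two-sided Student's t-test per analyte
#'
#' Tests the paired tumor-minus-normal differences of log10 abundances
#' (tissues are patient-matched). Implemented as a vectorized rowwise
#' computation. Analytes with fewer than 3 complete pairs get `p = NA`.
#' Degenerate cases: all differences zero gives `p = 1` by convention;
#' zero-variance nonzero differences give the smallest representable p.
#' An unpaired Welch test is available via `paired = FALSE`.
#'
#' @param ab an `abundance_matrix`.
#' @param paired logical, default TRUE (matched design).
#' @return data.frame with `analyte_id`, `t`, `df`, `p_value`.
#' @export
paired_t_test <- function(ab, paired = TRUE) {
  stopifnot(inherits(ab, "abundance_matrix"))
  lg <- log10(ab$values)
  tum <- ab$samples$group == "TUMOR"
  if (!paired) {
    res <- t(apply(lg, 1, function(x) {
      ok <- !is.na(x)
      if (sum(ok & tum) < 2 || sum(ok & !tum) < 2) return(c(NA, NA, NA))
      tt <- stats::t.test(x[tum], x[!tum])
      c(tt$statistic, tt$parameter, tt$p.value)
    }))
    return(data.frame(analyte_id = rownames(lg), t = res[, 1], df = res[, 2],
                      p_value = res[, 3], stringsAsFactors = FALSE))
  }
  pid <- ab$samples$pair_id
  ord_t <- order(pid[tum]); ord_n <- order(pid[!tum])
  d <- lg[, tum, drop = FALSE][, ord_t, drop = FALSE] -
    lg[, !tum, drop = FALSE][, ord_n, drop = FALSE]
  n_ok <- rowSums(!is.na(d))
  m <- rowMeans(d, na.rm = TRUE)
  s <- apply(d, 1, stats::sd, na.rm = TRUE)
  tstat <- m / (s / sqrt(n_ok))
  p <- 2 * stats::pt(-abs(tstat), df = n_ok - 1)
  zero_var <- !is.na(s) & s == 0
  if (any(zero_var & m == 0)) {
    message(sum(zero_var & m == 0), " analyte(s) with all-zero differences; p = 1")
    p[zero_var & m == 0] <- 1
  }
  if (any(zero_var & m != 0)) {
    message(sum(zero_var & m != 0),
            " analyte(s) with zero-variance nonzero differences; p set to minimum")
    p[zero_var & m != 0] <- .Machine$double.xmin
  }
  p[n_ok < 3] <- NA_real_
  data.frame(analyte_id = rownames(lg), t = unname(tstat),
             df = unname(n_ok - 1), p_value = unname(p),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment over all tested analytes; `NA` p-values are excluded
#' from the test count and passed through as `NA`.
#'
#' @param p numeric vector of p-values.
#' @return Adjusted p-values, same length/order.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Volcano selection: fold-change and significance filter
#'
#' Selects analytes with `p < p_threshold` and fold change outside
#' `[1/fc_threshold, fc_threshold]`, recording the direction.
#'
#' @param fc,p per-analyte fold changes and p-values (aligned).
#' @param fc_threshold fold-change cut (default 1.5).
#' @param p_threshold significance cut (default 0.05).
#' @return data.frame with `selected` and `direction`
#'   (`"UP"`/`"DOWN"`/`"NS"`).
#' @export
volcano_select <- function(fc, p, fc_threshold = 1.5, p_threshold = 0.05) {
  sel <- !is.na(p) & p < p_threshold &
    (fc > fc_threshold | fc < 1 / fc_threshold)
  data.frame(
    selected = sel,
    direction = ifelse(!sel, "NS", ifelse(fc > 1, "UP", "DOWN")),
    stringsAsFactors = FALSE
  )
}

#' Venn intersection of the VIP and volcano selections
#'
#' The differential set is the intersection of the multivariate selection
#' (VIP > 1) and the univariate volcano selection, with regulation labels
#' from the fold-change sign.
#'
#' @param vip_ids analytes with VIP above threshold.
#' @param volcano_ids analytes passing the volcano filter.
#' @param fc named fold-change vector over the analyte universe.
#' @return data.frame with `analyte_id` and `regulation` (`"UP"`/`"DOWN"`).
#' @export
venn_intersect <- function(vip_ids, volcano_ids, fc) {
  ids <- intersect(vip_ids, volcano_ids)
  data.frame(analyte_id = ids,
             regulation = ifelse(fc[ids] > 1, "UP", "DOWN"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full differential workflow
#'
#' Runs preprocess -> paired t + BH FDR -> fold change -> volcano filter ->
#' OPLS-DA VIP -> Venn intersection, returning one record per analyte in
#' the conventional report shape (analyte, VIP, FC, log2FC, p, FDR,
#' regulation) plus set memberships and the fitted OPLS-DA model.
#'
#' @param ab an `abundance_matrix`.
#' @param fc_threshold,p_threshold,vip_threshold selection thresholds
#'   (defaults 1.5, 0.05, 1.0).
#' @param n_orthogonal orthogonal OPLS-DA components (default 1).
#' @param cv logical; compute Q2 by 7-fold cross-validation (default TRUE).
#' @param seed seed for the CV fold assignment.
#' @return A list: `records` (per-analyte data.frame), `model`
#'   (the `opls_model`), `venn` (differential set with regulation).
#' @export
run_differential <- function(ab, fc_threshold = 1.5, p_threshold = 0.05,
                             vip_threshold = 1.0, n_orthogonal = 1,
                             cv = TRUE, seed = 1) {
  pp <- preprocess(ab)
  tt <- paired_t_test(ab)
  fc <- fold_change(ab)
  fdr <- fdr_adjust(tt$p_value)
  volcano <- volcano_select(fc$fc, tt$p_value, fc_threshold, p_threshold)
  labels <- ab$samples$group
  model <- fit_oplsda(pp$z, labels, n_orthogonal = n_orthogonal,
                      cv = cv, seed = seed)
  vip <- rep(NA_real_, nrow(fc))
  names(vip) <- fc$analyte_id
  vip[names(model$vip)] <- model$vip
  vip_ids <- names(model$vip)[model$vip > vip_threshold]
  volcano_ids <- fc$analyte_id[volcano$selected]
  fcv <- stats::setNames(fc$fc, fc$analyte_id)
  venn <- venn_intersect(vip_ids, volcano_ids, fcv)
  records <- data.frame(
    analyte_id = fc$analyte_id,
    vip = unname(vip),
    fc = fc$fc,
    log2_fc = fc$log2_fc,
    p_value = tt$p_value,
    fdr = fdr,
    in_vip_set = fc$analyte_id %in% vip_ids,
    in_volcano_set = fc$analyte_id %in% volcano_ids,
    in_venn_set = fc$analyte_id %in% venn$analyte_id,
    stringsAsFactors = FALSE
  )
  records$regulation <- ifelse(!records$in_venn_set, "NS",
                               ifelse(records$fc > 1, "UP", "DOWN"))
  list(records = records, model = model, venn = venn)
}
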