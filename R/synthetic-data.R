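#' Paired tumor/normal study design
#'
#' @param n_pairs number of patients (each contributing one tumor and one
#'   adjacent-normal tissue sample); default 24, the emulated study size.
#' @param seed integer RNG seed.
#' @return A `study_design` object with per-sample `group` and `pair_id`.
#' @export
study_design <- function(n_pairs = 24, seed = 1) {
  if (n_pairs < 3) stop("n_pairs must be >= 3")
  samples <- data.frame(
    sample_id = c(paste0("T", seq_len(n_pairs)), paste0("N", seq_len(n_pairs))),
    group = rep(c("TUMOR", "NORMAL"), each = n_pairs),
    pair_id = rep(seq_len(n_pairs), 2),
    stringsAsFactors = FALSE
  )
  structure(list(n_pairs = as.integer(n_pairs), samples = samples,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Calibrate within-pair noise from an observed p-value
#'
#' Inverts the paired Student's t-test: returns the within-pair SD (log10
#' scale) under which a paired t-test on `n_pairs` pairs attains exactly
#' `p_two_sided` in expectation at effect `delta_log10`, i.e.
#' `s_d = |delta| * sqrt(n) / qt(1 - p/2, n - 1)`.
#'
#' @param delta_log10 log10 fold-change effect (non-zero).
#' @param p_two_sided target two-sided p-value in (0, 1).
#' @param n_pairs number of pairs (>= 3).
#' @return Within-pair SD of the paired log10 differences.
#' @export
calibrate_sd_from_p <- function(delta_log10, p_two_sided, n_pairs) {
  if (n_pairs < 3) stop("n_pairs must be >= 3")
  if (p_two_sided <= 0 || p_two_sided >= 1) stop("p must be in (0, 1)")
  if (delta_log10 == 0) stop("delta_log10 must be non-zero")
  abs(delta_log10) * sqrt(n_pairs) /
    stats::qt(1 - p_two_sided / 2, df = n_pairs - 1)
}

#' Effect specifications for the abundance generator
#'
#' @param analyte_id analyte identifiers.
#' @param delta_log10 log10 fold-change effects (0 for null analytes).
#' @param within_pair_sd log10-scale SD of paired differences (> 0).
#' @param source provenance tag per analyte.
#' @return data.frame of effect specs.
#' @export
effect_spec <- function(analyte_id, delta_log10, within_pair_sd,
                        source = "CUSTOM") {
  if (any(within_pair_sd <= 0)) stop("within_pair_sd must be > 0")
  data.frame(analyte_id = analyte_id, delta_log10 = delta_log10,
             within_pair_sd = within_pair_sd, source = source,
             stringsAsFactors = FALSE)
}

#' Effect specs of the emulated 72-analyte study
#'
#' The 13 differential isomers carry their reported log2 fold changes with
#' within-pair noise calibrated (via [calibrate_sd_from_p()]) to their
#' reported paired-t p-values; the remaining panel analytes are null with
#' `within_pair_sd = null_sd`.
#'
#' @param n_pairs pairs used for the p-value calibration (default 24).
#' @param null_sd within-pair SD of null analytes, log10 scale
#'   (default 0.15, a plausible tissue-lipid biological CV).
#' @param panel analyte universe, default the built-in [fahfa_panel()].
#' @return data.frame of effect specs covering every panel analyte.
#' @export
study_effects <- function(n_pairs = 24, null_sd = 0.15,
                          panel = fahfa_panel()) {
  eff <- bc_effect_panel()
  sd_cal <- mapply(calibrate_sd_from_p, eff$delta_log10, eff$p_value,
                   MoreArgs = list(n_pairs = n_pairs))
  planted <- effect_spec(eff$analyte_id, eff$delta_log10, sd_cal,
                         source = "REPORTED")
  null_ids <- setdiff(panel$species_id, eff$analyte_id)
  nulls <- effect_spec(null_ids, 0, null_sd, source = "NULL")
  rbind(planted, nulls)
}

#' Generate a paired tumor/normal abundance study
#'
#' For analyte a and patient i, with patient random effect
#' `u_i ~ N(0, patient_sd^2)` and residuals `e, e' ~ N(0, s_d^2 / 2)`:
#' \deqn{log10(normal) = baseline_a + u_i + e}
#' \deqn{log10(tumor)  = baseline_a + u_i + delta_a + e'}
#' so the paired log10 difference has SD `s_d` and, log-variances being
#' equal in both groups, the ratio of group means equals `10^delta` in
#' expectation. Abundances are unitless ratios to internal standard.
#'
#' @param design a [study_design()].
#' @param effects effect specs covering all analytes ([effect_spec()]).
#' @param patient_sd SD of the per-patient random effect, log10 scale
#'   (default 0.2).
#' @param baseline_log10 per-analyte baseline level(s), recycled (default 0).
#' @param seed RNG seed; default taken from the design.
#' @return An `abundance_matrix`: positive `values` (analytes x samples),
#'   `samples` metadata (group, pair_id) and `analytes` metadata (including
#'   the generating truth).
#' @export
generate_abundance_study <- function(design, effects, patient_sd = 0.2,
                                     baseline_log10 = 0, seed = design$seed) {
  stopifnot(inherits(design, "study_design"))
  if (any(effects$within_pair_sd <= 0) || patient_sd < 0) {
    stop("SDs must be positive")
  }
  n <- design$n_pairs
  a <- nrow(effects)
  baseline <- rep_len(baseline_log10, a)
  local_seed(seed, {
    u <- stats::rnorm(n, 0, patient_sd)
    e_n <- matrix(stats::rnorm(a * n, 0, effects$within_pair_sd / sqrt(2)),
                  nrow = a)
    e_t <- matrix(stats::rnorm(a * n, 0, effects$within_pair_sd / sqrt(2)),
                  nrow = a)
    log_normal <- baseline + matrix(u, a, n, byrow = TRUE) + e_n
    log_tumor <- baseline + matrix(u, a, n, byrow = TRUE) +
      effects$delta_log10 + e_t
    values <- cbind(10 ^ log_tumor, 10 ^ log_normal)
  })
  dimnames(values) <- list(effects$analyte_id, design$samples$sample_id)
  abundance_matrix(values, design$samples,
                   analytes = data.frame(
                     analyte_id = effects$analyte_id,
                     true_delta_log10 = effects$delta_log10,
                     true_sd = effects$within_pair_sd,
                     source = effects$source,
                     stringsAsFactors = FALSE
                   ))
}

#' Generate a paired HFA abundance table
#'
#' Hydroxy fatty acids are the FAHFA precursors; the emulated study reports
#' only significance categories for them, so effect sizes here are package
#' defaults, not reported values: `DOWN` analytes get `delta_down`
#' (default log10(0.5)), `NS` analytes get 0.
#'
#' @param design a [study_design()].
#' @param directions named character vector analyte -> `"DOWN"` or `"NS"`;
#'   default the three precursor HFAs of the biomarker candidates.
#' @param delta_down log10 effect for DOWN analytes (negative).
#' @param within_pair_sd log10 within-pair SD (default 0.15).
#' @param patient_sd patient random-effect SD (default 0.2).
#' @param seed RNG seed.
#' @return An `abundance_matrix`.
#' @export
generate_hfa_table <- function(design,
                               directions = c("9-HSA" = "DOWN",
                                              "11-HSA" = "NS",
                                              "12-HPA" = "DOWN"),
                               delta_down = log10(0.5),
                               within_pair_sd = 0.15, patient_sd = 0.2,
                               seed = design$seed) {
  stopifnot(all(directions %in% c("DOWN", "NS")))
  if (delta_down >= 0) stop("delta_down must be negative")
  eff <- effect_spec(names(directions),
                     ifelse(directions == "DOWN", delta_down, 0),
                     within_pair_sd,
                     source = ifelse(directions == "DOWN", "DOWN", "NULL"))
  generate_abundance_study(design, eff, patient_sd = patient_sd, seed = seed)
}

#' Chromatographic fixture specification
#'
#' @param panel species panel (default [fahfa_panel()]).
#' @param ladder an [ri_ladder()] defining the RT window; species base RTs
#'   are placed by the family retention model through this ladder.
#' @param rt_jitter_sd run-to-run RT jitter of a species (min).
#' @param pair_rt_jitter_sd residual RT offset between the light and heavy
#'   peak of one species (min); co-elution is near-exact by construction.
#' @param height_meanlog,height_sdlog lognormal peak-height parameters.
#' @param ratio_sd SD of log2(heavy/light) height ratio; labeled aliquots
#'   are mixed 1:1, so the ratio is near 1.
#' @param n_decoys number of unpaired decoy peaks.
#' @param seed RNG seed.
#' @export
chrom_fixture_spec <- function(panel = fahfa_panel(),
                               ladder = default_ri_ladder(),
                               rt_jitter_sd = 0.01,
                               pair_rt_jitter_sd = 0.005,
                               height_meanlog = log(1e4),
                               height_sdlog = 1,
                               ratio_sd = 0.1,
                               n_decoys = 100,
                               seed = 1) {
  if (n_decoys < 0) stop("n_decoys must be >= 0")
  rt_base <- ri_to_rt(species_ri(panel$family, panel$position), ladder)
  rt_lim <- range(ladder$rt)
  if (any(rt_base < 0 | rt_base > 38)) {
    stop("species base RT outside the 0-38 min gradient window")
  }
  structure(list(panel = panel, ladder = ladder, rt_base = rt_base,
                 rt_jitter_sd = rt_jitter_sd,
                 pair_rt_jitter_sd = pair_rt_jitter_sd,
                 height_meanlog = height_meanlog, height_sdlog = height_sdlog,
                 ratio_sd = ratio_sd, n_decoys = as.integer(n_decoys),
                 rt_window = rt_lim, seed = as.integer(seed)),
            class = "chrom_fixture_spec")
}

#' Generate light/heavy chromatographic peak tables with decoys
#'
#' Each panel species yields one light peak (DMED precursor on the
#' LOSS_FA_63 screening channel, RT = base + jitter, lognormal height) and
#' one heavy peak (+4.0251 Da precursor, near-identical RT, height scaled by
#' `2^N(0, ratio_sd^2)`). Decoys are single unpaired peaks at random
#' m/z and RT, redrawn if they would form a candidate pair (within
#' `mz_tol`/`rt_tol`) with any peak in the opposite table, keeping the
#' ground truth unambiguous.
#'
#' @param spec a [chrom_fixture_spec()].
#' @param mz_tol,rt_tol tolerances used for the decoy-collision redraw
#'   (match the pairing defaults).
#' @return A list: `light` and `heavy` peak tables (`peak_id`,
#'   `precursor_mz`, `product_mz`, `rt`, `height`, `is_decoy`) and a
#'   `truth` sidecar (`species_id`, `light_id`, `heavy_id`).
#' @export
generate_chrom_fixture <- function(spec = chrom_fixture_spec(),
                                   mz_tol = 0.3, rt_tol = 0.05) {
  stopifnot(inherits(spec, "chrom_fixture_spec"))
  panel <- spec$panel
  n <- nrow(panel)
  tr <- panel_transitions(panel, tags = c("DMED", "d4-DMED"),
                          channels = "LOSS_FA_63")
  tl <- tr[tr$label == "DMED", ]
  th <- tr[tr$label == "d4-DMED", ]
  local_seed(spec$seed, {
    rt_l <- spec$rt_base + stats::rnorm(n, 0, spec$rt_jitter_sd)
    rt_h <- rt_l + stats::rnorm(n, 0, spec$pair_rt_jitter_sd)
    h_l <- stats::rlnorm(n, spec$height_meanlog, spec$height_sdlog)
    h_h <- h_l * 2 ^ stats::rnorm(n, 0, spec$ratio_sd)
    light <- data.frame(
      peak_id = paste0("L", seq_len(n)), precursor_mz = tl$precursor_mz,
      product_mz = tl$product_mz, rt = rt_l, height = h_l,
      is_decoy = FALSE, stringsAsFactors = FALSE
    )
    heavy <- data.frame(
      peak_id = paste0("H", seq_len(n)), precursor_mz = th$precursor_mz,
      product_mz = th$product_mz, rt = rt_h, height = h_h,
      is_decoy = FALSE, stringsAsFactors = FALSE
    )
    mz_range <- range(c(light$precursor_mz, heavy$precursor_mz)) + c(-20, 20)
    if (spec$n_decoys > 0) {
      for (k in seq_len(spec$n_decoys)) {
        to_light <- k %% 2 == 1
        repeat {
          mz <- stats::runif(1, mz_range[1], mz_range[2])
          rt <- stats::runif(1, spec$rt_window[1], spec$rt_window[2])
          other <- if (to_light) heavy else light
          offs <- if (to_light) other$precursor_mz - mz else mz - other$precursor_mz
          clash <- any(abs(offs - 4.02511) <= mz_tol & abs(other$rt - rt) <= rt_tol)
          if (!clash) break
        }
        row <- data.frame(
          peak_id = paste0("D", k), precursor_mz = mz,
          product_mz = mz - stats::runif(1, 250, 400), rt = rt,
          height = stats::rlnorm(1, spec$height_meanlog, spec$height_sdlog),
          is_decoy = TRUE, stringsAsFactors = FALSE
        )
        if (to_light) light <- rbind(light, row) else heavy <- rbind(heavy, row)
      }
    }
  })
  list(
    light = light, heavy = heavy,
    truth = data.frame(species_id = panel$species_id,
                       light_id = paste0("L", seq_len(n)),
                       heavy_id = paste0("H", seq_len(n)),
                       stringsAsFactors = FALSE),
    spec = spec
  )
}
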