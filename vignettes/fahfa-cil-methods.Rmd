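---
title: "Methods: CIL-LC-MS FAHFA profiling, annotation and differential statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CIL-LC-MS FAHFA profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cilFAHFA)
```

This vignette is the package's account of its methods: the mass and
fragmentation arithmetic, the pairing and annotation rules, the
statistical workflow, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was open.

## Chemistry and transition design

A FAHFA is a fatty acid (FA, formula $C_cH_{2c-2d}O_2$ for $c$ carbons and
$d$ double bonds) esterified to the hydroxyl of a hydroxy fatty acid (HFA,
$C_cH_{2c-2d}O_3$); esterification releases one water, so the neutral
monoisotopic mass is $m_{FA} + m_{HFA} - m_{H_2O}$. Atomic masses are
IUPAC monoisotopic values hard-coded to at least six decimals, and the
[M+H]$^+$ adduct uses the proton mass 1.00728 Da (not the hydrogen atom
mass), the positive-ion ESI convention.

Carboxyl derivatization with DMED forms an amide (reagent mass minus one
water, +70.0895 Da); the d4 reagent adds four deuteriums, +74.1146 Da, a
spacing of $4(m_{^2H} - m_{^1H}) = 4.0251$ Da. On collision-induced
dissociation the labeled species loses the esterified FA and, in the
screening channel, additionally dimethylamine plus water. All four
deuteriums ride on the dimethyl end and leave with the amine fragment, so
the combined neutral loss is nominally 63 Da for the light label and 67 Da
for the heavy one — this asymmetry is what makes the light and heavy
product ions of the 63/67 channel coincide. Three product channels are
supported (`LOSS_FA`, `LOSS_FA_45`, `LOSS_FA_63`) because printed
instrument tables in this field mix them; the package never guesses which
channel an instrument actually used for a family.

Printed unit-resolution quadrupole channels sit roughly 0.1–0.3 Da above
exact monoisotopic values, so all matching against printed channels uses a
±0.3 Da tolerance (`matches_printed_channel`) rather than equality.

The built-in panel (`fahfa_panel()`) enumerates 9 families × 8 ester-bond
positions = 72 isomers. The isomer list of the study this panel emulates
is not public; the panel is a documented synthetic reconstruction that
covers every named family and all 13 differential isomers, with
`has_standard` marking positions backed by an authentic standard.

## Peak pairing

Because the two labeled aliquots are mixed 1:1 and the label barely
perturbs retention, every true analyte appears as a light/heavy peak pair
with (i) precursor spacing 4.0251 Da, (ii) the same retention time, and
(iii) near-equal height. The source workflow states the criteria
qualitatively ("identical retention time and signal intensity"); the
defaults operationalizing them are engineering choices, exposed in the
configuration:

| parameter | default | units | rationale |
|---|---|---|---|
| `mz_tol` | 0.3 | Da | unit-resolution quadrupole setting |
| `rt_tol` | 0.05 | min | co-elution on a UPLC gradient |
| `max_log2_ratio` | 0.585 | log2 | height ratio within [2/3, 3/2] |

Matching is greedy: candidates satisfying all three criteria are sorted by
|ΔRT|, ties broken by |log₂ ratio|, and each peak joins at most one pair.
A globally optimal assignment would be a drop-in replacement, but at MRM
channel sparsity the greedy solution is deterministic, fast and — on the
synthetic fixtures — exact. Degenerate (zero) tolerances warn and reject
everything rather than erroring. Peak *height*, not area, is the intensity
measure throughout, matching the quantification convention.

## Retention-index annotation

Retention times are calibrated to retention indices by piecewise-linear
interpolation over a ladder of calibrants (`rt_to_ri`); queries outside
the ladder are linearly extrapolated from the terminal segment and
flagged. The original study's RI calibration protocol is not public; the
piecewise-linear scheme is a Kovats-style analogue and is deliberately the
exact inverse of the ladder mapping used by the fixture generator, so
generation and analysis round-trip without calibration error.

Within a family, log₁₀(RI) falls linearly with ester-bond position (later
positions elute earlier). Annotation is two-stage:

1. **Standard match** — a same-family authentic standard within
   `rt_match_tol` (default 0.05 min), closest first; two equidistant
   candidates raise an ambiguity error rather than a guess.
2. **Regression** — otherwise, the family's least-squares line
   $\log_{10}(RI) = a + b\,x$ (fitted by `stats::lm` on ≥ 3 standards at
   ≥ 3 distinct positions) is inverted:
   $\hat x = (\log_{10}(RI) - a)/b$, position $= \operatorname{round}(\hat x)$,
   confidence $= |\hat x - \operatorname{round}(\hat x)|$.

A confidence residual above 0.35 position units flags `LOW_CONFIDENCE`
but is still reported, since the emulated workflow reports predicted
positions without a stated acceptance band. Predicted positions outside
$[2, \text{HFA carbons} - 1]$ are rejected. Families with fewer than three
standards get no curve and their unmatched members stay unannotated — no
cross-family borrowing.

## Quantification

Relative abundance is the light/heavy peak-height ratio against the
spiked d4-labeled standard. Isomers without an authentic standard use the
same-family standard with the nearest position as surrogate; an exact
|Δposition| tie breaks toward the lower position (arbitrary but fixed and
logged). Missing cells are `NA`, never zero; analytes missing in more
than half the samples are dropped with a logged list; no imputation is
performed before statistics (missing values are excluded pairwise per
analyte). The source workflow is silent on all three points.

## Differential statistics

Abundances are log₁₀-transformed for testing and per-analyte z-scored for
the multivariate step. z-scoring divides by the population SD (root mean
squared deviation), so a three-point pattern {1, 10, 100} maps to
{−1.2247, 0, 1.2247}. Fold changes are always computed on the raw scale
as mean(tumor)/mean(normal).

The per-analyte test is a **paired two-sided Student's t** on log₁₀
abundances — tissues are patient-matched — with an unpaired Welch variant
behind a flag. (The source describes a "nonparametric univariate
Student's t-test", which is self-contradictory; the parametric paired
reading follows the matched design and the report table's footnote.)
Degenerate inputs follow fixed conventions: all-zero differences give
p = 1; zero-variance nonzero differences give the smallest representable
p; fewer than three complete pairs gives NA. Multiplicity is handled by
Benjamini–Hochberg step-up FDR ("classical one-step FDR" read as BH; a
Bonferroni-style one-step procedure would contradict "FDR"), with NAs
excluded from the test count.

**OPLS-DA** is a NIPALS-style fit with one predictive plus one orthogonal
component by default (SIMCA-like defaults; the emulated study names the
software but no settings). The ±1 class response is centered; orthogonal
components remove Y-uncorrelated X variation before the predictive
component is extracted. Q² uses stratified 7-fold cross-validation with
per-fold re-centering, deterministic given the seed. VIP is
$\sqrt{p \sum_a SS_a w_{aj}^2 / \sum_a SS_a}$ over the predictive and
orthogonal components, each weighted by the Y variation its scores
explain; orthogonal components carry near-zero Y variation by
construction, so discriminant-relevant weights dominate, and since weight
vectors are unit-norm the identity mean(VIP²) = 1 holds exactly.
(Weighting orthogonal components by their explained **X** variation
instead lets Y-unrelated variance dominate the score and ranks null
analytes highly; that variant was examined and rejected.) The
permutation test refits under label permutations (default n = 200) and
passes only if every permuted R²Y and Q² falls below the original.

The **differential set** is the Venn intersection of {VIP > 1} and the
volcano selection {p < 0.05 and FC > 1.5 or < 1/1.5}, with regulation
from the fold-change sign. The VIP cut-off is strict (> 1); reported VIPs
printed as 1.0 are taken to exceed 1 before rounding.

## Multivariate ROC

Panels are evaluated by Monte-Carlo cross-validation: stratified random
splits (2/3 train per class, 50 repeats — MetaboAnalyst-style defaults),
one held-out AUC per repeat by the rank/trapezoid rule, summarized as the
mean with a 2.5/97.5 percentile interval. Backends: Random Forest (500
trees), linear-kernel SVM (default cost, decision values), and a
2-component NIPALS PLS-DA scorer. Feature-subset models rank features
*inside* each training split by univariate |AUC − 0.5| (nested, no
selection leakage); `nested = FALSE` reproduces the optimistic
global-ranking variant that published workflows likely used.

## What the synthetic data emulates — and what it does not

`generate_chrom_fixture` plants one light/heavy pair per panel species:
retention times follow the family-wise RI lines through the ladder, pair
members co-elute within 0.005 min, heights are lognormal with
log₂-ratio noise of 0.1, and decoy peaks (default 100) are placed so they
cannot form a candidate pair with any other peak, keeping ground truth
unambiguous.

`generate_abundance_study` draws, for analyte $a$ and patient $i$,
$\log_{10}$ abundances $b_a + u_i (+ \delta_a) + e$ with patient effect
$u_i \sim N(0, 0.2^2)$ and residuals $N(0, s_{d,a}^2/2)$ in each tissue,
so the paired difference has SD $s_{d,a}$ and the group-mean ratio is
$10^{\delta_a}$ in expectation. The 13 differential analytes carry their
reported log₂ fold changes (the log₂ column, which is more precise than
the rounded FC column) with $s_d$ calibrated by inverting the paired
t-test, $s_d = |\delta|\sqrt{n}/t_{1-p/2,\,n-1}$, at the reported
p-value and n = 24; the other 59 analytes are null with $s_d = 0.15$.
The defaults patient SD 0.2 and null SD 0.15 (log₁₀) correspond to
plausible biological variability for tissue lipids and are exposed in the
configuration. HFA tables use package-default effect sizes
(DOWN = log₁₀(0.5)) because the emulated study reports only significance
categories for HFAs.

The generator does **not** emulate: raw chromatograms or peak shape,
isotope envelopes and interference, adducts other than [M+H]⁺,
missingness, batch or injection-order drift, correlated analytes
(co-regulation within families), or non-lognormal heavy tails. Passing
tests therefore demonstrate correctness of the pipeline's logic under the
stated statistical model, not robustness to those real-data features.

A consequence worth stating plainly: with noise calibrated so each
planted analyte attains its reported p-value *in expectation*, the
weakest planted effects straddle the selection thresholds by
construction — an analyte with true log₂FC −0.6 clears the 1.5× filter
(cut 0.585) by only 0.015 log₂ units, and a reported p of 8.8 × 10⁻³
implies roughly 77% power at α = 0.05. Single-study recovery of the full
13-analyte set is therefore the *modal-but-not-guaranteed* outcome class;
across 100 simulated studies the modal recovered set size is 11–13 with
the shortfall concentrated in those threshold-straddling analytes. This
is a property of the emulated study conditions, not a tunable defect.

## Determinism and problem sizes

Every stochastic step takes an explicit seed; pipeline stages derive
their seeds from one root seed, and identical configuration plus seed
reproduces every output byte for byte (asserted in the tests). The
simulation sizes used by the tests and the reproduction script — 100
simulated studies for recovery summaries, 10⁴ replicates for the type-I
error check, 50 MCCV repeats, 200 permutations — were chosen as the
smallest sizes at which the summarized quantities are stable to well
within their comparison tolerances.

## Known limitations

* The 72-isomer panel and all standard RIs are reconstructions; per-isomer
  identities beyond the 13 differential analytes are placeholders.
* Greedy pairing is not a global assignment; at very high peak densities
  it can differ from the optimum.
* The RI calibration transfer (piecewise-linear ladder) is an analogue of
  an unpublished protocol.
* OPLS-DA is limited to a two-class response and a single predictive
  component; VIP follows one of several published conventions (documented
  above).
* FDR values on subsets of analytes are not comparable to FDRs computed
  over a different analyte universe; the pipeline always adjusts over all
  tested analytes.
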