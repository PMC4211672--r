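---
title: "Methods: multi-compartment PK of rectal tenofovir gel vs oral TDF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-compartment PK of rectal tenofovir gel vs oral TDF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucosalpk)
```

This vignette documents the statistical and numerical choices behind
`mucosalpk`: the data-standardization rules, the noncompartmental estimators,
the robust cross-matrix regression, the paired testing layer, and the
synthetic cohort generator that stands in for the (unpublished) per-subject
clinical concentrations.

## Data standardization

**Sponge normalization.** Rectal and vaginal secretions are collected on
pre-weighed sponges and assayed as drug mass per sponge (ng/sponge).
`normalize_sponge()` divides by the fluid weight collected (g), giving ng/g.
A missing or non-positive fluid weight makes the concentration undefined; the
record is excluded and logged rather than guessed.

**BLQ policy.** Concentrations below the assay's lower limit of
quantification are left-censored. Two analysis modes treat them differently,
and `impute_blq()` makes the mode explicit:

* `"nca"` — every BLQ value is imputed as **0.01 in its native matrix
  units**. This is deliberately literal: the same constant is used in ng/mL,
  fmol/10⁶ cells, ng/mg and ng/g, because harmonizing it across unit systems
  would change AUC and Cmax summaries in censored-heavy matrices. The
  constant is configurable (`blq_value`) for sensitivity analysis.
* `"correlation"` — BLQ records are excluded entirely. Imputed constants on
  a log10 scale would otherwise create an artificial point mass two or more
  decades below the data and dominate a regression fit.

The two modes agree on every quantifiable record (a tested invariant), and
imputation is idempotent.

**Profile eligibility.** Per-subject NCA uses only profiles with (a) more
than two points, (b) a last sample at or before 24 h, and (c) a first sample
at or before 12 h, all bounds inclusive. Clause (b) is widened to 26 h:
the AUC engine linearly interpolates the 24 h concentration whenever the
last actual time overshoots 24 h, and a rule that rejected such profiles
outright would make that interpolation unreachable. The 26 h cap is the
nominal 24 h point plus the 2 h visit-jitter scale. Duplicate sampling times
keep the first record with a warning.

## Noncompartmental estimators

**AUC₀₋₂₄.** Linear trapezoid on actual times — not log-trapezoid, which is
deliberately rejected so that the integration matches plain linear
interpolation everywhere. Endpoint rules, with flags recording which fired:

* last time > 24 h: interpolate C(24) on the piecewise-linear curve,
  truncate at 24 h (`interpolated_at_24`);
* last time in [22, 24) h: that concentration *is* the 24 h value, so the
  closing segment is a rectangle C(t_L)·(24 − t_L) (`imputed_22_24`). The
  rectangle choice makes the two branches continuous as t_L → 24;
* no sample at or past 22 h: integrate to the last sample and flag
  `truncated`.

The implementation is verified against knot-exact fine-grid integration of
the interpolant at 1e−9 relative tolerance on a thousand random profiles
covering all three branches.

**Terminal half-life.** λz is the negative least-squares slope of
ln C vs. time over a terminal point set; t½ = ln 2 / λz. The original
analysis chose beta-phase points by hand, which is not reproducible; `auto`
mode instead scans every contiguous terminal subset of ≥ 3 points at/after
Tmax (excluding the Tmax point itself whenever more than three candidates
exist, since the peak still carries absorption) and keeps the subset with
the best adjusted R². A manual point set can be supplied. Non-negative
slopes and < 3 usable points yield a flagged missing half-life, never a
nonsensical number; fits that include imputed 0.01 values are flagged
`uses_imputed`.

**Composite profiles.** Biopsy matrices are too sparse per subject for NCA
(each subject contributes at most three biopsy times), so
`composite_profile()` takes the median across subjects at each *nominal*
time — actual times differ by subject, and order statistics need a common
grid — and downstream NCA runs on nominal times. Composite results are
labelled `basis = "composite"` so they are not misread as per-subject
statistics with dispersion.

**Accumulation ratio.** Multiple-dose/single-dose AUC₀₋₂₄ when both are
computable, otherwise the 0.5 h concentration ratio, with the basis
recorded. For linear kinetics with terminal rate k, seven daily doses give
the analytic factor (1 − e^(−7·24k))/(1 − e^(−24k)); the superposition
generator reproduces it within 5% (tested), which is what makes the ratio a
meaningful check rather than a free parameter.

**CV%.** 100·sd/mean at each nominal time (sample sd). A group whose values
are all equal after imputation — i.e. fully censored — returns 0, matching
how fully-BLQ groups present in variability summaries.

## Robust cross-matrix regression

All concentrations are log10-transformed (BLQ excluded upstream), and the
candidate model is

log10(DV) = β₀ + β₁·log10(IV) + β₂·CV + β₃·log10(IV)·CV,

with CV a 0/1 covariate (CD4 cell type, or dose route). `robust_lm()` fits
by iteratively reweighted least squares with a Huber ψ (tuning constant
1.345, ~95% normal efficiency), residual scale re-estimated each iteration
as median(|r|)/0.6745, convergence at 1e−8 relative change in coefficients
or 100 iterations, with a hard failure on non-convergence or a rank-deficient
design. A Tukey bisquare ψ (k = 4.685) is available via `psi = "bisquare"`
for fully redescending weights; this is offered instead of a full S+MM
estimator because with n in the tens to low hundreds and contamination well
under 30%, the monotone Huber fit is stable and far simpler to reason about.

Standard errors use the M-estimation asymptotic covariance
s²·[Σψ(u)²/(n−p)] / [mean ψ′(u)]² · (XᵀX)⁻¹ with the standard small-sample
correction factor (1 + p·var(ψ′)/(n·mean(ψ′)²))², and p-values are two-sided
from the t distribution with n − k degrees of freedom (small-n fidelity;
the normal reference would be anti-conservative at n ≈ 20–60).

**Backward elimination** removes one term per step — the least significant
non-intercept term with p > 0.05 — and refits, respecting marginality (a
main effect is never dropped while its interaction survives; the intercept
is never dropped). Single-step removal is order-stable and more conservative
than dropping all non-significant terms at once. The elimination trace is
kept, and refitting the final term set from scratch reproduces the final
coefficients (tested invariant).

**RSE.** The reported goodness-of-fit number is the robust residual scale on
log10 units (0 = perfect fit). The phrase "relative standard error" is
ambiguous in the source material; the robust scale is the interpretation
consistent with the printed magnitudes (0.13–0.67 log10 units) and with
"0 would be a perfect fit", and it is what the generator's `noise_sd_log10`
round-trips to.

**Prediction bands.** 10–90% pointwise intervals for the *mean* prediction,
fit ± z₀.₉₀·SE(x᷆ᵀβ), from the robust coefficient covariance (normal
approximation). Grid points outside the observed IV range are flagged
extrapolated rather than suppressed. A Monte-Carlo study in the test suite
confirms ~80% coverage of the true mean.

**Derived intercepts.** When a covariate is retained, the level-1 intercept
is β₀ + β₂ with SE from the full covariance (including the off-diagonal
term); the level difference test is the Wald test on β₂.

**Pooling.** Repeated measures per subject are pooled without a
within-subject correlation adjustment, matching the source analysis; the
standard errors are therefore mildly optimistic for strongly clustered data.
Mixed-effects modelling is intentionally out of scope.

## Paired testing layer

The two planned dosing contrasts (oral vs single rectal; single vs multiple
rectal) are paired Wilcoxon signed-rank tests at the Bonferroni-corrected
critical p = 0.05/2 = 0.025. Zero differences are dropped before ranking
(Wilcoxon's original treatment); with tie-free |differences| and ≤ 15 pairs
the p-value is exact (equivalent to full 2ⁿ sign enumeration, which is the
independent oracle in the tests), otherwise the normal approximation with
continuity and tie corrections is used. Half-life comparisons use a paired
t-test on log half-lives instead — half-lives are positive and
right-skewed, and the log transform makes the paired differences
approximately normal. A constant ratio across all pairs (zero variance on
the log scale) is flagged degenerate rather than reported as t = ∞. All
tests are two-sided.

## The synthetic cohort generator

There is no deposited per-subject dataset, so the generator *defines* the
study conditions every pipeline stage and acceptance check runs under.

What it emulates:

* the crossover design — 18 subjects, 12 on active gel (placebo-gel
  subjects contribute only the oral period), biopsy groups A/B alternating,
  core sampling at 0/0.5/2/4/24 h, single-period biopsies at 0.5 h plus
  24 h/day 7 (group A) or days 4/10 (group B), one biopsy point after the
  7th daily dose;
* one-compartment first-order absorption kinetics per period × matrix ×
  analyte, C(t) = D·ka/(ka−ke)·(e^(−ke·t) − e^(−ka·t)), with log-normal
  between-subject variability on D and ke (CV 0.5 and 0.2 by default —
  plausible mid-range values for the wide observed CV% spectrum) and
  residual log10 noise sd 0.15;
* dose scales set so single-dose peaks land on the observed medians (oral
  plasma Cmax ≈ 250 ng/mL, half-life 10.8 h, Tmax ≈ 1.9 h; rectal plasma
  Cmax ≈ 10.5 ng/mL in the flip-flop regime ka < ke, so the apparent
  half-life is ln 2/ka = 4.56 h; rectal-fluid Cmax ≈ 7.4e5 ng/g topical vs
  9.8e3 ng/g oral; tissue TFV ≈ 5.8 ng/mg topical);
* rectal tissue TFVdp with its own kinetics: a 60 h effective intracellular
  half-life (within the range reported for TFVdp retention), which makes
  seven-dose superposition accumulate roughly four-fold, and an oral-period
  scale below the 30 fmol/mg LLOQ so oral tissue TFVdp is censored — the
  observed pattern. A static cross-matrix map from tissue TFV was
  considered and rejected: it would impose a TFVdp–TFV correlation under
  rectal dosing (not observed), could not reproduce the oral censoring
  pattern, and has no mechanism for metabolite-specific accumulation;
* mucosal mononuclear cell TFVdp derived from tissue TFVdp through the
  reported cell model (slope 0.628, CD4+ offset +0.586, noise 0.46), split
  into CD4+/CD4−/total fractions;
* vaginal fluid from rectal fluid at −1.06 log10 (≈ 8.7%) during rectal
  periods and from plasma through the dose-route model during the oral
  period;
* truncated-normal sampling-time jitter (sd 0.15 h for intensive points,
  1 h at 24 h, 2 h for day-scale visits; never negative). The 24 h sd is
  chosen so both AUC endpoint rules fire regularly in a cohort;
* LLOQ censoring per matrix: plasma TFV 0.31 ng/mL and cellular TFVdp
  8 fmol/10⁶ cells are assay values; fluid (10 ng/g) and tissue TFVdp
  (30 fmol/mg) limits are unpublished and set as configurable placeholders
  near the bottom of the observed ranges;
* sponge records emitted as ng/sponge with a fluid weight drawn uniformly
  from 0.05–0.40 g, exercising the normalization path.

What it does **not** emulate: multi-compartment mechanistic distribution,
saturable renal elimination, adherence or gel-leakage behaviour, assay
calibration drift, heavy-tailed outliers in the kinetic matrices, or
within-subject correlation beyond shared D/ke random effects. Passing tests
therefore demonstrate that the *estimators implement their definitions* and
recover known generating parameters — not that the generator reproduces
every moment of the clinical data.

Cross-matrix regression datasets for the recovery studies are simulated
directly from the reported fitted models (`cross_matrix_models()` holds all
eight: coefficients, SEs, RSE, and the IV log10 ranges taken from the
stated or plotted concentration ranges, e.g. 0.10–10 ng/mg tissue TFV,
10–10,000 fmol/mg tissue TFVdp, 30–1,000 fmol/mg for the vaginal TFVdp
model). Residual sd equals the printed RSE; an optional two-component
mixture adds scale-inflated outliers for robustness studies.

## Numerical choices and degenerate inputs

* Seeds fix everything: cohorts, regression datasets and pipeline runs are
  byte-identical under an identical seed; replicate seeds in
  `recovery_study()` are drawn below 2³¹ from the master seed.
* ka = ke is a removable singularity of the kinetic curve; it is rejected
  unless the caller opts into the analytic limit D·ka·t·e^(−ka·t), so a
  mis-specified kinetic block fails loudly.
* All-BLQ profiles return Cmax = 0.01 at the first time, flagged degenerate;
  all-zero paired differences return p = 1, flagged.
* Cmax ties break to the earliest time; duplicate sampling times keep the
  first record.
* The IRLS perfect-fit branch (scale < 1e−12) reports zero RSE and treats
  exactly-zero coefficients as vacuous (p = 1) so elimination still prunes
  them.

## Problem sizes

The recovery studies use n = 300 observations and 200 replicates per model
(the acceptance script reports the median recovered coefficient across
replicates); the AUC oracle sweep uses 1,000 random profiles; the Wilcoxon
null calibration uses 2,000 replicates at n = 12; the band-coverage study
uses 400 replicates at n = 40. These sizes give Monte-Carlo error well below
the tolerances they are checked against.

## Known limitations

* The BLQ imputation constant is applied in native units across matrices
  whose scales differ by five orders of magnitude; censored-heavy summaries
  (PBMC, oral tissue TFVdp) are therefore imputation-dominated by design.
* Automatic λz selection can differ from hand-picked beta phases on noisy,
  sparse profiles; the manual override exists for exactly that case.
* Pooled regression SEs ignore within-subject clustering (see above).
* The generator's cross-matrix links are period-homogeneous except where
  the observed censoring forced a split; a cohort simulated under these
  defaults will not reproduce every reported matrix summary, only the ones
  the conditions target.
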