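# mucosalpk

Multi-compartment pharmacokinetic analysis of rectally applied tenofovir (TFV)
1% gel versus oral tenofovir disoproxil fumarate (TDF).

## The problem

HIV pre-exposure prophylaxis with tenofovir works only where the drug — and
its intracellular active metabolite tenofovir diphosphate (TFVdp) — actually
reaches the cells targeted by the virus. A crossover phase-1 design gives each
subject a single oral TDF dose, then (for the active-gel arm) a single rectal
1% TFV gel dose, then seven daily rectal doses, sampling six biological
matrices over 24 h and at follow-up biopsy visits: blood plasma (ng/mL), PBMC
(fmol/10^6 cells), rectal tissue homogenate (ng/mg TFV, fmol/mg TFVdp),
isolated rectal mucosal mononuclear cells split into CD4+ and CD4− fractions
(fmol/10^6 cells), and rectal and vaginal fluid collected by sponge (ng/g
after normalization by collected fluid weight).

`mucosalpk` implements the full analysis chain for such data, for PK and
biostatistics practitioners:

- **Standardization** — sponge normalization (ng/sponge ÷ g fluid → ng/g);
  below-limit-of-quantification (BLQ) handling by analysis mode (imputed as
  0.01 in native units for NCA, excluded for correlation analysis); profile
  eligibility screening (> 2 points, last point ≤ 24 h with an interpolation
  carve-out, first point ≤ 12 h).
- **Noncompartmental analysis** — Cmax/Tmax (earliest-time tie-break),
  linear-trapezoid AUC₀₋₂₄ with two endpoint rules (linear interpolation at
  24 h when the last sample overshoots; carry-forward of a sample in
  [22, 24) h), terminal half-life t½ = ln 2 / λz with λz chosen by best
  adjusted R² over contiguous beta-phase subsets, composite median profiles
  on nominal times for sparse biopsy matrices, and accumulation ratios
  (AUC₀₋₂₄ ratio, or the 0.5 h concentration ratio as fallback).
- **Robust cross-matrix regression** — the model
  `log10(DV) = β₀ + β₁·log10(IV) + β₂·CV + β₃·log10(IV)·CV`
  fitted by Huber M-estimation (MAD scale, k = 1.345) with backward
  elimination of terms at p > 0.05, robust residual scale (RSE), per-level
  derived intercepts, and 10–90% mean-prediction bands.
- **Paired comparisons** — paired Wilcoxon signed-rank tests (exact by
  enumeration for ≤ 15 tie-free pairs) at the Bonferroni-corrected critical
  p = 0.05/2 = 0.025, and a paired t-test on log half-lives.
- **A seeded synthetic cohort generator** that emulates the crossover
  sampling design (18 subjects, 12 on active gel, biopsy groups A/B,
  sampling at 0/0.5/2/4/24 h plus day-scale follow-ups), one-compartment
  first-order absorption kinetics with flip-flop rectal plasma kinetics,
  7-dose superposition, matrix-specific LLOQ censoring, and the reported
  cross-matrix relationships — so the entire pipeline is testable with no
  clinical data.

## Worked example

```r
library(mucosalpk)

rec      <- simulate_cohort(seed = 2026)          # synthetic crossover cohort
std      <- standardize_records(rec)              # sponge ng/sponge -> ng/g
ncar     <- impute_blq(std, "nca")                # BLQ -> 0.01 for NCA
profiles <- assemble_profiles(ncar)               # grouped, screened profiles

oral <- Filter(function(p) p$key$matrix == "plasma" &&
                 p$key$period == "single_oral" && p$eligible, profiles)
nca(oral[[1]])
#> Noncompartmental PK summary
#>   profile: S01 / single_oral / plasma / TFV / none
#>   Cmax 418.8 at Tmax 1.73 h
#>   AUC24 4642 (flags: imputed_22_24)
#>   terminal half-life 6.522 h (lambda_z 0.1063 /h, 3 points)
```

Subject S01's oral profile peaks at 419 ng/mL 1.7 h post-dose; its last
sample fell in the 22–24 h window, so that concentration was carried to 24 h
(flag `imputed_22_24`) before trapezoidal integration. Across the cohort the
median oral plasma half-life is 9.4 h, versus ~4.6 h under rectal dosing,
where slow absorption — not elimination — limits the terminal slope
(flip-flop kinetics).

Robust regression on data simulated from the reported mucosal-cell model
(slope 0.628, cell-type offset 0.586, RSE 0.46):

```r
d   <- simulate_regression_data(reference_model("mmc_tfvdp_on_tissue_tfvdp"),
                                n = 300, x_range_log10 = c(1, 4), seed = 9)
fit <- robust_lm(dv ~ iv * cv, d)
summary(fit)
#>             Estimate Std. Error t value   p value
#> (Intercept) 0.886813   0.083281  10.648 < 2.2e-16 ***
#> iv          0.563077   0.029196  19.286 < 2.2e-16 ***
#> cv          0.553276   0.052342  10.570 < 2.2e-16 ***
#> Robust residual scale (RSE): 0.4527  on 297 residual df (n = 300)
#> Dropped terms: iv:cv

derived_intercepts(fit)
#> CD4- intercept 0.887, CD4+ intercept 1.440 (p = 2.2e-22)
```

The null interaction is eliminated, the cell-type offset is retained, and the
CD4+ intercept sits one offset above the CD4− intercept: CD4+ cells carry
systematically more TFVdp at any homogenate concentration.

The all-in-one driver writes the full report bundle (records, exclusions,
NCA results, summary table, composite profiles, accumulation ratios,
regression report, prediction bands, comparisons, resolved config, log):

```r
run_pipeline(pipeline_config(seed = 1, out_dir = "run1"))
```

or from a shell: `Rscript inst/scripts/mucosalpk-run.R --seed 1 --out run1`.

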