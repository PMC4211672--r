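Package: mucosalpk
Title: Multi-Compartment Pharmacokinetics of Rectal Tenofovir Gel and Oral TDF
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Noncompartmental pharmacokinetic (NCA) analysis of tenofovir (TFV)
    and its active metabolite tenofovir diphosphate (TFVdp) across blood plasma,
    PBMC, rectal tissue, isolated mucosal mononuclear cells, and rectal/vaginal
    fluid, comparing single oral tenofovir disoproxil fumarate dosing with single
    and multiple rectal 1% gel dosing. Implements the study's data-standardization
    rules (sponge normalization, below-limit-of-quantification imputation and
    exclusion policies, profile eligibility screening), trapezoidal AUC with
    partial-interval interpolation and late-sample imputation, terminal-phase
    half-life selection, composite median profiles, accumulation ratios, robust
    log10-linear cross-matrix regression with backward elimination and 10-90%
    mean-prediction bands, paired Wilcoxon and log-scale paired t comparisons,
    and a seeded synthetic-cohort generator emulating the crossover sampling
    design so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    jsonlite
Config/testthat/edition: 3
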