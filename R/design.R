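#' Matrix specifications: units and assay lower limits of quantification
#'
#' Each biological matrix x analyte combination carries its native unit system
#' and the lower limit of quantification (LLOQ) of the bioanalytical assay.
#' Values generated or measured below the LLOQ are left-censored (BLQ).
#'
#' Defaults: plasma TFV 0.31 ng/mL (lowest calibration standard of the TFV
#' plasma assay), PBMC and mucosal mononuclear cell TFVdp 8 fmol/10^6 cells.
#' LLOQs for the fluid and tissue matrices were not published in final units
#' and are configurable placeholders chosen near the bottom of the observed
#' concentration ranges.
#'
#' @param overrides named list; names are `"<matrix>.<analyte>"` (for example
#'   `"plasma.TFV"`), values replacement LLOQs in matrix units.
#' @return data.frame with columns `matrix`, `analyte`, `units`, `lloq`.
#' @export
#' @examples
#' matrix_specs()
#' matrix_specs(overrides = list(plasma.TFV = 1.0))
matrix_specs <- function(overrides = NULL) {
  specs <- data.frame(
    matrix = c("plasma", "pbmc", "rectal_tissue", "rectal_tissue",
               "rectal_mmc", "rectal_fluid", "vaginal_fluid"),
    analyte = c("TFV", "TFVdp", "TFV", "TFVdp", "TFVdp", "TFV", "TFV"),
    units = c("ng/mL", "fmol/10^6 cells", "ng/mg", "fmol/mg",
              "fmol/10^6 cells", "ng/g", "ng/g"),
    lloq = c(0.31, 8, 0.05, 30, 8, 10, 10),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
      if (length(parts) != 2L)
        stop("override names must be '<matrix>.<analyte>'", call. = FALSE)
      i <- specs$matrix == parts[1L] & specs$analyte == parts[2L]
      if (!any(i)) stop("unknown matrix/analyte: ", nm, call. = FALSE)
      val <- as.numeric(overrides[[nm]])
      if (!is.finite(val) || val <= 0) stop("lloq must be > 0", call. = FALSE)
      specs$lloq[i] <- val
    }
  }
  specs
}

#' Crossover study design for the synthetic cohort
#'
#' Encodes the three-stage crossover sampling design: all subjects receive a
#' single oral TDF dose; the active-gel subjects additionally receive a single
#' rectal 1% TFV gel dose and, later, seven daily rectal doses. Plasma, PBMC
#' and fluid sponges are sampled intensively at 0, 0.5, 2, 4 and 24 h in every
#' period. Rectal biopsies (tissue homogenate and isolated mucosal mononuclear
#' cells) are taken at 0.5 h in all periods, with follow-up biopsies in the
#' single-dose periods at 24 h and day 7 for biopsy group A and days 4 and 10
#' for group B; the multiple-dose period has a single biopsy collection point.
#'
#' @param n_subjects total enrolled subjects (default 18).
#' @param n_active_gel subjects randomized to active TFV gel (default 12); the
#'   remainder receive placebo gel and contribute only the oral period.
#' @param jitter_sd_h standard deviations (hours) of the truncated-normal
#'   deviation of actual from nominal sampling time, named `intensive` (points
#'   through 4 h), `day1` (the 24 h point) and `visit` (day-scale visits).
#' @return object of class `study_design`.
#' @export
study_design <- function(n_subjects = 18L, n_active_gel = 12L,
                         jitter_sd_h = c(intensive = 0.15, day1 = 1, visit = 2)) {
  n_subjects <- as.integer(n_subjects)
  n_active_gel <- as.integer(n_active_gel)
  stopifnot(n_subjects >= 1L, n_active_gel >= 1L, n_active_gel <= n_subjects)
  if (any(jitter_sd_h < 0)) stop("jitter sds must be non-negative", call. = FALSE)
  jitter_sd_h <- jitter_sd_h[c("intensive", "day1", "visit")]
  if (anyNA(jitter_sd_h))
    stop("jitter_sd_h needs elements 'intensive', 'day1', 'visit'", call. = FALSE)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  structure(list(
    subjects = subjects,
    arm = ifelse(seq_len(n_subjects) <= n_active_gel, "TFV", "HEC"),
    # alternate biopsy groups so both arms contain A and B subjects
    group = ifelse(seq_len(n_subjects) %% 2L == 1L, "A", "B"),
    periods = c("single_oral", "single_rectal", "multiple_rectal"),
    core_times_h = c(0, 0.5, 2, 4, 24),
    biopsy_times_h = list(
      single = list(A = c(0.5, 24, 168), B = c(0.5, 96, 240)),
      multiple = list(A = 0.5, B = 0.5)
    ),
    jitter_sd_h = jitter_sd_h
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Crossover PK study design\n")
  cat("  subjects:", length(x$subjects),
      sprintf("(%d active gel, %d placebo gel)\n",
              sum(x$arm == "TFV"), sum(x$arm == "HEC")))
  cat("  periods:", paste(x$periods, collapse = ", "), "\n")
  cat("  core sampling (h):", paste(x$core_times_h, collapse = ", "), "\n")
  invisible(x)
}

#' Sampling schedule implied by a study design
#'
#' Expands a design into one row per subject x period x matrix x analyte x
#' nominal time, honouring arm restrictions (rectal periods only for active-gel
#' subjects) and the biopsy group schedules.
#'
#' @param design a [study_design()].
#' @return data.frame with columns `subject_id`, `arm`, `period`, `group`,
#'   `matrix`, `analyte`, `nominal_time_h`.
#' @keywords internal
design_schedule <- function(design) {
  stopifnot(inherits(design, "study_design"))
  specs <- matrix_specs()
  out <- vector("list", 0L)
  for (i in seq_along(design$subjects)) {
    subj <- design$subjects[i]
    arm <- design$arm[i]
    grp <- design$group[i]
    periods <- if (arm == "TFV") design$periods else "single_oral"
    for (per in periods) {
      for (j in seq_len(nrow(specs))) {
        mat <- specs$matrix[j]
        ana <- specs$analyte[j]
        if (mat %in% c("rectal_tissue", "rectal_mmc")) {
          stage <- if (per == "multiple_rectal") "multiple" else "single"
          times <- design$biopsy_times_h[[stage]][[grp]]
        } else {
          times <- design$core_times_h
        }
        out[[length(out) + 1L]] <- data.frame(
          subject_id = subj, arm = arm, period = per, group = grp,
          matrix = mat, analyte = ana, nominal_time_h = times,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

#' One-compartment concentration-time curve with first-order absorption
#'
#' C(t) = D * ka / (ka - ke) * (exp(-ke t) - exp(-ka t)). When `ka == ke` the
#' removable singularity is handled by its analytic limit D * ka * t * exp(-ka t)
#' only if `allow_equal_rates = TRUE`; otherwise equal rates are rejected so a
#' mis-specified kinetic block fails loudly.
#'
#' In the flip-flop regime (`ka < ke`) the terminal slope of the curve is `ka`,
#' i.e. absorption rate-limits the apparent elimination — the regime the rectal
#' plasma kinetics are generated in.
#'
#' @param t times (h), non-negative.
#' @param ka absorption rate constant (1/h).
#' @param ke elimination rate constant (1/h).
#' @param D dose scale in matrix concentration units.
#' @param allow_equal_rates permit the ka == ke limit form.
#' @return concentrations at `t`, same units as `D`.
#' @export
#' @examples
#' conc_curve(c(1, 2, 4), ka = 1, ke = 0.1, D = 100)
conc_curve <- function(t, ka, ke, D, allow_equal_rates = FALSE) {
  if (any(t < 0)) stop("negative times are not allowed", call. = FALSE)
  stopifnot(ka > 0, ke > 0, D >= 0)
  if (ka == ke) {
    if (!allow_equal_rates)
      stop("ka == ke; set allow_equal_rates = TRUE for the limit form",
           call. = FALSE)
    return(D * ka * t * exp(-ka * t))
  }
  D * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
}

#' Time of maximum of the one-compartment curve
#'
#' Closed-form maximizer t* = ln(ka/ke) / (ka - ke) (limit 1/ka when the rates
#' are equal).
#'
#' @inheritParams conc_curve
#' @return tmax in hours.
#' @export
conc_curve_tmax <- function(ka, ke) {
  stopifnot(ka > 0, ke > 0)
  if (ka == ke) return(1 / ka)
  log(ka / ke) / (ka - ke)
}

#' Multiple-dose curve by superposition
#'
#' Concentration at time `t` after the n-th daily dose of a linear-kinetics
#' drug equals the sum of `n` single-dose curves offset by the dosing interval
#' (24 h). Pre-dose concentrations at t = 0 are nonzero for n > 1.
#'
#' @inheritParams conc_curve
#' @param n_doses number of daily doses already given (default 7).
#' @param tau_h dosing interval in hours (default 24).
#' @export
conc_curve_multi <- function(t, ka, ke, D, n_doses = 7L, tau_h = 24,
                             allow_equal_rates = FALSE) {
  stopifnot(n_doses >= 1L, tau_h > 0)
  out <- numeric(length(t))
  for (j in seq_len(n_doses) - 1L)
    out <- out + conc_curve(t + j * tau_h, ka, ke, D, allow_equal_rates)
  out
}

#' Kinetic parameter blocks for the synthetic cohort
#'
#' One block per period x matrix x analyte for the kinetically simulated
#' matrices (plasma TFV, PBMC TFVdp, rectal fluid TFV, rectal tissue TFV and
#' TFVdp); the mucosal-cell and vaginal-fluid matrices are derived through
#' cross-matrix links (see [cross_matrix_models()]). Defaults target the
#' study's headline observed quantities: oral plasma half-life 10.8 h with
#' Cmax about 250 ng/mL and Tmax near 1.9 h; rectal plasma in the flip-flop
#' regime (ka < ke) with apparent terminal half-life 4.56 h and Cmax about
#' 10.5 ng/mL; rectal fluid Cmax around 7.4e5 ng/g after a rectal dose and
#' 9.8e3 ng/g after oral dosing; tissue TFV 30-min levels of a few ng/mg
#' under rectal dosing; tissue TFVdp with a long (60 h) effective
#' intracellular half-life so seven daily doses accumulate roughly four-fold,
#' and an oral tissue TFVdp scale below its LLOQ, reproducing the censoring
#' pattern of oral dosing.
#'
#' `cmax_target` is the peak of a single-dose curve and `D` the dose scale
#' achieving it; the multiple-dose period superposes seven such doses, so
#' accumulation emerges from the kinetics rather than from a separate target.
#' Between-subject variability is log-normal on `D` and `ke` with the given
#' CVs; residual assay noise is normal on the log10 scale.
#'
#' @param bsv_cv_D,bsv_cv_ke between-subject coefficients of variation.
#' @param noise_sd_log10 residual log10-scale noise sd.
#' @return data.frame of class `kinetic_params`, one row per period x matrix
#'   x analyte.
#' @export
kinetic_params <- function(bsv_cv_D = 0.5, bsv_cv_ke = 0.2,
                           noise_sd_log10 = 0.15) {
  stopifnot(bsv_cv_D >= 0, bsv_cv_ke >= 0, noise_sd_log10 >= 0)
  row <- function(period, matrix, analyte, ka, ke, cmax)
    data.frame(period = period, matrix = matrix, analyte = analyte,
               ka = ka, ke = ke, cmax_target = cmax)
  t_half <- function(h) log(2) / h
  kp <- rbind(
    # oral plasma: ka set so tmax is about 1.9 h; ke gives the 10.8 h
    # half-life. rectal plasma: flip-flop regime, terminal slope = ka
    # (4.56 h apparent half-life); fast ke puts tmax near the 0.5 h sample
    row("single_oral", "plasma", "TFV", 1.8, t_half(10.8), 250),
    row("single_rectal", "plasma", "TFV", t_half(4.56), 10, 10.5),
    row("multiple_rectal", "plasma", "TFV", t_half(4.56), 10, 10.5),
    # PBMC TFVdp: detectable only around the oral median; rectal dosing far
    # below the 8 fmol/10^6 cells LLOQ (all censored)
    row("single_oral", "pbmc", "TFVdp", 0.5, t_half(20), 0.38),
    row("single_rectal", "pbmc", "TFVdp", 0.5, t_half(20), 0.05),
    row("multiple_rectal", "pbmc", "TFVdp", 0.5, t_half(20), 0.05),
    # rectal fluid: oral exposure arrives late and low; topical is immediate
    row("single_oral", "rectal_fluid", "TFV", 0.05, t_half(8), 9800),
    row("single_rectal", "rectal_fluid", "TFV", 8, t_half(4), 7.4e5),
    row("multiple_rectal", "rectal_fluid", "TFV", 8, t_half(4), 7.4e5),
    # tissue TFV washes out within a day (no net accumulation)
    row("single_oral", "rectal_tissue", "TFV", 0.1, t_half(12), 0.35),
    row("single_rectal", "rectal_tissue", "TFV", 4, t_half(4), 5.8),
    row("multiple_rectal", "rectal_tissue", "TFV", 4, t_half(4), 5.8),
    # tissue TFVdp: long intracellular retention drives multiple-dose
    # accumulation; oral scale sits below the 30 fmol/mg LLOQ
    row("single_oral", "rectal_tissue", "TFVdp", 0.1, t_half(60), 2),
    row("single_rectal", "rectal_tissue", "TFVdp", 4, t_half(60), 176),
    row("multiple_rectal", "rectal_tissue", "TFVdp", 4, t_half(60), 176)
  )
  # dose scale: unit curve peaks at conc_curve(tmax; ka, ke, 1)
  kp$D <- kp$cmax_target /
    mapply(function(ka, ke) conc_curve(conc_curve_tmax(ka, ke), ka, ke, 1),
           kp$ka, kp$ke)
  attr(kp, "bsv_cv_D") <- bsv_cv_D
  attr(kp, "bsv_cv_ke") <- bsv_cv_ke
  attr(kp, "noise_sd_log10") <- noise_sd_log10
  class(kp) <- c("kinetic_params", "data.frame")
  kp
}
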