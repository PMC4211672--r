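jitter_sd_for_time <- function(t, jitter_sd_h) {
  ifelse(t == 0, 0,
         ifelse(t <= 4, jitter_sd_h[["intensive"]],
                ifelse(t <= 24, jitter_sd_h[["day1"]], jitter_sd_h[["visit"]])))
}

#' Simulate a multi-compartment concentration-record cohort
#'
#' Generates one concentration record per subject x period x matrix x analyte
#' x nominal time of the crossover design. Kinetic matrices (plasma TFV, PBMC
#' TFVdp, rectal fluid TFV, rectal tissue TFV) follow a one-compartment
#' first-order absorption curve with log-normal between-subject variability on
#' dose scale and elimination rate and log10-scale residual noise; the
#' multiple-rectal period superposes seven daily doses, so pre-dose
#' concentrations are nonzero. The metabolite matrices are derived through the
#' study's cross-matrix links: rectal tissue TFVdp from tissue TFV, mucosal
#' mononuclear cell TFVdp (CD4+, CD4-, total) from tissue TFVdp with the
#' cell-type intercept offset, and vaginal fluid TFV from rectal fluid (rectal
#' periods, fixed -1.06 log10 offset) or plasma (oral period, dose-route
#' model). Values below the matrix LLOQ are emitted with the `blq` flag set
#' and the value withheld. Sponge matrices are emitted as ng/sponge amounts
#' with the collected fluid weight, ready for [normalize_sponge()].
#'
#' @param design a [study_design()].
#' @param kinetics a [kinetic_params()] table.
#' @param specs a [matrix_specs()] table.
#' @param seed integer seed; identical seeds give identical record sets.
#' @param matrices optional character subset of matrices to generate.
#' @return data.frame of concentration records with columns `subject_id`,
#'   `arm`, `period`, `group`, `matrix`, `analyte`, `cell_fraction`,
#'   `nominal_time_h`, `actual_time_h`, `value`, `units`, `blq`,
#'   `sponge_fluid_g`.
#' @export
#' @examples
#' rec <- simulate_cohort(seed = 42)
#' table(rec$matrix, rec$period)
simulate_cohort <- function(design = study_design(),
                            kinetics = kinetic_params(),
                            specs = matrix_specs(),
                            seed = 1L,
                            matrices = NULL) {
  stopifnot(inherits(design, "study_design"))
  set.seed(as.integer(seed))
  sched <- design_schedule(design)
  if (!is.null(matrices)) sched <- sched[sched$matrix %in% matrices, ]
  if (!nrow(sched)) stop("empty schedule", call. = FALSE)

  bsv_D <- attr(kinetics, "bsv_cv_D")
  bsv_ke <- attr(kinetics, "bsv_cv_ke")
  noise <- attr(kinetics, "noise_sd_log10")
  sdlog_D <- sqrt(log(1 + bsv_D^2))
  sdlog_ke <- sqrt(log(1 + bsv_ke^2))

  # subject-level random effects, one pair per subject (shared across periods
  # and matrices: a "high absorber" is high everywhere)
  n_sub <- length(design$subjects)
  re_D <- exp(stats::rnorm(n_sub, 0, sdlog_D))
  re_ke <- exp(stats::rnorm(n_sub, 0, sdlog_ke))
  names(re_D) <- names(re_ke) <- design$subjects

  sched$cell_fraction <- ifelse(sched$matrix == "pbmc", "total",
                                ifelse(sched$matrix == "rectal_mmc", "total", "none"))

  # deterministic row order for reproducible draws
  sched <- sched[order(sched$subject_id, sched$period, sched$matrix,
                       sched$analyte, sched$nominal_time_h), ]

  # actual times: nominal + truncated-normal jitter (per-row sd, >= 0)
  sdj <- jitter_sd_for_time(sched$nominal_time_h, design$jitter_sd_h)
  z <- stats::rnorm(nrow(sched))
  act <- sched$nominal_time_h + z * sdj
  neg <- which(act < 0)
  while (length(neg)) {
    act[neg] <- sched$nominal_time_h[neg] + stats::rnorm(length(neg)) * sdj[neg]
    neg <- neg[act[neg] < 0]
  }
  sched$actual_time_h <- act

  # kinetic true concentrations (noise-free curve with subject effects)
  true_val <- rep(NA_real_, nrow(sched))
  kin_rows <- integer(0)
  for (i in seq_len(nrow(kinetics))) {
    kp <- kinetics[i, ]
    if (kp$ka == kp$ke)
      stop("kinetic block with ka == ke (", kp$period, " ", kp$matrix,
           "); use distinct rates", call. = FALSE)
    sel <- which(sched$matrix == kp$matrix & sched$period == kp$period &
                   sched$analyte == kp$analyte)
    if (!length(sel)) next
    kin_rows <- c(kin_rows, sel)
    Di <- kp$D * re_D[sched$subject_id[sel]]
    kei <- kp$ke * re_ke[sched$subject_id[sel]]
    kei[kei == kp$ka] <- kp$ka * (1 + 1e-9)  # guard removable singularity
    tt <- sched$actual_time_h[sel]
    v <- if (kp$period == "multiple_rectal") {
      mapply(function(t1, D1, ke1) conc_curve_multi(t1, kp$ka, ke1, D1, 7L),
             tt, Di, kei)
    } else {
      mapply(function(t1, D1, ke1) conc_curve(t1, kp$ka, ke1, D1),
             tt, Di, kei)
    }
    true_val[sel] <- v
  }

  # residual assay noise on kinetic matrices (log10 scale, skip zeros)
  kin_rows <- sort(kin_rows)
  if (noise > 0) {
    eps <- stats::rnorm(length(kin_rows), 0, noise)
    pos <- true_val[kin_rows] > 0
    true_val[kin_rows[pos]] <- true_val[kin_rows[pos]] * 10^eps[pos]
  }

  # derived matrices ------------------------------------------------------
  key_of <- function(d) paste(d$subject_id, d$period, d$nominal_time_h)

  # both tissue analytes come from the same biopsy: align actual times
  src <- which(sched$matrix == "rectal_tissue" & sched$analyte == "TFV")
  dst <- which(sched$matrix == "rectal_tissue" & sched$analyte == "TFVdp")
  if (length(dst)) {
    map <- match(key_of(sched[dst, ]), key_of(sched[src, ]))
    sched$actual_time_h[dst] <- sched$actual_time_h[src][map]
  }

  # mucosal mononuclear cells from tissue TFVdp: CD4-, CD4+, total
  link_mmc <- reference_model("mmc_tfvdp_on_tissue_tfvdp")
  mmc <- which(sched$matrix == "rectal_mmc")
  if (length(mmc)) {
    map <- match(key_of(sched[mmc, ]), key_of(sched[dst, ]))
    base <- true_val[dst][map]
    lbase <- ifelse(base > 0, log10(base), NA_real_)
    eps_n <- stats::rnorm(length(mmc), 0, link_mmc$noise_sd_log10)
    eps_p <- stats::rnorm(length(mmc), 0, link_mmc$noise_sd_log10)
    v_neg <- ifelse(is.na(lbase), 0, 10^(link_mmc$beta0 + link_mmc$beta1 * lbase + eps_n))
    v_pos <- ifelse(is.na(lbase), 0,
                    10^(link_mmc$beta0 + link_mmc$beta2 + link_mmc$beta1 * lbase + eps_p))
    sched$actual_time_h[mmc] <- sched$actual_time_h[dst][map]
    neg_rows <- sched[mmc, ]; neg_rows$cell_fraction <- "CD4neg"
    pos_rows <- sched[mmc, ]; pos_rows$cell_fraction <- "CD4pos"
    true_val[mmc] <- (v_neg + v_pos) / 2  # total fraction
    sched <- rbind(sched, neg_rows, pos_rows)
    true_val <- c(true_val, v_neg, v_pos)
  }

  # vaginal fluid TFV: rectal periods from rectal fluid (-1.06 log10);
  # oral period from plasma via the dose-route model (route = 0)
  vag <- which(sched$matrix == "vaginal_fluid")
  if (length(vag)) {
    rf <- which(sched$matrix == "rectal_fluid")
    pl <- which(sched$matrix == "plasma")
    link_v <- reference_model("vaginal_tfv_on_plasma_route")
    eps <- stats::rnorm(length(vag), 0, 0.15)
    eps_o <- stats::rnorm(length(vag), 0, link_v$noise_sd_log10)
    for (k in seq_along(vag)) {
      r <- vag[k]
      if (sched$period[r] == "single_oral") {
        m <- match(key_of(sched[r, , drop = FALSE]), key_of(sched[pl, ]))
        base <- true_val[pl][m]
        true_val[r] <- if (isTRUE(base > 0))
          10^(link_v$beta0 + link_v$beta1 * log10(base) + eps_o[k]) else 0
      } else {
        m <- match(key_of(sched[r, , drop = FALSE]), key_of(sched[rf, ]))
        base <- true_val[rf][m]
        true_val[r] <- if (isTRUE(base > 0))
          base * 10^(-1.06 + eps[k]) else 0
      }
    }
  }

  # units, censoring, sponge bookkeeping ----------------------------------
  sk <- paste(sched$matrix, sched$analyte)
  spk <- paste(specs$matrix, specs$analyte)
  m <- match(sk, spk)
  if (anyNA(m)) stop("schedule contains matrix/analyte without a spec")
  sched$units <- specs$units[m]
  lloq <- specs$lloq[m]

  sched$blq <- as.integer(!is.na(true_val) & true_val < lloq)
  sched$value <- ifelse(sched$blq == 1L, NA_real_, true_val)

  sponge <- sched$matrix %in% c("rectal_fluid", "vaginal_fluid")
  sched$sponge_fluid_g <- NA_real_
  if (any(sponge)) {
    w <- stats::runif(sum(sponge), 0.05, 0.40)
    sched$sponge_fluid_g[sponge] <- round(w, 4)
    # emit sponges as mass per sponge; standardization divides by weight
    sched$value[sponge] <- sched$value[sponge] * sched$sponge_fluid_g[sponge]
    sched$units[sponge] <- "ng/sponge"
  }

  sched <- sched[order(sched$subject_id, sched$period, sched$matrix,
                       sched$analyte, sched$cell_fraction,
                       sched$nominal_time_h), ]
  rownames(sched) <- NULL
  sched$value <- ifelse(is.na(sched$value), NA_real_, signif(sched$value, 8))
  sched[, c("subject_id", "arm", "period", "group", "matrix", "analyte",
            "cell_fraction", "nominal_time_h", "actual_time_h", "value",
            "units", "blq", "sponge_fluid_g")]
}

#' Write / read the concentration-record CSV dialect
#'
#' One row per record, mandatory header, UTF-8, missing values as empty
#' fields.
#'
#' @param records data.frame as returned by [simulate_cohort()].
#' @param path file path.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8",
                         colClasses = c(subject_id = "character"))
  num <- c("nominal_time_h", "actual_time_h", "value", "sponge_fluid_g")
  for (cn in intersect(num, names(rec))) rec[[cn]] <- as.numeric(rec[[cn]])
  rec
}
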