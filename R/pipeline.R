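#' Run configuration for the analysis pipeline
#'
#' @param seed integer seed driving every stochastic stage.
#' @param input_csv optional path to an existing concentration-record CSV;
#'   when `NULL` a synthetic cohort is simulated.
#' @param design,kinetics,specs study design, kinetic parameter and matrix
#'   specification blocks (synthetic mode).
#' @param blq_value NCA imputation constant (default 0.01).
#' @param alpha,m_comparisons family-wise alpha and number of planned
#'   contrasts (defaults 0.05 and 2, critical p 0.025).
#' @param psi,tuning_k,max_iter robust-regression estimator options.
#' @param out_dir output directory (created if needed).
#' @return object of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L, input_csv = NULL,
                            design = study_design(),
                            kinetics = kinetic_params(),
                            specs = matrix_specs(),
                            blq_value = 0.01, alpha = 0.05,
                            m_comparisons = 2L,
                            psi = "huber", tuning_k = NULL, max_iter = 100L,
                            out_dir = tempfile("mucosalpk_run_")) {
  structure(list(seed = as.integer(seed), input_csv = input_csv,
                 design = design, kinetics = kinetics, specs = specs,
                 blq_value = blq_value, alpha = alpha,
                 m_comparisons = as.integer(m_comparisons),
                 psi = psi, tuning_k = tuning_k,
                 max_iter = as.integer(max_iter), out_dir = out_dir),
            class = "run_config")
}

resolved_config_list <- function(config) {
  list(seed = config$seed,
       input_csv = if (is.null(config$input_csv)) "" else config$input_csv,
       n_subjects = length(config$design$subjects),
       n_active_gel = sum(config$design$arm == "TFV"),
       jitter_sd_h = as.list(config$design$jitter_sd_h),
       bsv_cv_D = attr(config$kinetics, "bsv_cv_D"),
       bsv_cv_ke = attr(config$kinetics, "bsv_cv_ke"),
       noise_sd_log10 = attr(config$kinetics, "noise_sd_log10"),
       lloq = stats::setNames(as.list(config$specs$lloq),
                              paste(config$specs$matrix, config$specs$analyte,
                                    sep = ".")),
       blq_value = config$blq_value, alpha = config$alpha,
       m_comparisons = config$m_comparisons, psi = config$psi,
       max_iter = config$max_iter)
}

#' Schema and invariant diagnostics for a record CSV
#'
#' Checks column presence, enumerated values, per-matrix units, BLQ/value
#' consistency, sponge fluid-weight presence, non-negative times and
#' monotone (non-duplicated) sampling times per profile. The data are not
#' modified.
#'
#' @param records a data.frame of records or a CSV path.
#' @return data.frame of diagnostics (`row`, `field`, `problem`); zero rows
#'   means a clean dataset.
#' @export
validate_records <- function(records) {
  if (is.character(records)) records <- read_records(records)
  diag <- list()
  note <- function(row, field, problem)
    diag[[length(diag) + 1L]] <<- data.frame(row = row, field = field,
                                             problem = problem)
  required <- c("subject_id", "arm", "period", "group", "matrix", "analyte",
                "cell_fraction", "nominal_time_h", "actual_time_h", "value",
                "units", "blq", "sponge_fluid_g")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    note(NA_integer_, paste(missing_cols, collapse = ","), "missing column")
    return(do.call(rbind, diag))
  }
  enums <- list(
    arm = c("TFV", "HEC"),
    period = c("single_oral", "single_rectal", "multiple_rectal"),
    group = c("A", "B"),
    matrix = c("plasma", "pbmc", "rectal_tissue", "rectal_mmc",
               "rectal_fluid", "vaginal_fluid"),
    analyte = c("TFV", "TFVdp"),
    cell_fraction = c("total", "CD4pos", "CD4neg", "none"))
  for (f in names(enums)) {
    bad <- which(!records[[f]] %in% enums[[f]])
    for (r in bad) note(r, f, paste0("invalid value '", records[[f]][r], "'"))
  }
  bad <- which(records$blq == 1L & !is.na(records$value))
  for (r in bad) note(r, "value", "blq record carries a numeric value")
  bad <- which(records$blq == 0L & is.na(records$value))
  for (r in bad) note(r, "value", "quantified record missing a value")
  bad <- which(records$actual_time_h < 0 | records$nominal_time_h < 0)
  for (r in bad) note(r, "actual_time_h", "negative time")
  sponge <- records$matrix %in% c("rectal_fluid", "vaginal_fluid")
  bad <- which(sponge & (is.na(records$sponge_fluid_g) |
                           records$sponge_fluid_g <= 0))
  for (r in bad) note(r, "sponge_fluid_g", "sponge record without fluid weight")
  bad <- which(!sponge & !is.na(records$sponge_fluid_g))
  for (r in bad) note(r, "sponge_fluid_g", "fluid weight on non-sponge matrix")
  key <- paste(records$subject_id, records$period, records$matrix,
               records$analyte, records$cell_fraction)
  dup <- which(duplicated(paste(key, records$actual_time_h)))
  for (r in dup) note(r, "actual_time_h", "duplicate sampling time in profile")
  if (!length(diag))
    return(data.frame(row = integer(0), field = character(0),
                      problem = character(0)))
  out <- do.call(rbind, diag)
  rownames(out) <- NULL
  out
}

nca_parameter_rows <- function(res, basis) {
  k <- res$key
  data.frame(
    subject_id = if (!is.null(k$subject_id)) k$subject_id else NA_character_,
    period = k$period, matrix = k$matrix, analyte = k$analyte,
    cell_fraction = if (!is.null(k$cell_fraction)) k$cell_fraction else "none",
    parameter = c("cmax", "tmax_h", "auc24", "half_life_h"),
    value = c(res$cmax, res$tmax_h, res$auc24, res$half_life_h),
    auc_flags = res$auc_flags, basis = basis)
}

#' Run the full simulate / standardize / NCA / regression / comparison
#' pipeline
#'
#' Orchestrates every analysis stage and writes the report bundle to
#' `config$out_dir`: `records.csv`, `exclusions.csv`, `nca_results.csv`,
#' `table2_summary.csv`, `composite_profiles.csv`, `accumulation_ratios.csv`,
#' `regression_report.csv`, `bands.csv`, `comparisons.csv`, a fully-resolved
#' `config_resolved.yaml` and a `run.log` of per-stage record counts. Outputs
#' are byte-identical for identical config + seed. Any stage failure removes
#' partial outputs and aborts with a stage-tagged message.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress console progress.
#' @return invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(out_dir, c(
    records = "records.csv", exclusions = "exclusions.csv",
    nca = "nca_results.csv", table2 = "table2_summary.csv",
    composite = "composite_profiles.csv",
    accumulation = "accumulation_ratios.csv",
    regression = "regression_report.csv", bands = "bands.csv",
    comparisons = "comparisons.csv", config = "config_resolved.yaml",
    log = "run.log"))
  names(files) <- c("records", "exclusions", "nca", "table2", "composite",
                    "accumulation", "regression", "bands", "comparisons",
                    "config", "log")
  log_lines <- character(0)
  stage <- "init"
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  on_fail <- function(e) {
    unlink(files)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    stage <- "simulate"
    t0 <- proc.time()[[3L]]
    records <- if (is.null(config$input_csv)) {
      simulate_cohort(config$design, config$kinetics, config$specs,
                      seed = config$seed)
    } else read_records(config$input_csv)
    say("[simulate] ", nrow(records), " records")

    stage <- "validate"
    diags <- validate_records(records)
    if (nrow(diags))
      stop(nrow(diags), " schema diagnostics; first: ", diags$problem[1L])
    say("[validate] 0 diagnostics")

    stage <- "standardize"
    std <- standardize_records(records)
    excl <- attr(std, "exclusions")
    write_records(std, files[["records"]])
    say("[standardize] ", nrow(std), " records (",
        nrow(excl), " sponge exclusions)")

    stage <- "nca"
    nca_rec <- impute_blq(std, "nca", config$blq_value)
    say("[nca] imputed ", attr(nca_rec, "n_imputed"), " BLQ records at ",
        config$blq_value)
    profiles <- suppressWarnings(assemble_profiles(nca_rec))
    elig <- Filter(function(p) p$eligible, profiles)
    inelig <- Filter(function(p) !p$eligible, profiles)
    excl2 <- do.call(rbind, c(list(excl), lapply(inelig, function(p)
      data.frame(subject_id = p$key$subject_id, period = p$key$period,
                 matrix = p$key$matrix, analyte = p$key$analyte,
                 nominal_time_h = NA_real_,
                 reason = paste(p$reasons, collapse = "; ")))))
    utils::write.csv(excl2, files[["exclusions"]], row.names = FALSE, na = "")
    say("[nca] ", length(elig), " eligible profiles, ", length(inelig),
        " ineligible")
    nca_tab <- do.call(rbind, lapply(elig, function(p)
      nca_parameter_rows(nca(p, config$blq_value), basis = "per_subject")))

    # composite profiles for the sparse biopsy matrices
    comp_rows <- list(); comp_nca <- list()
    for (mat in c("rectal_tissue", "rectal_mmc")) {
      for (per in config$design$periods) {
        for (ana in unique(nca_rec$analyte[nca_rec$matrix == mat])) {
          sel <- Filter(function(p)
            p$key$matrix == mat && p$key$period == per &&
              p$key$analyte == ana &&
              p$key$cell_fraction %in% c("none", "total"), profiles)
          if (length(sel) < 2L) next
          cp <- composite_profile(sel)
          comp_rows[[length(comp_rows) + 1L]] <- data.frame(
            period = per, matrix = mat, analyte = ana,
            nominal_time_h = cp$data$actual_time_h,
            median_value = cp$data$value, n = cp$n_per_time)
          if (nrow(cp$data) > 2L && min(cp$data$actual_time_h) <= 12) {
            res <- nca(cp, config$blq_value)
            res$key <- list(period = per, matrix = mat, analyte = ana,
                            cell_fraction = "total")
            comp_nca[[length(comp_nca) + 1L]] <-
              nca_parameter_rows(res, basis = "composite")
          }
        }
      }
    }
    utils::write.csv(do.call(rbind, comp_rows), files[["composite"]],
                     row.names = FALSE, na = "")
    nca_tab <- rbind(nca_tab, do.call(rbind, comp_nca))
    utils::write.csv(nca_tab, files[["nca"]], row.names = FALSE, na = "")
    say("[nca] ", nrow(nca_tab), " parameter rows")

    # Table-2-shaped summary: median (min-max); N per matrix x analyte x
    # parameter x period
    per_subj <- nca_tab[nca_tab$basis == "per_subject" &
                          is.finite(nca_tab$value), ]
    grp <- interaction(per_subj$matrix, per_subj$analyte, per_subj$parameter,
                       per_subj$period, drop = TRUE)
    t2 <- do.call(rbind, lapply(split(per_subj, grp), function(d)
      data.frame(matrix = d$matrix[1L], analyte = d$analyte[1L],
                 parameter = d$parameter[1L], period = d$period[1L],
                 median = stats::median(d$value), min = min(d$value),
                 max = max(d$value), N = nrow(d), basis = "per_subject")))
    t2 <- t2[order(t2$matrix, t2$analyte, t2$parameter, t2$period), ]
    utils::write.csv(t2, files[["table2"]], row.names = FALSE, na = "")

    stage <- "accumulation"
    acc <- list()
    by_key <- split(profiles, vapply(profiles, function(p)
      paste(p$key$subject_id, p$key$matrix, p$key$analyte,
            p$key$cell_fraction), ""))
    for (ps in by_key) {
      per <- vapply(ps, function(p) p$key$period, "")
      if (!all(c("single_rectal", "multiple_rectal") %in% per)) next
      multi <- ps[[which(per == "multiple_rectal")[1L]]]
      single <- ps[[which(per == "single_rectal")[1L]]]
      ar <- tryCatch(accumulation_ratio(multi, single),
                     error = function(e) NULL)
      if (is.null(ar) || is.na(ar$ratio)) next
      acc[[length(acc) + 1L]] <- data.frame(
        subject_id = multi$key$subject_id, matrix = multi$key$matrix,
        analyte = multi$key$analyte,
        cell_fraction = multi$key$cell_fraction,
        ratio = ar$ratio, basis = ar$basis)
    }
    acc <- do.call(rbind, acc)
    utils::write.csv(acc, files[["accumulation"]], row.names = FALSE, na = "")
    say("[accumulation] ", if (is.null(acc)) 0L else nrow(acc), " ratios")

    stage <- "correlate"
    corr_rec <- impute_blq(std, "correlation")
    say("[correlate] excluded ", attr(corr_rec, "n_excluded"),
        " BLQ records")
    models <- cross_matrix_models()
    rep_rows <- list(); band_rows <- list()
    for (i in seq_len(nrow(models))) {
      mrow <- models[i, ]
      d <- cohort_model_data(corr_rec, mrow)
      n_min <- if (mrow$cv_role == "none") 4L else 6L
      if (is.null(d) || nrow(d) < n_min) next
      form <- if (mrow$cv_role == "none") dv ~ iv else dv ~ iv * cv
      fit <- tryCatch(
        robust_lm(form, d, psi = config$psi, k = config$tuning_k,
                  alpha_drop = config$alpha, max_iter = config$max_iter),
        error = function(e) NULL)
      if (is.null(fit)) next
      cf <- fit$coefficients
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        model_id = mrow$model_id, term = names(cf), estimate = unname(cf),
        se = unname(fit$se), p = unname(fit$p_values), retained = TRUE,
        rse = fit$rse, n = fit$n_used)
      if (length(fit$elimination_trace))
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          model_id = mrow$model_id, term = fit$elimination_trace,
          estimate = NA_real_, se = NA_real_, p = NA_real_,
          retained = FALSE, rse = fit$rse, n = fit$n_used)
      grid <- data.frame(iv = seq(min(d$iv), max(d$iv), length.out = 25))
      if ("cv" %in% all.vars(fit$formula)) grid$cv <- 0
      pb <- predict(fit, grid, interval = "band")
      band_rows[[length(band_rows) + 1L]] <- data.frame(
        model_id = mrow$model_id, iv = grid$iv, fit = pb$fit,
        lo10 = pb$lo, hi90 = pb$hi)
    }
    utils::write.csv(do.call(rbind, rep_rows), files[["regression"]],
                     row.names = FALSE, na = "")
    utils::write.csv(do.call(rbind, band_rows), files[["bands"]],
                     row.names = FALSE, na = "")
    say("[correlate] ", length(band_rows), " models fitted")

    stage <- "compare"
    cmp <- list()
    for (sel in list(c("rectal_tissue", "TFV", "none"),
                     c("rectal_tissue", "TFVdp", "none"),
                     c("rectal_mmc", "TFVdp", "total"))) {
      d <- nca_rec[nca_rec$matrix == sel[1L] & nca_rec$analyte == sel[2L] &
                     nca_rec$cell_fraction == sel[3L], ]
      cc <- dosing_contrasts(d, 0.5, config$alpha, config$m_comparisons)
      cc <- cbind(matrix = sel[1L], analyte = sel[2L],
                  endpoint = "C30min", test = "wilcoxon_signed_rank", cc)
      cmp[[length(cmp) + 1L]] <- cc
    }
    # half-life contrast: paired t on log half-lives, oral vs single rectal
    hl <- nca_tab[nca_tab$parameter == "half_life_h" &
                    nca_tab$matrix == "plasma" & is.finite(nca_tab$value), ]
    ho <- hl[hl$period == "single_oral", ]
    hr <- hl[hl$period == "single_rectal", ]
    common <- intersect(ho$subject_id, hr$subject_id)
    if (length(common) >= 2L) {
      pt <- paired_t_log(ho$value[match(common, ho$subject_id)],
                         hr$value[match(common, hr$subject_id)])
      cmp[[length(cmp) + 1L]] <- data.frame(
        matrix = "plasma", analyte = "TFV", endpoint = "half_life_h",
        test = "paired_t_log", contrast = "oral_vs_single_rectal",
        n_pairs = pt$n_pairs, statistic = pt$t, p_value = pt$p_value,
        critical_p = config$alpha,
        significant = isTRUE(pt$p_value <= config$alpha))
    }
    cmp <- do.call(rbind, cmp)
    utils::write.csv(cmp, files[["comparisons"]], row.names = FALSE, na = "")
    say("[compare] ", nrow(cmp), " contrasts")

    stage <- "report"
    yaml::write_yaml(resolved_config_list(config), files[["config"]])
    writeLines(log_lines, files[["log"]])
    if (!quiet)
      message(sprintf("[done] %.1f s elapsed", proc.time()[[3L]] - t0))
  }, error = on_fail)
  invisible(as.list(files))
}

#' Extract paired log10 observations for one cross-matrix model from a cohort
#'
#' Matches dependent- and independent-variable records on subject, period and
#' nominal time (correlation mode: BLQ already excluded), log10-transforms
#' both, and encodes the covariate: CD4 cell type (CD4neg 0 / CD4pos 1) or
#' dose route (oral 0 / rectal 1).
#'
#' @param records correlation-mode records (ng/g sponge units, BLQ excluded).
#' @param model_row one row of [cross_matrix_models()].
#' @return data.frame `iv`, `cv`, `dv` or `NULL` when no pairs match.
#' @export
cohort_model_data <- function(records, model_row) {
  split_sel <- function(s) strsplit(s, ".", fixed = TRUE)[[1L]]
  dvs <- split_sel(model_row$dv)
  ivs <- split_sel(model_row$iv)
  dv_rec <- records[records$matrix == dvs[1L] & records$analyte == dvs[2L], ]
  iv_rec <- records[records$matrix == ivs[1L] & records$analyte == ivs[2L], ]
  if (model_row$cv_role == "cell_type") {
    dv_rec <- dv_rec[dv_rec$cell_fraction %in% c("CD4neg", "CD4pos"), ]
  } else if (dvs[1L] == "rectal_mmc") {
    dv_rec <- dv_rec[dv_rec$cell_fraction == "total", ]
  }
  if (ivs[1L] == "rectal_mmc") iv_rec <- iv_rec[iv_rec$cell_fraction == "total", ]
  if (model_row$model_id == "tissue_tfvdp_on_tissue_tfv_oral")
    dv_rec <- dv_rec[dv_rec$period == "single_oral", ]
  key <- function(d) paste(d$subject_id, d$period, d$nominal_time_h)
  m <- match(key(dv_rec), key(iv_rec))
  ok <- !is.na(m) & dv_rec$value > 0 & iv_rec$value[m] > 0
  if (!any(ok)) return(NULL)
  dv_rec <- dv_rec[ok, ]
  iv_val <- iv_rec$value[m[ok]]
  cv <- switch(model_row$cv_role,
               none = 0,
               cell_type = as.numeric(dv_rec$cell_fraction == "CD4pos"),
               route = as.numeric(dv_rec$period != "single_oral"))
  data.frame(iv = log10(iv_val), cv = cv, dv = log10(dv_rec$value))
}
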