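#' Normalize a sponge drug amount to a fluid concentration
#'
#' Sponge samples are assayed as drug mass per sponge (ng/sponge); dividing by
#' the weight of fluid collected on the sponge (grams, post-weight minus
#' pre-weight) gives the reported ng/g concentration.
#'
#' @param amount_ng_per_sponge drug mass recovered from the sponge (ng).
#' @param fluid_weight_g fluid weight on the sponge (g), must be > 0.
#' @return concentration in ng/g.
#' @export
#' @examples
#' normalize_sponge(100, 0.1)  # 1000 ng/g
normalize_sponge <- function(amount_ng_per_sponge, fluid_weight_g) {
  if (any(!is.finite(fluid_weight_g)) || any(fluid_weight_g <= 0))
    stop("fluid weight must be a positive number of grams", call. = FALSE)
  amount_ng_per_sponge / fluid_weight_g
}

#' Apply sponge normalization across a record set
#'
#' Converts every `ng/sponge` record to `ng/g` by dividing by
#' `sponge_fluid_g`. Sponge records with a missing or non-positive fluid
#' weight cannot be normalized: they are dropped and logged in the
#' `exclusions` attribute with reason `"invalid_sponge_weight"`.
#'
#' @param records concentration records (see [simulate_cohort()]).
#' @return records with sponge values in ng/g; attribute `exclusions` is a
#'   data.frame (subject_id, period, matrix, analyte, nominal_time_h, reason).
#' @export
standardize_records <- function(records) {
  sponge <- which(records$units == "ng/sponge")
  excl <- records[0, c("subject_id", "period", "matrix", "analyte",
                       "nominal_time_h")]
  excl$reason <- character(0)
  if (length(sponge)) {
    w <- records$sponge_fluid_g[sponge]
    bad <- sponge[!is.finite(w) | w <= 0]
    ok <- setdiff(sponge, bad)
    records$value[ok] <- records$value[ok] / records$sponge_fluid_g[ok]
    records$units[ok] <- "ng/g"
    if (length(bad)) {
      excl <- records[bad, c("subject_id", "period", "matrix", "analyte",
                             "nominal_time_h")]
      excl$reason <- "invalid_sponge_weight"
      records <- records[-bad, ]
    }
  }
  rownames(records) <- NULL
  attr(records, "exclusions") <- excl
  records
}

#' BLQ policy: impute for NCA or exclude for correlation analysis
#'
#' Below-limit-of-quantification records are handled differently by analysis
#' mode: for noncompartmental PK analysis every BLQ value is imputed as 0.01
#' in its native matrix units; for cross-matrix correlation analysis BLQ
#' records are excluded entirely.
#'
#' @param records concentration records.
#' @param mode `"nca"` (impute) or `"correlation"` (exclude).
#' @param imputed_value value assigned to BLQ records in nca mode
#'   (default 0.01, native matrix units).
#' @return records after the policy; attributes `n_imputed` / `n_excluded`
#'   count affected records.
#' @export
#' @examples
#' rec <- data.frame(value = c(5, NA), blq = c(0L, 1L))
#' impute_blq(rec, "nca")$value        # 5.00 0.01
#' nrow(impute_blq(rec, "correlation")) # 1
impute_blq <- function(records, mode = c("nca", "correlation"),
                       imputed_value = 0.01) {
  mode <- match.arg(mode)
  is_blq <- records$blq == 1L & (is.na(records$value) |
                                   records$value == imputed_value)
  # second clause keeps the operation idempotent: an already-imputed record
  # is not double-counted, an already-excluded set has no blq rows left
  if (mode == "nca") {
    n <- sum(is_blq & is.na(records$value))
    records$value[is_blq] <- imputed_value
    attr(records, "n_imputed") <- n
    attr(records, "n_excluded") <- 0L
  } else {
    n <- sum(records$blq == 1L)
    records <- records[records$blq != 1L, , drop = FALSE]
    rownames(records) <- NULL
    attr(records, "n_imputed") <- 0L
    attr(records, "n_excluded") <- n
  }
  records
}

#' Assemble per-profile objects and screen NCA eligibility
#'
#' Groups records by subject x period x matrix x analyte x cell fraction,
#' orders each group by actual sampling time (duplicate times keep the first
#' record, with a warning), and evaluates the three-clause eligibility rule
#' for per-subject NCA: (a) more than two data points, (b) last sampling time
#' at or before 24 h — extended to 26 h because the AUC engine interpolates
#' the 24 h concentration when the last actual time overshoots — and (c)
#' first sampling time at or before 12 h. Ineligible profiles are retained
#' with reason codes but should be excluded from per-subject NCA.
#'
#' @param records standardized records (post [impute_blq()] for NCA use).
#' @param last_time_max_h upper bound for clause (b) including the
#'   interpolation carve-out (default 26).
#' @return list of `pk_profile` objects; each has fields `key` (named list),
#'   `data` (time-ordered records), `eligible` (flag) and `reasons`
#'   (character vector of failed clauses).
#' @export
assemble_profiles <- function(records, last_time_max_h = 26) {
  key <- interaction(records$subject_id, records$period, records$matrix,
                     records$analyte, records$cell_fraction, drop = TRUE)
  out <- lapply(split(records, key), function(d) {
    d <- d[order(d$actual_time_h), , drop = FALSE]
    dup <- duplicated(d$actual_time_h)
    if (any(dup)) {
      warning("duplicate sampling time in profile ", d$subject_id[1L], " ",
              d$matrix[1L], "; keeping first record", call. = FALSE)
      d <- d[!dup, , drop = FALSE]
    }
    reasons <- character(0)
    if (nrow(d) <= 2L) reasons <- c(reasons, "<=2 points")
    if (nrow(d) >= 1L) {
      if (max(d$actual_time_h) > last_time_max_h)
        reasons <- c(reasons, "last point after 24 h window")
      if (min(d$actual_time_h) > 12)
        reasons <- c(reasons, "first point after 12 h")
    }
    structure(list(
      key = list(subject_id = d$subject_id[1L], period = d$period[1L],
                 matrix = d$matrix[1L], analyte = d$analyte[1L],
                 cell_fraction = d$cell_fraction[1L]),
      data = d,
      eligible = length(reasons) == 0L,
      reasons = reasons
    ), class = "pk_profile")
  })
  names(out) <- NULL
  out
}

#' @export
print.pk_profile <- function(x, ...) {
  k <- x$key
  cat(sprintf("PK profile %s / %s / %s %s (%s)\n", k$subject_id, k$period,
              k$matrix, k$analyte, k$cell_fraction))
  cat(sprintf("  %d points over %.2f-%.2f h; %s\n", nrow(x$data),
              min(x$data$actual_time_h), max(x$data$actual_time_h),
              if (x$eligible) "eligible for NCA"
              else paste("ineligible:", paste(x$reasons, collapse = "; "))))
  invisible(x)
}

#' Minimal profile constructor (times and values only)
#'
#' Convenience for tests and direct NCA use when full record metadata is not
#' needed.
#'
#' @param time_h actual sampling times (h), strictly increasing.
#' @param value concentrations at those times.
#' @param nominal_time_h optional nominal times (defaults to `time_h`).
#' @param key optional named list of identifiers.
#' @export
pk_profile <- function(time_h, value, nominal_time_h = time_h, key = list()) {
  stopifnot(length(time_h) == length(value))
  if (is.unsorted(time_h, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  d <- data.frame(nominal_time_h = nominal_time_h, actual_time_h = time_h,
                  value = value)
  structure(list(key = key, data = d,
                 eligible = nrow(d) > 2L && max(time_h) <= 26 && min(time_h) <= 12,
                 reasons = character(0)),
            class = "pk_profile")
}
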