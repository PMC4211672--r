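#' AUC to 24 h by the linear trapezoidal rule with endpoint rules
#'
#' Integrates the piecewise-linear concentration-time curve from the first
#' observation to 24 h using actual sampling times. Endpoint handling:
#' if the last sampling time exceeds 24 h and an earlier point at or before
#' 24 h exists, the 24 h concentration is linearly interpolated and the
#' integral truncated at 24 h (`interpolated_at_24`); if the last time falls
#' in \[22, 24) h, its concentration is carried forward as the 24 h value, so
#' the closing segment contributes a rectangle `C(t_L) * (24 - t_L)`
#' (`imputed_22_24`); if no point reaches 22 h the AUC runs only to the last
#' time and is flagged `truncated`.
#'
#' @param profile a `pk_profile` (values already BLQ-imputed).
#' @return list with `auc24` (conc x h) and `flags` (character).
#' @export
#' @examples
#' p <- pk_profile(c(0, 6, 12, 24), rep(10, 4))
#' auc24(p)$auc24  # 240
auc24 <- function(profile) {
  stopifnot(inherits(profile, "pk_profile"))
  t <- profile$data$actual_time_h
  y <- profile$data$value
  if (length(t) < 2L) stop("AUC needs at least 2 points", call. = FALSE)
  if (anyNA(y)) stop("AUC needs imputed values (run impute_blq first)",
                     call. = FALSE)
  flags <- character(0)
  tl <- t[length(t)]
  if (tl > 24) {
    keep <- t <= 24
    if (!any(keep)) stop("no observation at or before 24 h", call. = FALSE)
    c24 <- stats::approx(t, y, xout = 24)$y
    t <- c(t[keep], 24)
    y <- c(y[keep], c24)
    flags <- "interpolated_at_24"
  } else if (tl >= 22 && tl < 24) {
    # carry the last concentration forward to 24 h (rectangle segment)
    t <- c(t, 24)
    y <- c(y, y[length(y)])
    flags <- "imputed_22_24"
  } else if (tl < 22) {
    flags <- "truncated"
  }
  auc <- sum(diff(t) * (y[-1L] + y[-length(y)]) / 2)
  list(auc24 = auc, flags = if (length(flags)) flags else "none")
}

#' Maximum concentration and its time
#'
#' Ties are broken by the earliest time. An all-BLQ profile (every value equal
#' to the imputation constant) returns that constant at the first time and is
#' flagged degenerate.
#'
#' @param profile a `pk_profile`.
#' @param blq_value the NCA imputation constant used upstream.
#' @return list with `cmax`, `tmax_h`, `degenerate`.
#' @export
cmax_tmax <- function(profile, blq_value = 0.01) {
  y <- profile$data$value
  t <- profile$data$actual_time_h
  if (!length(y) || all(is.na(y))) stop("no values in profile", call. = FALSE)
  i <- which.max(y)  # first index at ties
  list(cmax = y[i], tmax_h = t[i],
       degenerate = all(y == blq_value))
}

#' Terminal (beta-phase) half-life
#'
#' Fits ln(concentration) against actual time by least squares over a terminal
#' point set and reports lambda_z = -slope and half-life ln(2)/lambda_z. In
#' `auto` mode all contiguous terminal subsets of at least 3 points drawn from
#' the points at or after Tmax (excluding the Tmax point itself whenever more
#' than 3 candidates exist) are scanned and the subset with the best adjusted
#' R-squared wins. `manual` selection takes explicit time points.
#'
#' @param profile a `pk_profile` with positive values.
#' @param selection `"auto"` or a numeric vector of times to use (manual).
#' @param blq_value imputation constant; fits containing such values are
#'   flagged `uses_imputed`.
#' @return list with `half_life_h`, `lambda_z`, `points` (times used),
#'   `adj_r2`, `flags`; half-life is `NA` (flagged) when no valid negative
#'   slope exists or fewer than 3 usable points remain.
#' @export
half_life <- function(profile, selection = "auto", blq_value = 0.01) {
  t <- profile$data$actual_time_h
  y <- profile$data$value
  i_tmax <- which.max(y)
  none <- list(half_life_h = NA_real_, lambda_z = NA_real_,
               points = numeric(0), adj_r2 = NA_real_)
  if (is.numeric(selection)) {
    keep <- t %in% selection & y > 0
    if (sum(keep) < 3L) return(c(none, list(flags = "fewer_than_3_points")))
    cand <- list(which(keep))
  } else {
    after <- which(seq_along(t) >= i_tmax & y > 0)
    if (length(after) < 3L) return(c(none, list(flags = "fewer_than_3_points")))
    if (length(after) > 3L) after <- setdiff(after, i_tmax)
    n_a <- length(after)
    # contiguous terminal subsets: last k points, k = 3..n_a
    cand <- lapply(3:n_a, function(k) after[(n_a - k + 1L):n_a])
  }
  best <- NULL
  for (idx in cand) {
    fit <- stats::lm.fit(cbind(1, t[idx]), log(y[idx]))
    r <- fit$residuals
    tss <- sum((log(y[idx]) - mean(log(y[idx])))^2)
    n <- length(idx)
    r2 <- if (tss > 0) 1 - sum(r^2) / tss else 1
    adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
    if (is.null(best) || adj > best$adj)
      best <- list(idx = idx, adj = adj,
                   slope = unname(fit$coefficients[2L]))
  }
  if (!is.finite(best$slope) || best$slope >= 0)
    return(c(none, list(flags = "non_negative_slope")))
  lam <- -best$slope
  flags <- if (any(y[best$idx] == blq_value)) "uses_imputed" else "none"
  list(half_life_h = log(2) / lam, lambda_z = unname(lam),
       points = t[best$idx], adj_r2 = best$adj, flags = flags)
}

#' Full noncompartmental summary of one profile
#'
#' @param profile a `pk_profile` (BLQ-imputed values).
#' @param blq_value imputation constant.
#' @return object of class `nca_result`.
#' @export
#' @examples
#' p <- pk_profile(c(0, 0.5, 2, 4, 24), conc_curve(c(0, 0.5, 2, 4, 24), 1, 0.1, 100))
#' nca(p)
nca <- function(profile, blq_value = 0.01) {
  stopifnot(inherits(profile, "pk_profile"))
  cm <- cmax_tmax(profile, blq_value)
  au <- auc24(profile)
  hl <- half_life(profile, blq_value = blq_value)
  structure(list(key = profile$key, cmax = cm$cmax, tmax_h = cm$tmax_h,
                 auc24 = au$auc24, auc_flags = au$flags,
                 half_life_h = hl$half_life_h, lambda_z = hl$lambda_z,
                 lambda_z_points = hl$points,
                 degenerate = cm$degenerate, n_points = nrow(profile$data)),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat("Noncompartmental PK summary\n")
  if (length(x$key))
    cat("  profile:", paste(unlist(x$key), collapse = " / "), "\n")
  cat(sprintf("  Cmax %.4g at Tmax %.3g h\n", x$cmax, x$tmax_h))
  cat(sprintf("  AUC24 %.4g (flags: %s)\n", x$auc24,
              paste(x$auc_flags, collapse = ", ")))
  if (is.finite(x$half_life_h))
    cat(sprintf("  terminal half-life %.4g h (lambda_z %.4g /h, %d points)\n",
                x$half_life_h, x$lambda_z, length(x$lambda_z_points)))
  else cat("  terminal half-life not estimable\n")
  invisible(x)
}

#' Composite median profile across subjects
#'
#' For sparse matrices (rectal biopsies) no subject has a complete profile;
#' the composite takes the median concentration across subjects at each
#' nominal time, regardless of actual time, and downstream NCA on the
#' composite uses nominal times. Values must be BLQ-imputed first. Nominal
#' times with no subjects are omitted.
#'
#' @param profiles list of `pk_profile` sharing period x matrix x analyte.
#' @return object of class `composite_profile`: a `pk_profile` on nominal
#'   times with `n_per_time`.
#' @export
composite_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  d <- do.call(rbind, lapply(profiles, function(p)
    p$data[, c("nominal_time_h", "value")]))
  d <- d[!is.na(d$value), , drop = FALSE]
  med <- tapply(d$value, d$nominal_time_h, stats::median)
  n <- tapply(d$value, d$nominal_time_h, length)
  tt <- as.numeric(names(med))
  o <- order(tt)
  k <- profiles[[1L]]$key
  out <- pk_profile(tt[o], as.numeric(med)[o],
                    key = list(period = k$period, matrix = k$matrix,
                               analyte = k$analyte, basis = "composite"))
  out$n_per_time <- as.integer(n)[o]
  class(out) <- c("composite_profile", class(out))
  out
}

#' @export
print.composite_profile <- function(x, ...) {
  cat("Composite median profile (no per-subject dispersion)\n")
  print(data.frame(nominal_time_h = x$data$actual_time_h,
                   median_value = x$data$value, n = x$n_per_time),
        row.names = FALSE)
  invisible(x)
}

#' Accumulation ratio of multiple- to single-dose exposure
#'
#' AUC24 ratio of the multiple-dose to the single-dose profile when both AUCs
#' are computable; otherwise the 0.5 h concentration ratio (records matched on
#' nominal time 0.5 h). The basis used is recorded.
#'
#' @param multi,single `pk_profile` objects for the same subject x matrix x
#'   analyte under multiple and single dosing.
#' @return list with `ratio`, `basis` (`"auc24_ratio"` or `"c30min_ratio"`),
#'   `flags`.
#' @export
accumulation_ratio <- function(multi, single) {
  auc_m <- tryCatch(auc24(multi), error = function(e) NULL)
  auc_s <- tryCatch(auc24(single), error = function(e) NULL)
  if (!is.null(auc_m) && !is.null(auc_s) && auc_s$auc24 > 0) {
    return(list(ratio = auc_m$auc24 / auc_s$auc24, basis = "auc24_ratio",
                flags = "none"))
  }
  c_at <- function(p) {
    i <- which(p$data$nominal_time_h == 0.5)
    if (length(i)) p$data$value[i[1L]] else NA_real_
  }
  cm <- c_at(multi); cs <- c_at(single)
  if (is.na(cm) || is.na(cs) || cs <= 0)
    return(list(ratio = NA_real_, basis = "c30min_ratio",
                flags = "denominator_missing"))
  list(ratio = cm / cs, basis = "c30min_ratio", flags = "none")
}

#' Coefficient of variation (percent) of concentrations at one nominal time
#'
#' 100 * sample sd / mean. Groups in which every value is identical (for
#' example all BLQ, all imputed to the same constant) return 0.
#'
#' @param values at least two concentration values.
#' @return CV in percent.
#' @export
#' @examples
#' cv_percent(c(1, 3))  # 70.7
cv_percent <- function(values) {
  if (length(values) < 2L) stop("CV%% needs at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("CV%% undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}
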