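#' Bonferroni-corrected critical p-value
#'
#' The two planned dosing contrasts (oral vs single rectal, single vs multiple
#' rectal) are tested against alpha / m; with alpha 0.05 and m = 2 the
#' critical p-value is 0.025.
#'
#' @param alpha family-wise significance level, in (0, 1).
#' @param m number of planned comparisons, >= 1.
#' @return alpha / m.
#' @export
#' @examples
#' bonferroni_critical(0.05, 2)  # 0.025
bonferroni_critical <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be a positive integer", call. = FALSE)
  alpha / m
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on the paired differences x - y. Zero
#' differences are dropped before ranking (Wilcoxon's original treatment);
#' with no ties among the absolute differences and at most `exact_max_n`
#' remaining pairs the p-value is exact (full enumeration of sign
#' assignments), otherwise the normal approximation with continuity and tie
#' corrections is used. All differences zero gives p = 1, flagged degenerate.
#'
#' @param x,y paired measurements (same subjects, same order).
#' @param exact_max_n largest n for the exact p-value (default 15).
#' @return list with `statistic` (V, sum of positive ranks), `p_value`,
#'   `n_pairs` (nonzero differences used), `exact`, `degenerate`.
#' @export
#' @examples
#' wilcoxon_paired(c(5, 7, 9, 11, 13, 15), c(1, 2, 3, 4, 5, 6))$p_value # 0.03125
wilcoxon_paired <- function(x, y, exact_max_n = 15L) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p_value = 1, n_pairs = 0L,
                exact = TRUE, degenerate = TRUE))
  ties <- any(duplicated(abs(d)))
  use_exact <- !ties && n <= exact_max_n
  wt <- suppressWarnings(stats::wilcox.test(
    d, mu = 0, alternative = "two.sided",
    exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = min(1, wt$p.value),
       n_pairs = n, exact = use_exact, degenerate = FALSE)
}

#' Paired t-test on log-transformed values
#'
#' One-sample t on log(x) - log(y), two-sided, df = n - 1. Used for
#' half-life comparisons (half-lives are log-normally distributed across
#' subjects). A constant ratio across all pairs gives zero variance of the
#' differences; the result is flagged degenerate rather than reporting an
#' infinite t.
#'
#' @param x,y paired positive values.
#' @return list with `t`, `p_value`, `df`, `n_pairs`, `degenerate`.
#' @export
paired_t_log <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (any(x <= 0) || any(y <= 0))
    stop("log-scale paired t needs strictly positive values", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- log(x) - log(y)
  if (stats::sd(d) < 1e-10 * max(abs(d), 1)) {
    if (all(abs(d) < 1e-12))
      return(list(t = 0, p_value = 1, df = length(d) - 1L,
                  n_pairs = length(d), degenerate = FALSE))
    return(list(t = Inf * sign(d[1L]), p_value = NA_real_,
                df = length(d) - 1L, n_pairs = length(d), degenerate = TRUE))
  }
  tt <- stats::t.test(d, mu = 0)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), n_pairs = length(d), degenerate = FALSE)
}

#' Median percentage ratio between two matrices at matched times
#'
#' Matches records on subject and nominal time (both members non-BLQ) and
#' reports the median of 100 * numerator / denominator — e.g. vaginal fluid
#' concentrations as a percentage of rectal fluid concentrations sampled at
#' the same time.
#'
#' @param num,den data.frames of records with columns `subject_id`,
#'   `nominal_time_h`, `value`, `blq`.
#' @return list with `median_percent` and `n_pairs`; `median_percent` is `NA`
#'   when no pairs match.
#' @export
concentration_ratio_summary <- function(num, den) {
  key <- function(d) paste(d$subject_id, d$nominal_time_h)
  num <- num[num$blq == 0L & !is.na(num$value), ]
  den <- den[den$blq == 0L & !is.na(den$value) & den$value > 0, ]
  m <- match(key(num), key(den))
  ok <- !is.na(m)
  if (!any(ok)) return(list(median_percent = NA_real_, n_pairs = 0L))
  ratio <- 100 * num$value[ok] / den$value[m[ok]]
  list(median_percent = stats::median(ratio), n_pairs = sum(ok))
}

#' Planned paired dosing contrasts for one matrix x analyte x time
#'
#' Runs the two planned contrasts (single oral vs single rectal; single vs
#' multiple rectal) as paired Wilcoxon signed-rank tests at the
#' Bonferroni-corrected critical p, pairing on subject.
#'
#' @param records BLQ-imputed records for one matrix/analyte/cell fraction.
#' @param nominal_time_h the sampling time compared (default 0.5 h).
#' @param alpha family-wise alpha (default 0.05).
#' @param m_comparisons number of planned comparisons (default 2).
#' @return data.frame, one row per contrast: `contrast`, `n_pairs`,
#'   `statistic`, `p_value`, `critical_p`, `significant`.
#' @export
dosing_contrasts <- function(records, nominal_time_h = 0.5, alpha = 0.05,
                             m_comparisons = 2L) {
  crit <- bonferroni_critical(alpha, m_comparisons)
  at_t <- records[records$nominal_time_h == nominal_time_h, ]
  val <- function(per) {
    d <- at_t[at_t$period == per, ]
    stats::setNames(d$value, d$subject_id)
  }
  one <- function(a, b, label) {
    va <- val(a); vb <- val(b)
    common <- intersect(names(va), names(vb))
    if (length(common) < 2L)
      return(data.frame(contrast = label, n_pairs = length(common),
                        statistic = NA_real_, p_value = NA_real_,
                        critical_p = crit, significant = NA))
    w <- wilcoxon_paired(va[common], vb[common])
    data.frame(contrast = label, n_pairs = w$n_pairs,
               statistic = w$statistic, p_value = w$p_value,
               critical_p = crit, significant = w$p_value <= crit)
  }
  rbind(one("single_oral", "single_rectal", "oral_vs_single_rectal"),
        one("single_rectal", "multiple_rectal", "single_vs_multiple_rectal"))
}
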