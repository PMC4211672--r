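#' Cross-matrix log10-linear model specification
#'
#' A generative model on the log10 concentration scale,
#' dv = beta0 + beta1 * iv + beta2 * cv + beta3 * iv * cv + eps,
#' where `iv`/`dv` are log10-transformed concentrations in two matrices, `cv`
#' is a 0/1 covariate (cell type or dose route), and eps is a two-component
#' normal mixture: a core component with sd `noise_sd_log10` and, with
#' probability `contamination_fraction`, an outlier component whose sd is
#' inflated by `contamination_scale`.
#'
#' @param beta0,beta1 intercept and slope (log10 scale).
#' @param beta2 categorical offset (default 0).
#' @param beta3 interaction coefficient (default 0).
#' @param noise_sd_log10 residual sd on the log10 scale (> 0 for stochastic
#'   generation; 0 allowed for noiseless checks).
#' @param contamination_fraction probability of the outlier component, in
#'   `[0, 0.5)`.
#' @param contamination_scale sd inflation of the outlier component (>= 1).
#' @param iv_matrix,dv_matrix optional labels for the matrices involved.
#' @return object of class `cross_matrix_model`.
#' @export
#' @examples
#' m <- cross_matrix_model(2.37, 0.366, noise_sd_log10 = 0.37)
#' d <- simulate_regression_data(m, n = 50, x_range_log10 = c(-1, 1), seed = 1)
#' head(d)
cross_matrix_model <- function(beta0, beta1, beta2 = 0, beta3 = 0,
                               noise_sd_log10 = 0,
                               contamination_fraction = 0,
                               contamination_scale = 1,
                               iv_matrix = NA_character_,
                               dv_matrix = NA_character_) {
  stopifnot(is.finite(beta0), is.finite(beta1),
            noise_sd_log10 >= 0,
            contamination_fraction >= 0, contamination_fraction < 0.5,
            contamination_scale >= 1)
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 noise_sd_log10 = noise_sd_log10,
                 contamination_fraction = contamination_fraction,
                 contamination_scale = contamination_scale,
                 iv_matrix = iv_matrix, dv_matrix = dv_matrix),
            class = "cross_matrix_model")
}

#' @export
print.cross_matrix_model <- function(x, ...) {
  cat("Cross-matrix log10-linear model\n")
  cat(sprintf("  dv = %.3g + %.3g*iv", x$beta0, x$beta1))
  if (x$beta2 != 0) cat(sprintf(" + %.3g*cv", x$beta2))
  if (x$beta3 != 0) cat(sprintf(" + %.3g*iv:cv", x$beta3))
  cat(sprintf("  (noise sd %.3g log10)\n", x$noise_sd_log10))
  if (!is.na(x$iv_matrix))
    cat("  iv:", x$iv_matrix, " dv:", x$dv_matrix, "\n")
  invisible(x)
}

#' Reference cross-matrix models of the rectal TFV gel / oral TDF study
#'
#' The eight fitted robust log10-linear models the study reports, with their
#' coefficients, standard errors, robust residual scale (RSE) and the log10
#' concentration range of the independent variable used when simulating from
#' them. The covariate (`cv_role`) is the CD4 cell type for the mucosal
#' mononuclear cell model and the dose route (oral 0 / rectal 1) for the
#' vaginal-fluid-on-plasma model.
#'
#' @return data.frame with one row per model; columns `model_id`, `dv`, `iv`,
#'   `cv_role`, `beta0`, `beta1`, `beta2`, `se0`, `se1`, `se2`, `rse`,
#'   `iv_lo`, `iv_hi` (log10-scale simulation range).
#' @export
cross_matrix_models <- function() {
  m <- rbind(
    data.frame(model_id = "tissue_tfvdp_on_tissue_tfv_oral",
               dv = "rectal_tissue.TFVdp", iv = "rectal_tissue.TFV",
               cv_role = "none", beta0 = 2.37, beta1 = 0.366, beta2 = 0,
               se0 = 0.168, se1 = 0.121, se2 = NA, rse = 0.37,
               iv_lo = -1, iv_hi = 1),
    data.frame(model_id = "mmc_tfvdp_on_tissue_tfvdp",
               dv = "rectal_mmc.TFVdp", iv = "rectal_tissue.TFVdp",
               cv_role = "cell_type", beta0 = 0.680, beta1 = 0.628,
               beta2 = 0.586, se0 = 0.205, se1 = 0.0818, se2 = 0.125,
               rse = 0.46, iv_lo = 1, iv_hi = 4),
    data.frame(model_id = "plasma_tfv_on_rectal_fluid",
               dv = "plasma.TFV", iv = "rectal_fluid.TFV",
               cv_role = "none", beta0 = -1.23, beta1 = 0.386, beta2 = 0,
               se0 = 0.170, se1 = 0.0328, se2 = NA, rse = 0.38,
               iv_lo = 2, iv_hi = 6),
    data.frame(model_id = "tissue_tfv_on_rectal_fluid",
               dv = "rectal_tissue.TFV", iv = "rectal_fluid.TFV",
               cv_role = "none", beta0 = -2.43, beta1 = 0.634, beta2 = 0,
               se0 = 0.335, se1 = 0.0777, se2 = NA, rse = 0.67,
               iv_lo = 2, iv_hi = 6),
    data.frame(model_id = "tissue_tfvdp_on_rectal_fluid",
               dv = "rectal_tissue.TFVdp", iv = "rectal_fluid.TFV",
               cv_role = "none", beta0 = 1.41, beta1 = 0.197, beta2 = 0,
               se0 = 0.272, se1 = 0.0612, se2 = NA, rse = 0.66,
               iv_lo = 2, iv_hi = 6),
    data.frame(model_id = "vaginal_tfv_on_plasma_route",
               dv = "vaginal_fluid.TFV", iv = "plasma.TFV",
               cv_role = "route", beta0 = 1.32, beta1 = 0.778,
               beta2 = 0.951, se0 = 0.0948, se1 = 0.0704, se2 = 0.169,
               rse = 0.44, iv_lo = -0.5, iv_hi = 2.5),
    data.frame(model_id = "vaginal_tfv_on_tissue_tfv",
               dv = "vaginal_fluid.TFV", iv = "rectal_tissue.TFV",
               cv_role = "none", beta0 = -0.37, beta1 = 0.741, beta2 = 0,
               se0 = 0.402, se1 = 0.105, se2 = NA, rse = 0.47,
               iv_lo = -1, iv_hi = 1),
    data.frame(model_id = "vaginal_tfv_on_tissue_tfvdp",
               dv = "vaginal_fluid.TFV", iv = "rectal_tissue.TFVdp",
               cv_role = "none", beta0 = -6.91, beta1 = 1.66, beta2 = 0,
               se0 = 0.649, se1 = 0.114, se2 = NA, rse = 0.13,
               iv_lo = 1.5, iv_hi = 3)
  )
  m
}

#' Build a [cross_matrix_model()] from a reference table row
#'
#' @param model_id a `model_id` from [cross_matrix_models()].
#' @export
reference_model <- function(model_id) {
  tab <- cross_matrix_models()
  row <- tab[tab$model_id == model_id, ]
  if (nrow(row) != 1L) stop("unknown model_id: ", model_id, call. = FALSE)
  cross_matrix_model(row$beta0, row$beta1, beta2 = row$beta2,
                     noise_sd_log10 = row$rse,
                     iv_matrix = row$iv, dv_matrix = row$dv)
}

#' Simulate paired log10-scale observations from a cross-matrix model
#'
#' `iv` is uniform over `x_range_log10`; when the model carries a covariate
#' (`beta2` or `beta3` nonzero, or `balanced_cv = TRUE`) half the observations
#' get cv = 0 and half cv = 1. Residuals are the two-component normal mixture
#' described in [cross_matrix_model()].
#'
#' @param model a [cross_matrix_model()].
#' @param n number of observations (>= 10).
#' @param x_range_log10 length-2 interval for the iv values.
#' @param seed integer seed; the generation is reproducible given the seed.
#' @param balanced_cv force a balanced 0/1 covariate even when beta2 = 0
#'   (used to test that backward elimination drops a null covariate).
#' @return data.frame with columns `iv`, `cv`, `dv` (log10 scale) and
#'   `outlier` (logical, drawn from the inflated component).
#' @export
simulate_regression_data <- function(model, n, x_range_log10, seed = NULL,
                                     balanced_cv = FALSE) {
  stopifnot(inherits(model, "cross_matrix_model"))
  if (n < 10) stop("n must be >= 10", call. = FALSE)
  if (length(x_range_log10) != 2L || diff(range(x_range_log10)) <= 0)
    stop("x_range_log10 must be a non-empty interval", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  iv <- stats::runif(n, min(x_range_log10), max(x_range_log10))
  has_cv <- balanced_cv || model$beta2 != 0 || model$beta3 != 0
  cv <- if (has_cv) rep_len(c(0, 1), n)[sample.int(n)] else rep(0, n)
  outlier <- stats::runif(n) < model$contamination_fraction
  sd_i <- model$noise_sd_log10 * ifelse(outlier, model$contamination_scale, 1)
  eps <- if (model$noise_sd_log10 > 0) stats::rnorm(n, 0, sd_i) else rep(0, n)
  dv <- model$beta0 + model$beta1 * iv + model$beta2 * cv +
    model$beta3 * iv * cv + eps
  data.frame(iv = iv, cv = cv, dv = dv, outlier = outlier)
}
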