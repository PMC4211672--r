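test_that("noiseless data are fitted exactly and null terms are dropped", {
  set.seed(1)
  d <- data.frame(iv = runif(40, -1, 2))
  d$cv <- rep_len(c(0, 1), 40)
  d$dv <- 1 + 2 * d$iv
  fit <- robust_lm(dv ~ iv * cv, d)
  expect_equal(unname(fit$coefficients[c("(Intercept)", "iv")]), c(1, 2),
               tolerance = 1e-10)
  expect_setequal(fit$retained_terms, "iv")
  expect_setequal(fit$elimination_trace, c("iv:cv", "cv"))
  expect_equal(fit$rse, 0, tolerance = 1e-10)
})

test_that("on clean normal data the robust fit tracks least squares", {
  set.seed(2)
  d <- data.frame(iv = runif(200, 0, 3))
  d$dv <- 0.5 + 1.2 * d$iv + rnorm(200, 0, 0.3)
  fit <- robust_lm(dv ~ iv, d, eliminate = FALSE)
  b_ols <- oracle_ols(cbind(1, d$iv), d$dv)
  expect_equal(unname(fit$coefficients), as.numeric(b_ols), tolerance = 0.02)
})

test_that("the fit agrees with an independent M-estimation implementation", {
  set.seed(3)
  m <- cross_matrix_model(-1.23, 0.386, noise_sd_log10 = 0.38,
                          contamination_fraction = 0.1,
                          contamination_scale = 8)
  d <- simulate_regression_data(m, 150, c(2, 6), seed = 4)
  fit <- robust_lm(dv ~ iv, d, eliminate = FALSE)
  ref <- MASS::rlm(dv ~ iv, d, psi = MASS::psi.huber, k = 1.345,
                   scale.est = "MAD", maxit = 100)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-3)
  se_ref <- sqrt(diag(vcov(ref)))
  expect_equal(unname(fit$se), unname(se_ref), tolerance = 0.1)
})

test_that("regression equivariance: dv shift moves only the intercept,
           iv scaling inverts the slope", {
  set.seed(4)
  d <- simulate_regression_data(cross_matrix_model(1, 0.7, noise_sd_log10 = 0.3),
                                100, c(0, 2), seed = 5)
  f0 <- robust_lm(dv ~ iv, d, eliminate = FALSE)
  d_shift <- transform(d, dv = dv + 3)
  f1 <- robust_lm(dv ~ iv, d_shift, eliminate = FALSE)
  expect_equal(f1$coefficients[["(Intercept)"]],
               f0$coefficients[["(Intercept)"]] + 3, tolerance = 1e-6)
  expect_equal(f1$coefficients[["iv"]], f0$coefficients[["iv"]],
               tolerance = 1e-6)
  d_scale <- transform(d, iv = 2 * iv)
  f2 <- robust_lm(dv ~ iv, d_scale, eliminate = FALSE)
  expect_equal(f2$coefficients[["iv"]], f0$coefficients[["iv"]] / 2,
               tolerance = 1e-6)
})

test_that("outliers displace the Huber fit far less than least squares", {
  set.seed(5)
  n <- 100
  d <- data.frame(iv = runif(n, 0, 3))
  d$dv <- 1 + 0.5 * d$iv + rnorm(n, 0, 0.2)
  slope_clean <- robust_lm(dv ~ iv, d, eliminate = FALSE)$coefficients[["iv"]]
  ols_clean <- oracle_ols(cbind(1, d$iv), d$dv)[2]
  bad <- sample(n, n %/% 10)
  d$dv[bad] <- d$dv[bad] + 10 * sign(rnorm(length(bad))) * 2
  slope_rob <- robust_lm(dv ~ iv, d, eliminate = FALSE)$coefficients[["iv"]]
  ols_bad <- oracle_ols(cbind(1, d$iv), d$dv)[2]
  expect_lt(abs(slope_rob - slope_clean), abs(ols_bad - ols_clean) / 3)
})

test_that("backward elimination is sound and refits reproduce the result", {
  set.seed(6)
  m <- cross_matrix_model(0.68, 0.628, beta2 = 0.586, noise_sd_log10 = 0.46)
  d <- simulate_regression_data(m, 300, c(1, 4), seed = 7)
  fit <- robust_lm(dv ~ iv * cv, d)
  # every retained non-intercept term is significant at the final fit
  keep <- setdiff(names(fit$p_values), "(Intercept)")
  expect_true(all(fit$p_values[keep] <= 0.05))
  # the interaction (true beta3 = 0) is dropped, cv (true beta2 != 0) kept
  expect_true("iv:cv" %in% fit$elimination_trace)
  expect_true("cv" %in% fit$retained_terms)
  # refitting the final term set from scratch reproduces the coefficients
  refit <- robust_lm(fit$formula, d, eliminate = FALSE)
  expect_equal(refit$coefficients, fit$coefficients, tolerance = 1e-8)
})

test_that("derived intercepts add the covariate offset and test it", {
  set.seed(7)
  # the printed mucosal-cell model: CD4+ intercept 0.680 + 0.586 = 1.27 (3 sf)
  d <- data.frame(iv = runif(60, 1, 4), cv = rep_len(c(0, 1), 60))
  d$dv <- 0.680 + 0.628 * d$iv + 0.586 * d$cv
  fit <- robust_lm(dv ~ iv + cv, d, eliminate = FALSE)
  di <- derived_intercepts(fit)
  expect_equal(unname(di$intercepts), c(0.680, 1.266), tolerance = 1e-6)
  expect_equal(signif(di$intercepts[["level1"]], 3), 1.27)
  # the printed vaginal route model: rectal intercept 1.32 + 0.951 = 2.27
  d$dv <- 1.32 + 0.778 * d$iv + 0.951 * d$cv
  di <- derived_intercepts(robust_lm(dv ~ iv + cv, d, eliminate = FALSE))
  expect_equal(unname(di$intercepts), c(1.32, 2.271), tolerance = 1e-6)
  # null offset: identical intercepts
  d$dv <- 1 + 0.5 * d$iv
  di <- derived_intercepts(robust_lm(dv ~ iv + cv, d, eliminate = FALSE))
  expect_equal(unname(di$intercepts["level0"]), 1, tolerance = 1e-8)
  expect_length(di$intercepts, 2L)
  # covariate dropped by elimination: one common intercept
  di <- derived_intercepts(robust_lm(dv ~ iv + cv, d))
  expect_named(di$intercepts, "common")
})

test_that("prediction band is centred, tightest at the centroid, zero for a
           perfect fit", {
  set.seed(8)
  d <- simulate_regression_data(cross_matrix_model(2, 0.5, noise_sd_log10 = 0.3),
                                120, c(-1, 1), seed = 9)
  fit <- robust_lm(dv ~ iv, d, eliminate = FALSE)
  grid <- data.frame(iv = seq(-1.5, 1.5, length.out = 61))
  pb <- predict(fit, grid, interval = "band")
  halfw <- (pb$hi - pb$lo) / 2
  # narrowest near the iv centroid; z_0.90 * SE at every point
  expect_lt(abs(grid$iv[which.min(halfw)] - mean(d$iv)), 0.2)
  expect_equal(halfw, qnorm(0.90) * pb$se_mean, tolerance = 1e-12)
  expect_true(all(pb$extrapolated[grid$iv < min(d$iv)]))
  expect_false(any(pb$extrapolated[grid$iv >= min(d$iv) &
                                     grid$iv <= max(d$iv)]))
  # noiseless fit: band collapses
  d0 <- data.frame(iv = seq(0, 1, length.out = 30))
  d0$dv <- 1 + 2 * d0$iv
  pb0 <- predict(robust_lm(dv ~ iv, d0), data.frame(iv = c(0.2, 0.8)),
                 interval = "band")
  expect_equal(pb0$hi - pb0$lo, c(0, 0), tolerance = 1e-10)
})

test_that("the 10-90% band covers the true mean prediction about 80% of the
           time", {
  set.seed(9)
  hits <- 0L; n_rep <- 400L
  x_eval <- data.frame(iv = 0.7)
  truth <- 1 + 0.5 * 0.7
  for (r in seq_len(n_rep)) {
    d <- data.frame(iv = runif(40, 0, 2))
    d$dv <- 1 + 0.5 * d$iv + rnorm(40, 0, 0.4)
    pb <- predict(robust_lm(dv ~ iv, d, eliminate = FALSE), x_eval,
                  interval = "band")
    if (pb$lo <= truth && truth <= pb$hi) hits <- hits + 1L
  }
  expect_gt(hits / n_rep, 0.72)
  expect_lt(hits / n_rep, 0.88)
})

test_that("fit errors are informative", {
  d <- data.frame(iv = c(1, 1, 1, 1, 1, 1), dv = c(1, 2, 3, 4, 5, 6))
  expect_error(robust_lm(dv ~ iv, d), "collinear")
  d2 <- data.frame(iv = c(1, 2, 3), dv = c(1, 2, 3))
  expect_error(robust_lm(dv ~ iv + I(iv^2), d2), "observations")
  d3 <- data.frame(iv = c(1, NA, 3, 4, 5), dv = 1:5)
  expect_error(robust_lm(dv ~ iv, d3))
})

test_that("simulate method reproduces the fitted error scale", {
  set.seed(10)
  d <- simulate_regression_data(cross_matrix_model(0, 1, noise_sd_log10 = 0.3),
                                200, c(0, 2), seed = 11)
  fit <- robust_lm(dv ~ iv, d, eliminate = FALSE)
  sims <- simulate(fit, nsim = 20, seed = 12)
  sds <- vapply(sims, function(s) sd(s - fit$fitted), numeric(1))
  expect_equal(mean(sds), fit$rse, tolerance = 0.1)
})
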