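test_that("AUC24 trapezoid handles the three endpoint rules", {
  # rectangle
  expect_equal(auc24(pk_profile(c(0, 6, 12, 24), rep(10, 4)))$auc24, 240)
  # plain trapezoid: 0.5*1*10 + 23*(10+2)/2 = 143
  r <- auc24(pk_profile(c(0, 1, 24), c(0, 10, 2)))
  expect_equal(r$auc24, 143)
  expect_identical(r$flags, "none")
  # last sample beyond 24 h: interpolate C(24) between (1,10) and (25,2),
  # truncate at 24
  r <- auc24(pk_profile(c(0, 1, 25), c(0, 10, 2)))
  c24 <- 10 + (2 - 10) * (24 - 1) / (25 - 1)
  expect_equal(c24, 7 / 3)
  expect_equal(r$auc24, 0.5 * 1 * 10 + (10 + c24) / 2 * 23)
  expect_identical(r$flags, "interpolated_at_24")
  # last sample in [22, 24): concentration carried to 24 h as a rectangle
  r <- auc24(pk_profile(c(0, 1, 23), c(0, 10, 4)))
  expect_equal(r$auc24, 5 + (10 + 4) / 2 * 22 + 4 * 1)
  expect_identical(r$flags, "imputed_22_24")
  # nothing at or past 22 h: truncated
  r <- auc24(pk_profile(c(0, 1, 20), c(0, 10, 4)))
  expect_identical(r$flags, "truncated")
  expect_equal(r$auc24, 5 + (10 + 4) / 2 * 19)
  expect_error(auc24(pk_profile(2, 5)), "2 points")
})

test_that("AUC24 agrees with fine-grid integration and is monotone", {
  set.seed(101)
  for (branch in c("inside", "interp", "impute")) {
    for (rep in 1:25) {
      p <- random_profile(branch)
      t <- p$data$actual_time_h; y <- p$data$value
      expected <- switch(branch,
        inside = oracle_auc_linear(t, y, max(t)),
        interp = oracle_auc_linear(t, y, 24),
        impute = oracle_auc_linear(t, y, max(t)) + y[length(y)] * (24 - max(t)))
      expect_equal(auc24(p)$auc24, expected, tolerance = 1e-9)
      # pointwise-larger profile has larger-or-equal AUC
      p2 <- pk_profile(t, y + runif(length(y), 0, 5))
      expect_gte(auc24(p2)$auc24, auc24(p)$auc24)
    }
  }
})

test_that("Cmax/Tmax take the first maximum and flag all-BLQ profiles", {
  r <- cmax_tmax(pk_profile(c(0, 1, 24), c(0, 10, 2)))
  expect_equal(r$cmax, 10)
  expect_equal(r$tmax_h, 1)
  r <- cmax_tmax(pk_profile(c(0, 1, 2, 24), c(0, 10, 10, 2)))
  expect_equal(r$tmax_h, 1)  # tie broken by earliest time
  r <- cmax_tmax(pk_profile(c(0, 1, 2), rep(0.01, 3)))
  expect_true(r$degenerate)
  expect_equal(r$cmax, 0.01)
  expect_equal(r$tmax_h, 0)
  # dense sampling of the closed-form curve recovers the analytic maximizer
  tt <- seq(0, 24, by = 0.01)
  r <- cmax_tmax(pk_profile(tt, conc_curve(tt, 1, 0.1, 100)))
  expect_equal(r$tmax_h, log(10) / 0.9, tolerance = 0.01)
})

test_that("half-life is exact on single exponentials and picks the terminal
           phase of biexponential curves", {
  tt <- c(2, 4, 8, 24)
  hl <- half_life(pk_profile(tt, 100 * exp(-0.1 * tt)))
  expect_equal(hl$half_life_h, log(2) / 0.1, tolerance = 1e-9)
  expect_equal(hl$lambda_z, 0.1, tolerance = 1e-9)
  # exactness holds for any >=3-point terminal manual selection
  hl <- half_life(pk_profile(tt, 100 * exp(-0.1 * tt)), selection = c(4, 8, 24))
  expect_equal(hl$half_life_h, log(2) / 0.1, tolerance = 1e-9)
  # biexponential: fast phase 1/h, terminal 0.05/h; auto selection must fit
  # terminal points only and match the terminal rate within 5%
  tt <- c(0.5, 1, 2, 4, 8, 12, 18, 24)
  y <- 80 * exp(-1 * tt) + 20 * exp(-0.05 * tt)
  hl <- half_life(pk_profile(tt, y))
  expect_equal(hl$lambda_z, 0.05, tolerance = 0.05)
  expect_true(all(hl$points >= 8))
  # terminal phase rising after an early peak: no negative slope, flagged
  hl <- half_life(pk_profile(c(0, 6, 12, 18, 24), c(10, 1, 2, 3, 4)))
  expect_true(is.na(hl$half_life_h))
  expect_identical(hl$flags, "non_negative_slope")
  expect_identical(half_life(pk_profile(c(0, 24), c(2, 1)))$flags,
                   "fewer_than_3_points")
})

test_that("flip-flop kinetics yield the absorption-limited half-life", {
  tt <- c(0.5, 2, 4, 8, 24)
  y <- conc_curve(tt, ka = 0.152, ke = 10, D = 50)
  hl <- half_life(pk_profile(tt, y))
  expect_equal(hl$lambda_z, 0.152, tolerance = 0.01)   # = ka, not ke
  expect_equal(hl$half_life_h, log(2) / 0.152, tolerance = 0.05)
})

test_that("composite profile is the per-nominal-time median and commutes
           with scaling", {
  mk <- function(vals, times = c(0.5, 2, 24)) {
    p <- pk_profile(times, vals)
    p$key <- list(period = "single_rectal", matrix = "rectal_tissue",
                  analyte = "TFV", cell_fraction = "none")
    p
  }
  cp <- composite_profile(list(mk(c(1, 5, 2)), mk(c(2, 6, 3)), mk(c(9, 7, 4))))
  expect_equal(cp$data$value, c(2, 6, 3))
  expect_equal(cp$n_per_time, c(3L, 3L, 3L))
  # identical profiles: composite equals any one of them
  cp1 <- composite_profile(list(mk(c(1, 5, 2)), mk(c(1, 5, 2))))
  expect_equal(cp1$data$value, c(1, 5, 2))
  # sparse design: union of nominal grids even though no subject has all
  pa <- mk(c(4, 8), times = c(0.5, 24)); pb <- mk(c(6, 1), times = c(0.5, 96))
  cpu <- composite_profile(list(pa, pb))
  expect_equal(cpu$data$actual_time_h, c(0.5, 24, 96))
  expect_equal(cpu$n_per_time, c(2L, 1L, 1L))
  # scaling all subjects by c scales composite values and AUC by c
  profs <- list(mk(c(1, 5, 2)), mk(c(2, 6, 3)), mk(c(9, 7, 4)))
  sc <- lapply(profs, function(p) pk_profile(p$data$actual_time_h,
                                             3 * p$data$value, key = p$key))
  expect_equal(composite_profile(sc)$data$value, 3 * cp$data$value)
  expect_equal(auc24(composite_profile(sc))$auc24, 3 * auc24(cp)$auc24)
})

test_that("accumulation ratio uses AUC when possible, else the 0.5 h ratio", {
  tt <- c(0, 0.5, 2, 4, 24)
  single <- pk_profile(tt, conc_curve(tt, 2, 0.1, 10))
  expect_equal(accumulation_ratio(single, single)$ratio, 1.0)
  dbl <- pk_profile(tt, 2 * conc_curve(tt, 2, 0.1, 10))
  r <- accumulation_ratio(dbl, single)
  expect_equal(r$ratio, 2.0)
  expect_identical(r$basis, "auc24_ratio")
  # sparse biopsy profiles (one point at 0.5 h): falls back to C30min ratio
  s1 <- pk_profile(0.5, 10); m1 <- pk_profile(0.5, 35)
  r <- accumulation_ratio(m1, s1)
  expect_identical(r$basis, "c30min_ratio")
  expect_equal(r$ratio, 3.5)
  expect_true(is.na(accumulation_ratio(m1, pk_profile(0.4, 10))$ratio))
})

test_that("7-dose superposition matches the analytic accumulation factor", {
  # long effective half-life (35 h): substantial accumulation expected
  ke <- log(2) / 35
  tt <- seq(0, 24, by = 0.1)
  single <- pk_profile(tt, conc_curve(tt, ka = 5, ke = ke, D = 100))
  multi <- pk_profile(tt, conc_curve_multi(tt, ka = 5, ke = ke, D = 100, n_doses = 7L))
  r <- accumulation_ratio(multi, single)
  # oracle: 7-dose linear accumulation factor on the terminal rate
  factor7 <- (1 - exp(-ke * 24 * 7)) / (1 - exp(-ke * 24))
  expect_identical(r$basis, "auc24_ratio")
  expect_gt(r$ratio, 2)
  expect_equal(r$ratio, factor7, tolerance = 0.05)
})

test_that("CV% summarises inter-subject variability", {
  expect_equal(cv_percent(c(1, 3)), 100 * sqrt(2) / 2)
  expect_equal(cv_percent(c(1, 1, 1)), 0)  # all-BLQ group after imputation
  expect_error(cv_percent(5), "at least 2")
  expect_error(cv_percent(c(-1, 1)), "zero mean")
})
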