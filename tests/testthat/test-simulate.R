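test_that("one-compartment curve honours closed forms and rejects bad input", {
  expect_error(conc_curve(-1, 1, 0.1, 10), "negative")
  expect_error(conc_curve(1, 0.5, 0.5, 10), "ka == ke")
  # limit form continuous at ka -> ke
  expect_equal(conc_curve(3, 0.5, 0.5, 10, allow_equal_rates = TRUE),
               conc_curve(3, 0.5 + 1e-9, 0.5, 10), tolerance = 1e-6)
  # analytic maximizer
  tstar <- conc_curve_tmax(1, 0.1)
  expect_equal(tstar, log(10) / 0.9)
  grid <- seq(0.01, 30, by = 0.01)
  expect_equal(grid[which.max(conc_curve(grid, 1, 0.1, 5))], tstar,
               tolerance = 0.01)
  # superposition reduces to single dose for one dose
  tt <- c(0.5, 2, 24)
  expect_identical(conc_curve_multi(tt, 1, 0.1, 5, n_doses = 1L),
                   conc_curve(tt, 1, 0.1, 5))
})

test_that("design schedule respects arms, groups and monotone times", {
  des <- study_design()
  expect_length(des$subjects, 18L)
  expect_identical(sum(des$arm == "TFV"), 12L)
  expect_true(all(des$group %in% c("A", "B")))
  sched <- mucosalpk:::design_schedule(des)
  # placebo-arm subjects contribute the oral period only
  hec <- sched[sched$arm == "HEC", ]
  expect_identical(unique(hec$period), "single_oral")
  # nominal times strictly increasing within every profile
  key <- paste(sched$subject_id, sched$period, sched$matrix, sched$analyte)
  ok <- vapply(split(sched$nominal_time_h, key),
               function(t) !is.unsorted(t, strictly = TRUE), TRUE)
  expect_true(all(ok))
})

test_that("a noiseless single-subject cohort reproduces the analytic curve", {
  des <- study_design(1L, 1L, jitter_sd_h = c(intensive = 0, day1 = 0, visit = 0))
  kin <- kinetic_params(bsv_cv_D = 0, bsv_cv_ke = 0, noise_sd_log10 = 0)
  i <- kin$period == "single_oral" & kin$matrix == "plasma"
  kin$ka[i] <- 1; kin$ke[i] <- 0.1
  kin$D[i] <- 250 / conc_curve(2, 1, 0.1, 1)  # C(2 h) = 250 ng/mL
  rec <- simulate_cohort(des, kin, seed = 5, matrices = "plasma")
  oral <- rec[rec$period == "single_oral", ]
  expect_equal(oral$value[oral$nominal_time_h == 2], 250, tolerance = 1e-6)
  expect_equal(oral$actual_time_h, oral$nominal_time_h)
  # Tmax recovery closure: observed argmax within one sampling interval of
  # the analytic maximizer
  tstar <- conc_curve_tmax(1, 0.1)
  t_obs <- oral$nominal_time_h[which.max(oral$value)]
  gaps <- diff(sort(unique(oral$nominal_time_h)))
  expect_lt(abs(t_obs - tstar), max(gaps[findInterval(tstar, sort(unique(oral$nominal_time_h)))]))
})

test_that("equal seeds give identical cohorts, different seeds differ", {
  a <- simulate_cohort(seed = 11)
  b <- simulate_cohort(seed = 11)
  c <- simulate_cohort(seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$actual_time_h, c$actual_time_h))
})

test_that("cohort obeys censoring and design-fidelity invariants", {
  rec <- simulate_cohort(seed = 3)
  std <- standardize_records(rec)
  specs <- matrix_specs()
  m <- match(paste(std$matrix, std$analyte),
             paste(specs$matrix, specs$analyte))
  quantified <- std$blq == 0L
  expect_true(all(std$value[quantified] >= specs$lloq[m][quantified]))
  expect_true(all(is.na(std$value[!quantified])))
  # counts per matrix x period match the schedule exactly (MMC triplicated
  # into total / CD4pos / CD4neg fractions)
  sched <- mucosalpk:::design_schedule(study_design())
  want <- table(sched$matrix, sched$period)
  want["rectal_mmc", ] <- 3L * want["rectal_mmc", ]
  got <- table(rec$matrix, rec$period)
  expect_equal(unclass(got)[rownames(want), colnames(want)], unclass(want),
               ignore_attr = TRUE)
})

test_that("rectal-period plasma is generated in the flip-flop regime", {
  des <- study_design(2L, 2L, jitter_sd_h = c(intensive = 0, day1 = 0, visit = 0))
  kin <- kinetic_params(bsv_cv_D = 0, bsv_cv_ke = 0, noise_sd_log10 = 0)
  i <- kin$period == "single_rectal" & kin$matrix == "plasma"
  kin$ka[i] <- 0.15; kin$ke[i] <- 1.0
  rec <- simulate_cohort(des, kin, seed = 9, matrices = "plasma")
  sr <- rec[rec$period == "single_rectal" & rec$subject_id == "S01", ]
  tail_t <- sr$nominal_time_h[sr$nominal_time_h >= 4]
  # oracle: log-linear fit to the analytic curve tail
  slope_oracle <- oracle_loglin_slope(tail_t, conc_curve(tail_t, 0.15, 1.0,
                                                         kin$D[i][1]))
  slope_gen <- oracle_loglin_slope(tail_t,
                                   sr$value[sr$nominal_time_h %in% tail_t])
  expect_equal(slope_gen, slope_oracle, tolerance = 1e-8)
  expect_equal(-slope_gen, 0.15, tolerance = 0.02)
  expect_gt(abs(-slope_gen - 1.0), 0.8)  # nowhere near the elimination rate
})

test_that("regression-data generator matches its moments and null cases", {
  m0 <- cross_matrix_model(1, 2)
  d0 <- simulate_regression_data(m0, 20, c(0, 1), seed = 1)
  expect_equal(d0$dv, 1 + 2 * d0$iv)  # noiseless exact line
  expect_error(simulate_regression_data(m0, 5, c(0, 1)), ">= 10")
  expect_error(simulate_regression_data(m0, 20, c(1, 1)), "interval")

  # generating model of the tissue TFVdp-on-TFV relationship: OLS slope on
  # simulated data within 3 standard errors of the generating slope
  m4 <- cross_matrix_model(2.37, 0.366, noise_sd_log10 = 0.37)
  d4 <- simulate_regression_data(m4, 300, c(-1, 1), seed = 2)
  X <- cbind(1, d4$iv)
  bhat <- oracle_ols(X, d4$dv)
  resid <- d4$dv - X %*% bhat
  se <- sqrt(sum(resid^2) / (nrow(X) - 2) * solve(crossprod(X))[2, 2])
  expect_lt(abs(bhat[2] - 0.366), 3 * se)

  # contamination inflates residual spread beyond the core sd
  mc <- cross_matrix_model(0, 1, noise_sd_log10 = 0.2,
                           contamination_fraction = 0.2,
                           contamination_scale = 10)
  dc <- simulate_regression_data(mc, 500, c(0, 1), seed = 3)
  expect_gt(sd(dc$dv - dc$iv), 0.2)
})
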