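test_that("trapezoid_to_24 matches hand arithmetic with the zero anchor", {
  expect_equal(
    trapezoid_to_24(data.frame(time_h = c(4, 24), rate_gy_per_h = c(0.9, 0.6))),
    16.8)
  expect_equal(
    trapezoid_to_24(data.frame(time_h = 24, rate_gy_per_h = 1.0)), 12.0)
  expect_equal(
    trapezoid_to_24(data.frame(time_h = c(4, 24), rate_gy_per_h = c(0, 0))), 0)
  # samples beyond 24 h are ignored
  expect_equal(
    trapezoid_to_24(data.frame(time_h = c(4, 24, 48), rate_gy_per_h = c(0.9, 0.6, 0.3))),
    16.8)
  expect_error(
    trapezoid_to_24(data.frame(time_h = 48, rate_gy_per_h = 1)),
    "no early-phase data")
})

test_that("trapezoid converges to the analytic integral on a dense grid", {
  # pure decaying exponential; a measured t = 0 sample replaces the zero anchor
  lambda <- log(2) / 30
  tt <- seq(0, 24, length.out = 64)
  s <- data.frame(time_h = tt, rate_gy_per_h = exp(-lambda * tt))
  analytic <- (1 - exp(-lambda * 24)) / lambda
  expect_equal(trapezoid_to_24(s) / analytic, 1, tolerance = 1e-3)
})

test_that("tail_integral is the analytic mono-exponential tail", {
  expect_equal(tail_integral(1, log(2)), 1)
  expect_equal(tail_integral(0.6, 34.657), 30.0, tolerance = 1e-4)
  expect_equal(tail_integral(0, 77), 0)
  expect_error(tail_integral(1, 0), "non-positive")
  # monotone in both arguments
  expect_gt(tail_integral(1.1, 30), tail_integral(1.0, 30))
  expect_gt(tail_integral(1.0, 31), tail_integral(1.0, 30))
})

test_that("absorbed_dose combines trapezoid and tail, anchored at the 24 h scan", {
  teff <- 34.657
  r24 <- 0.6
  t <- c(4, 24, 48, 72)
  r <- c(0.9, r24, r24 * 2^(-24 / teff), r24 * 2^(-48 / teff))
  s <- dose_rate_series("X", 1, "tumour", t, r)
  fit <- fit_monoexponential(s)
  res <- absorbed_dose(s, fit, aa_gbq = 2)
  expect_equal(res$trapezoid_gy, 16.8)
  expect_equal(res$tail_gy, 30.0, tolerance = 1e-3)
  expect_equal(res$ad_gy, res$trapezoid_gy + res$tail_gy) # exact identity
  expect_equal(res$rate_24_gy_per_h, r24) # measured sample, not the fit
  expect_equal(res$ad_per_aa_gy_per_gbq, res$ad_gy / 2)
})

test_that("absorbed_dose falls back to the fitted 24 h rate when unmeasured", {
  teff <- 40
  s <- biexp_series(amplitude = 1, teff = teff, times = c(4, 30, 48, 72))
  fit <- fit_monoexponential(s, window_start_h = 30)
  res <- absorbed_dose(s, fit)
  expect_equal(res$rate_24_gy_per_h, predict_rate(fit, 24), tolerance = 1e-12)
  expect_equal(res$ad_gy, res$trapezoid_gy + res$tail_gy)
})

test_that("hybrid estimate is within 10% of the analytic truth (noiseless)", {
  for (teff in c(30, 50, 90)) {
    s <- biexp_series(amplitude = 1, teff = teff, uptake_halftime = 2)
    truth <- true_absorbed_dose(1, teff, 2)
    est <- absorbed_dose(s, fit_monoexponential(s))$ad_gy
    expect_equal(est / truth, 1, tolerance = 0.1)
  }
})

test_that("absorbed dose is linear in the rate scale", {
  s <- biexp_series(amplitude = 1, teff = 45)
  base <- absorbed_dose(s, fit_monoexponential(s))
  for (c_scale in c(0.2, 7)) {
    s2 <- dose_rate_series("T1", 1, "tumour", s$samples$time_h,
                           c_scale * s$samples$rate_gy_per_h)
    res <- absorbed_dose(s2, fit_monoexponential(s2))
    expect_equal(res$ad_gy, c_scale * base$ad_gy, tolerance = 1e-9)
    expect_equal(res$t_eff_h, base$t_eff_h, tolerance = 1e-9)
  }
})

test_that("dose_per_activity reproduces the cohort's printed Gy/GBq", {
  expect_equal(dose_per_activity(21.3, 2.86), 7.448, tolerance = 1e-3)
  expect_equal(dose_per_activity(8.12, 1.54), 5.273, tolerance = 1e-3)
  expect_equal(dose_per_activity(0, 3), 0)
  expect_error(dose_per_activity(5, 0), "> 0")
})

test_that("kidney_aggregate averages all fields and checks structures", {
  sL <- biexp_series(amplitude = 0.02, teff = 80, structure = "kidney_left")
  sR <- biexp_series(amplitude = 0.03, teff = 100, structure = "kidney_right")
  L <- absorbed_dose(sL, fit_monoexponential(sL))
  R <- absorbed_dose(sR, fit_monoexponential(sR))
  agg <- kidney_aggregate(L, R)
  expect_equal(agg$ad_gy, (L$ad_gy + R$ad_gy) / 2)
  expect_equal(agg$t_eff_h, (L$t_eff_h + R$t_eff_h) / 2)
  expect_identical(agg$structure, "kidney")
  # idempotent on identical inputs
  same <- kidney_aggregate(L, absorbed_dose(sL, fit_monoexponential(sL)))
  expect_equal(same$ad_gy, L$ad_gy)
  tum <- absorbed_dose(biexp_series(), fit_monoexponential(biexp_series()))
  expect_error(kidney_aggregate(L, tum), "kidney_left/kidney_right")
})

test_that("analyze_series aggregates kidneys and joins administered activity", {
  series <- list(
    biexp_series(amplitude = 1, teff = 40, pid = "A", structure = "tumour"),
    biexp_series(amplitude = 0.02, teff = 80, pid = "A", structure = "kidney_left"),
    biexp_series(amplitude = 0.03, teff = 100, pid = "A", structure = "kidney_right"))
  aa <- data.frame(patient_id = "A", cycle = 1, aa_gbq = 2.5)
  est <- analyze_series(series, aa_table = aa)
  expect_setequal(est$structure, c("tumour", "kidney"))
  kid <- est[est$structure == "kidney", ]
  left <- absorbed_dose(series[[2]], fit_monoexponential(series[[2]]))
  right <- absorbed_dose(series[[3]], fit_monoexponential(series[[3]]))
  expect_equal(kid$ad_gy, (left$ad_gy + right$ad_gy) / 2, tolerance = 1e-12)
  expect_equal(est$ad_per_aa_gy_per_gbq, est$ad_gy / 2.5, tolerance = 1e-12)
})
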