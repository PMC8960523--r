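test_that("simulation_config validates its stated world", {
  expect_error(simulation_config(), "seed")
  cfg <- simulation_config(seed = 1)
  expect_equal(cfg$aa_mbq_per_kg, c(75, 100))
  expect_equal(cfg$noise_cv, 0.10)
  expect_equal(cfg$sample_times_h, c(4, 24, 48, 72))
  expect_equal(cfg$decline_factor, 0.7)
  expect_error(simulation_config(seed = 1, decline_factor = 0), "decline")
  expect_error(simulation_config(seed = 1, tumour_teff_range_h = c(1, 3)))
})

test_that("true_absorbed_dose is the closed-form biexponential integral", {
  expect_equal(true_absorbed_dose(1, 48, 2), 46 / log(2), tolerance = 1e-12)
  expect_equal(true_absorbed_dose(2, 48, 2), 2 * true_absorbed_dose(1, 48, 2))
  # fast-uptake limit approaches the pure mono-exponential integral A/lambda
  expect_equal(true_absorbed_dose(1, 48, 1e-9), 48 / log(2), tolerance = 1e-6)
  expect_error(true_absorbed_dose(1, 2, 2), "slower than uptake")
})

test_that("generation is deterministic given the seed and stable under cohort growth", {
  cfg <- simulation_config(n_patients = 3, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_equal(a$truth, b$truth, tolerance = 0)
  expect_equal(cohort_table(a$courses), cohort_table(b$courses), tolerance = 0)
  expect_equal(cyclodose:::series_table(a$series),
               cyclodose:::series_table(b$series), tolerance = 0)
  # per-patient substreams: patient 2 is identical in a larger cohort
  big <- generate_cohort(simulation_config(n_patients = 5, seed = 99))
  expect_equal(big$truth[big$truth$patient_id == "S02", ],
               a$truth[a$truth$patient_id == "S02", ], tolerance = 0)
})

test_that("generator honours the weight-based activity schedule", {
  sim <- generate_cohort(simulation_config(n_patients = 4, seed = 5))
  tab <- cohort_table(sim$courses)
  expect_equal(1000 * tab$aa_gbq[tab$cycle == 1] / tab$weight_kg[tab$cycle == 1],
               rep(75, 4), tolerance = 1e-9)
  expect_equal(1000 * tab$aa_gbq[tab$cycle == 3] / tab$weight_kg[tab$cycle == 3],
               rep(100, 4), tolerance = 1e-9)
})

test_that("noise-free null case yields constant dose-per-activity and unit ratios", {
  sim <- generate_cohort(simulation_config(n_patients = 3, decline_factor = 1,
                                           noise_cv = 0, seed = 21))
  st <- schema_table(sim$courses)
  expect_true(all(abs(st$ratio_median - 1) < 1e-9))
  # declining case at the truth level: cycle-4 ratio is decline^3 exactly
  sim7 <- generate_cohort(simulation_config(n_patients = 3, decline_factor = 0.7,
                                            noise_cv = 0, seed = 21))
  r4 <- schema_ratios(sim7$courses, "tumour", 4)
  expect_equal(r4$ratio, rep(0.7^3, 3), tolerance = 1e-9)
  # kidney kinetics are stable regardless of the tumour decline
  rk <- schema_ratios(sim7$courses, "kidney", 4)
  expect_equal(rk$ratio, rep(1, 3), tolerance = 1e-9)
})

test_that("generated series follow the biexponential shape with mean-1 noise", {
  sim <- generate_cohort(simulation_config(n_patients = 1, noise_cv = 0, seed = 3))
  tr <- sim$truth[sim$truth$structure == "tumour" & sim$truth$cycle == 1, ]
  s <- Filter(function(x) x$structure == "tumour" && x$cycle == 1, sim$series)[[1]]
  lambda <- log(2) / tr$clearance_teff_h
  mu <- log(2) / tr$uptake_halftime_h
  expect_equal(s$samples$rate_gy_per_h,
               tr$amplitude_gy_per_h * (exp(-lambda * s$samples$time_h) -
                                          exp(-mu * s$samples$time_h)),
               tolerance = 1e-12)
  # analytic dose equals the closed form from the truth parameters
  expect_equal(tr$true_ad_gy,
               true_absorbed_dose(tr$amplitude_gy_per_h, tr$clearance_teff_h,
                                  tr$uptake_halftime_h),
               tolerance = 1e-12)
})

test_that("pipeline recovery at 10% noise: small bias, calibrated spread", {
  # 240 structure-level replicates (5 cohorts x 6 patients x 4 cycles x
  # {tumour, kidney}); thresholds frozen from the package calibration run
  rel_teff <- c()
  rel_ad <- c()
  for (s in 1:5) {
    sim <- generate_cohort(simulation_config(n_patients = 6, seed = 1000 + s))
    aa <- unique(sim$truth[, c("patient_id", "cycle", "aa_gbq")])
    est <- suppressWarnings(
      analyze_series(sim$series, aa_table = aa, on_error = "omit"))
    truth_key <- split(sim$truth,
                       interaction(sim$truth$patient_id, sim$truth$cycle))
    trk <- do.call(rbind, lapply(truth_key, function(g) {
      kid <- g$structure != "tumour"
      data.frame(patient_id = g$patient_id[1], cycle = g$cycle[1],
                 tumour_ad = g$true_ad_gy[!kid],
                 tumour_teff = g$clearance_teff_h[!kid],
                 kidney_ad = mean(g$true_ad_gy[kid]),
                 kidney_teff = mean(g$clearance_teff_h[kid]))
    }))
    for (st in c("tumour", "kidney")) {
      m <- merge(est[est$structure == st, ], trk, by = c("patient_id", "cycle"))
      rel_teff <- c(rel_teff, m$teff_h / m[[paste0(st, "_teff")]] - 1)
      rel_ad <- c(rel_ad, m$ad_gy / m[[paste0(st, "_ad")]] - 1)
    }
  }
  expect_gte(length(rel_teff), 200)
  # bias: the median estimate tracks the truth
  expect_lt(abs(median(rel_teff)), 0.07)
  expect_lt(abs(median(rel_ad)), 0.12)
  # spread: frozen regression thresholds from the calibration run
  expect_lt(median(abs(rel_teff)), 0.20)
  expect_lt(median(abs(rel_ad)), 0.12)
})

test_that("end-to-end null and effect recovery of the schema ratio", {
  null_meds <- vapply(1:50, function(s) {
    sim <- generate_cohort(simulation_config(n_patients = 6, decline_factor = 1,
                                             seed = 2000 + s))
    est <- suppressWarnings(estimate_courses(sim))
    median(schema_ratios(est, "tumour", 4)$ratio, na.rm = TRUE)
  }, 0)
  expect_lt(abs(median(null_meds) - 1), 0.05)

  eff_meds <- vapply(1:50, function(s) {
    sim <- generate_cohort(simulation_config(n_patients = 6, decline_factor = 0.7,
                                             seed = 3000 + s))
    est <- suppressWarnings(estimate_courses(sim))
    median(schema_ratios(est, "tumour", 4)$ratio, na.rm = TRUE)
  }, 0)
  expect_lt(abs(median(eff_meds) - 0.343), 0.08)
})
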