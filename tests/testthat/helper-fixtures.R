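# Shared fixtures built in code.

# Minimal two-cycle course for constructor/validator tests.
toy_course <- function(aa = c(2.0, 2.5), tumour_ad = c(15, 12),
                       kidney_ad = c(1.5, 1.4)) {
  patient_course("T1", "F", 120, data.frame(
    cycle = seq_along(aa), aa_gbq = aa, weight_kg = rep(30, length(aa)),
    tumour_ad_gy = tumour_ad, kidney_ad_gy = kidney_ad,
    tumour_teff_h = rep(45, length(aa)), kidney_teff_h = rep(90, length(aa))
  ))
}

# Noiseless uptake-clearance series sampled on the nominal schedule.
biexp_series <- function(amplitude = 1, teff = 50, uptake_halftime = 2,
                         times = c(4, 24, 48, 72), pid = "T1", cycle = 1,
                         structure = "tumour") {
  lambda <- log(2) / teff
  mu <- log(2) / uptake_halftime
  dose_rate_series(pid, cycle, structure, times,
                   amplitude * (exp(-lambda * times) - exp(-mu * times)))
}

# Per Table 1, the printed MBq/kg column (used to cross-check aa/weight).
printed_aa_per_weight <- data.frame(
  patient_id = rep(c("P1", "P2", "P3", "P4", "P5", "P6"), each = 4),
  cycle = rep(1:4, 6),
  mbq_per_kg = c(76.9, 85.7, 109.3, 96.6, 76.3, 95.6, 109, 113,
                 71.9, 82.6, 80.2, 79.3, 77.2, 101, 95.2, 94.2,
                 77.5, 106, 97.1, 110, 88.4, 104, 86.2, 102)
)

# Printed cumulative tumour/kidney absorbed dose columns of the reference
# table (P2 cycle 4 uses the reading consistent with the per-cycle sums).
printed_cumulative <- list(
  tumour = list(P1 = c(21.3, 32.7, 65.6, 72.2), P2 = c(13.5, 24.9, 42.6, 43.3),
                P3 = c(8.12, 17.79, 20.52, 30.92), P4 = c(17.7, 42.6, 50.1, 70.2),
                P5 = c(11.8, 23.1, 27.25, 29.17), P6 = c(26.4, 55.2, 70.4, 71.4)),
  kidney = list(P1 = c(2.6, 5.78, 7.25, 11.27), P2 = c(1, 2.03, 3.69, 5.50),
                P3 = c(1.28, 2.47, 3.75, 5.73), P4 = c(1.53, 3.12, 5.99, 8.81),
                P5 = c(0.66, 1.32, 3.09, 4.88), P6 = c(2.32, 5.52, 8.55, 11.58))
)
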