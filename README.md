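# cyclodose

Per-cycle internal dosimetry for multi-cycle radionuclide therapy
([177Lu]Lu-DOTATATE peptide receptor radionuclide therapy and similar
regimens).

Clinical treatment planning commonly assumes *stable biokinetics*: the
absorbed dose per unit administered activity (Gy/GBq) measured after cycle 1
is assumed to hold for all later cycles, so the expected dose of cycle
*c* is

    AD_E(c) = (AD/AA)_delivered(cycle 1) x AA(c)

cyclodose provides the full analysis chain needed to test that assumption on
serial SPECT-derived dose-rate data:

* **Kinetics** — mono-exponential clearance fit (log-linear OLS on the
  ≥ 24 h samples) giving the effective half-life `T_eff = ln 2 / lambda`.
* **Integration** — hybrid absorbed dose: trapezoidal integration of the
  measured dose-rate curve to 24 h (zero anchor at injection) plus the
  analytic tail `D_tail = D'(24h) x T_eff / ln 2`; kidneys reported as the
  left/right mean.
* **Cycle analysis** — inter-cycle relative differences
  `100 x (V_c - V_1)/V_1`, cumulative doses, per-cycle contribution
  fractions, cohort median/range summaries.
* **Schema simulation** — expected vs delivered dose and their ratio per
  cycle (the fixed-schema stress test).
* **Statistics** — Wilcoxon–Mann–Whitney (continuity-corrected normal
  default, exact enumeration oracle) and Spearman correlation with
  t-approximation p-values, implemented to match how such cohorts are
  analysed in practice.
* **Synthetic cohorts** — a seeded generator with biexponential
  uptake–clearance kinetics and closed-form true doses, for end-to-end
  validation with known ground truth.
* **Reference cohort** — `ludo_fixture()`: six pediatric neuroblastoma
  patients, four cycles each, from the LuDO trial (ISRCTN98918118), at
  published precision.

## Worked example

```r
library(cyclodose)
cohort <- ludo_fixture()

# Per-cycle tumour absorbed dose: the median falls from 15.6 Gy to 4.3 Gy
sapply(1:4, function(cc) cohort_summary(cohort, "ad_gy", "tumour", cc)$median)
#> [1] 15.60 11.40 11.35  4.26

# Fixed-schema ratios: the schema increasingly over-predicts the tumour dose
st <- schema_table(cohort)
subset(st, structure == "tumour", select = c(cycle, ratio_median, p_value))
#>   cycle ratio_median    p_value
#> 1     1    1.0000000         NA
#> 2     2    0.7615859 0.29710698
#> 3     3    0.3899197 0.12820528
#> 4     4    0.1570207 0.01306523

# ... while kidney doses stay close to prediction (ratio ~ 1)
subset(st, structure == "kidney", select = c(cycle, ratio_median))
#>   cycle ratio_median
#> 5     1    1.0000000
#> 6     2    0.7396322
#> 7     3    1.0065859
#> 8     4    1.0742324
```

By cycle 4 the tumour receives a median 16% of the dose the cycle-1
biokinetics predicted (Mann–Whitney U = 2, p = 0.013), while the kidney
ratio stays near 1 — the dose-limiting organ is predictable, the tumour is
not.

A synthetic end-to-end check with known truth:

```r
sim <- generate_cohort(simulation_config(n_patients = 6, seed = 1))
est <- estimate_courses(sim)              # fit + integrate the noisy series
median(schema_ratios(est, "tumour", 4)$ratio, na.rm = TRUE)
#> [1] 0.3503079                           # truth: 0.7^3 = 0.343
```

## Command line

```sh
Rscript exec/cyclodose report   --input fixture --out out/
Rscript exec/cyclodose simulate --seed 7 --n-patients 6 --out sim/
```

Subcommands: `analyze` (per-cycle summary tables), `schema` (expected vs
delivered table with p-values), `report` (both plus contribution table),
`simulate` (synthetic cohort + series + truth CSVs). Report CSVs are
rounded to 3 significant figures, with full-precision `*_full.csv` twins.

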