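# csiaray

Compound-specific isotope analysis (CSIA) of microbial hydrocarbon
biodegradation, built for the situation where the isotopic signature of the
*residual* compound is the only direct chemical evidence that degradation is
happening — anoxic aquifers, microcosm enrichments, monitored natural
attenuation of BTEX. The package is aimed at biogeochemists and
bioremediation practitioners who have reduced concentration + δ¹³C/δ²H time
series in hand and need the full inference chain behind them.

## What it computes

Closed-system isotope fractionation follows the Rayleigh distillation law.
With f = C_t/C₀ the fraction of compound remaining and
R_t/R₀ = (δ_t + 1000)/(δ₀ + 1000),

    ln(R_t/R₀) = (ε / 1000) · ln f

and the bulk enrichment factor ε (‰, negative for a normal kinetic isotope
effect) is estimated by OLS with a t-based 95% CI (`fit_rayleigh()`). From
there:

* **AKIE** — apparent kinetic isotope effect with position-specific
  correction, AKIE = 1/(1 + z·ε_rp/1000), z = 6 for fully symmetric
  benzene (`epsilon_reactive_position()`, `akie()`);
* **Λ (lambda)** — the dual-isotope slope of Δδ²H on Δδ¹³C
  (`fit_lambda()`), plus the ε_H/ε_C ratio definition, both labeled;
* **redox classification** — Λ ∈ [22, 28] → low redox potential
  (sulfate-reducing / methanogenic / fermenting), Λ ∈ [12, 16] →
  nitrate-reducing, otherwise unclassified (`classify_redox()`), backed by
  a packaged 15-entry literature compilation of benzene (ε_C, ε_H) pairs
  (`load_reference_db()`, `nearest_reference()`, `akie_biplot_points()`);
* **microcosm kinetics** — control- and internal-standard-normalized
  residual curves, lag and halt detection, doubling times
  (`residual_percentage()`, `detect_lag()`, `detect_halt()`,
  `doubling_time()`);
* **a forward simulator** of BTEX microcosms (`simulate_microcosm()`,
  `btex_scenario()`, `simulate_rayleigh_series()`) producing
  concentration and isotope trajectories with the exact Rayleigh law,
  first-order kinetics after configurable lags, non-fractionating septa
  loss, inhibition events, and Gaussian instrument noise under a single
  seed.

`run_full_analysis()` chains all stages into a versioned report;
`inst/cli/csia.R` exposes `fit`, `simulate`, `classify`, `kinetics`, and
`report` subcommands for shell use.

## Worked example

Simulate the benzene-only isotope-fractionation flask of the canonical
sulfate-reducing scenario (12 ppm benzene, ε_C = −2.4‰, ε_H = −57‰,
instrument noise 0.3‰/2.5‰) and run the pipeline:

```r
library(csiaray)
sim <- simulate_microcosm(btex_scenario(benzene_only = TRUE))
rep <- run_full_analysis(sim$live, sim$control, use_internal_std = TRUE)
print(rep)
#> <analysis_report> schema 1.0, csiaray 0.1.0
#>   epsilon_C: -2.55 +/- 0.22 permil (R2 = 0.987, n = 11)
#>   epsilon_H: -54.7 +/- 3.5 permil (R2 = 0.993, n = 11)
#>   AKIE_C:    1.0155
#>   AKIE_H:    1.4888
#>   lambda:    21.651 +/- 2.403 (regression; epsilon ratio 21.451)
#>   redox:     unclassified
#>   <kinetics_summary> benzene: lag = 35 d, removal = 83.6%
#>   <kinetics_summary> o-xylene: lag = none d, removal = 0.0%
```

Reading this: the fitted enrichment factors bracket the generating values
(−2.4‰ and −57‰) within their CIs; the carbon AKIE of 1.0155 sits in the
anaerobic-benzene cluster of the reference compilation; and this *single*
flask's Λ of 21.7 ± 2.4 falls just below the low-redox interval [22, 28] —
an honest illustration that one noisy flask cannot always be classified.
The estimator itself is well centered, which shows as soon as replicate
flasks are averaged:

```r
lam <- mean(vapply(1:50, function(i) fit_lambda(simulate_rayleigh_series(
  exp(seq(0, log(0.19), length.out = 10)), seed = i))$lambda_slope, numeric(1)))
classify_redox(lam)
#> <redox_classification> lambda = 23.3 -> low_redox
#>   lambda in [22, 28]: low redox potential (fermenting / methanogenic / sulfate-reducing)
```

From the shell:

```sh
Rscript inst/cli/csia.R simulate --seed 9 --out scratch/demo --benzene-only
Rscript inst/cli/csia.R report --input scratch/demo_live.tsv \
  --control scratch/demo_control.tsv --internal-std --out scratch/report.json
Rscript inst/cli/csia.R classify --lambda 23.8
```

## Input format

Delimited UTF-8 tables (TSV or CSV, `#` comments) with header
`time_days, compound, conc, conc_control, conc_internal_std,
delta13C_permil, delta2H_permil`; optional cells may be empty. See
`read_isotope_series()` / `write_isotope_series()`.
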