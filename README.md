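# sbrtpkpd

Pharmacokinetic–pharmacodynamic (PKPD) modelling of lung tumour response
to stereotactic body radiotherapy (SBRT).

## What problem this solves

SBRT for early-stage or oligometastatic non-small-cell lung cancer leaves
the clinician with exactly two numbers per lesion: the gross tumour volume
(GTV) on the planning CT and the GTV on a follow-up CT a few months after
treatment. `sbrtpkpd` turns those two measurements, plus the fractionation
calendar, into a calibrated dynamical model of the lesion — useful to
pharmacometricians and radiation-oncology researchers who want to compare
fractionation regimens, quantify patient-to-patient variability in
treatment response, and propagate baseline-volume uncertainty through the
predicted outcome.

The model couples proliferating tumour volume $x_1$ and necrotic volume
$x_2$ to a radiotherapy exposure compartment driven by the dose schedule
$u_r(t)$ (one rectangular pulse per fraction):

$$
\dot x_1 = (a-n)x_1 - E\,x_1,\qquad
\dot x_2 = n x_1 + E x_1 - \lambda_w x_2,\qquad
\dot x_5 = -c_r x_5 + u_r(t),\qquad
\dot x_{e5} = E_{tr} x_5
$$

The kill rate $E$ is a Hill response to an interaction index combining
normalised tumour burden and normalised cumulative exposure,

$$
I = U_{nt} + U_{nr} + \sigma U_{nr}U_{nt},\qquad
E \propto \frac{I^{\gamma}}{1+I^{\gamma}},
$$

and the single per-lesion parameter $\gamma$ (the patient-response
exponent) is fitted so the simulated volume at follow-up matches the
measured one. A 19-patient, 23-lesion reference cohort is bundled as a
plain CSV; a synthetic-cohort generator with the same statistical
structure makes the whole pipeline testable without external data. See
`vignettes/sbrt-pkpd-model.Rmd` for the full model account and design
rationale.

## Worked example

```r
library(sbrtpkpd)
library(dplyr)

cohort <- load_cohort("bundled")

# Mean efficacy (percent GTV reduction) per fractionation regimen
regimen_efficacy(cohort)
#> # A tibble: 4 × 5
#>   regimen total_dose_gy n_fractions n_lesions mean_efficacy_pct
#>   <chr>           <dbl>       <int>     <int>             <dbl>
#> 1 34 Gy/1            34           1         2             66.7
#> 2 48 Gy/4            48           4         9             68.8
#> 3 54 Gy/3            54           3         9             67.3
#> 4 60 Gy/8            60           8         1             -4.76
```

Three regimens achieved a mean volume reduction near 67–69%; the single
centrally-located lesion treated with 60 Gy in 8 fractions progressed
slightly (−4.76%). Calibrating one lesion (patient 008: 18 cm³ before,
1.5 cm³ after 48 Gy in 4 fractions):

```r
rec <- filter(cohort, patient_id == "008")
calibrate_lesion(rec) |> select(patient_id, gamma_hat, v_sim_final, bound_hit)
#> # A tibble: 1 × 4
#>   patient_id gamma_hat v_sim_final bound_hit
#>   <chr>          <dbl>       <dbl> <chr>
#> 1 008           0.0489        1.50 none
```

The fitted exponent 0.049 reproduces the measured 1.5 cm³ follow-up
volume. Calibrating the whole cohort and summarising:

```r
cal <- calibrate_cohort(cohort)   # ~15 s
glance(cal)                       # slope ≈ 1, r > 0.999, rmse < 0.001 cm³
autoplot(cal)                     # measured vs simulated scatter
sensitivity_analysis(cohort, cal) # 5/10/20 % baseline perturbations
```

`run_calibrate()`, `run_simulate()`, `run_report()` and `run_synth()`
write the same results as CSV/JSON artifacts; `exec/sbrt-pkpd` exposes
them as a command line
(`sbrt-pkpd calibrate|simulate|report|sensitivity|synth`).

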