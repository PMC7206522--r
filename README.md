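# idiovar

Idiographic (N-of-1) time-series analysis of daily sleep diaries and
depression self-ratings. For each patient — not for a pooled cohort —
the package asks: do changes in sleep precede changes in depression
core symptoms, or the reverse, and is more sleep followed by more or
less depression?

It is aimed at researchers analyzing ecological momentary assessment /
daily-diary studies in affective disorders, and ships everything needed
to run and validate the pipeline without access to clinical data: a
synthetic-cohort generator with known ground truth stands in for raw
diaries.

## The model

Per day *t*, three variables are derived from the raw logs: time in bed
(TIB, minutes, from the go-to-bed/get-up clock times), total sleep time
(TST, minutes, self-reported) and the depression core-symptom score
(mean of two 0–10 items). The night reported on the morning of day *t*
is indexed with that evening's rating, so lag 1 is "yesterday predicts
today". For each patient, a bivariate VAR(p) is fitted twice (model 1:
TST and depression; model 2: TIB and depression):

```
y1[t] = a1 + sum_{i=1..p} b_i * y1[t-i] + sum_{i=1..p} c_i * y2[t-i] + e1[t]
y2[t] = a2 + sum_{i=1..p} d_i * y2[t-i] + sum_{i=1..p} f_i * y1[t-i] + e2[t]
```

after Kalman-smoothing imputation of missing days (univariate ARIMA
state space, so no cross-correlation is manufactured) and
ADF/KPSS-guided differencing to stationarity. The lag order p (max 7
days) is chosen by AIC. Granger causality is tested in both directions
with the small-sample F test; dynamics of significant associations are
quantified by orthogonalized impulse responses to a 1-SD shock over a
10-day horizon (with residual-bootstrap 95% bands), their cumulative
sums, and the forecast-error variance decomposition. A cohort layer
applies the inclusion filter (>= 130 days, <= 30% missing), classifies
associations by direction and sign, and aggregates the per-patient
tables.

## Worked example

```r
library(idiovar)

truth <- synthetic_truth(
  patient_id = "demo", n_days = 170, seed = 42,
  coef_matrices = list(matrix(c(0.35, 0, 0.006, 0.4), 2, 2, byrow = TRUE)),
  intercepts = c(312, 0.6), missing_prob = 0.1)
logs   <- generate_patient(truth)   # raw morning/evening diary rows
series <- align_series(logs)        # daily TIB / TST / depression series
inclusion_filter(series)
#> INCLUDE (170 days; tib_min 8.8%, tst_min 8.8%, dep_score 11.8%)

pat <- analyze_patient(series, model = "tib")
pat
#> Patient demo, model TIB: VAR(6)
#> Granger causality tib -> dep: F(6, 151) = 2.836, p = 0.0121 [significant at 0.05, positive association]
#> Granger causality dep -> tib: F(6, 151) = 1.384, p = 0.2247 [not significant]
```

The ground truth couples sleep to next-day depression (about 0.3 SD per
SD); the pipeline recovers exactly that: the sleep-to-depression
direction is significant with a positive sign — longer time in bed is
followed by more depression — and the reverse direction is not. The
impulse response shows where the effect lives in time:

```r
irf(pat$fit, impulse = "tib", response = "dep", boot = TRUE, runs = 500, seed = 1)
#> Orthogonalized IRF: shock of 1 SD (48.29, series scale) in tib -> response of dep
#>  horizon response cumulative  lower  upper
#>        0    0.025      0.025 -0.094  0.161
#>        1    0.229      0.255  0.074  0.381
#>        2    0.225      0.480  0.065  0.371
#>        3    0.042      0.522 -0.099  0.185
#>  ...
```

A 1-SD (48 min) increase in time in bed is followed by a significant
rise of the depression score of about 0.23 scale units on each of the
next two days (band excluding 0), after which the effect fades — and
`fevd(pat$fit)` reports how much of the depression score's forecast
error that sleep shock explains. `generate_cohort()` +
`analyze_cohort()` run the same machinery over a whole simulated cohort
and tabulate associations by model, direction and sign.

Published per-patient summary tables from the motivating feasibility
study (22 outpatients with recurrent major depressive disorder, 143–205
diary days each) ship in `inst/extdata/` via `study_demographics()`,
`study_cumulative_irf()` and `study_fevd_shares()`, so the cohort
aggregation conventions can be exercised against printed values.

See `vignettes/sleep-depression-var.Rmd` for the methods account.

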