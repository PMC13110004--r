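# mrdsim

Joint simulation of longitudinal minimal-residual-disease (MRD)
trajectories and survival outcomes.

MRD assays (flow cytometry, NGS clonality, circulating tumor DNA) measure
the residual tumor burden left after treatment; longitudinal MRD series
increasingly drive trial design and surrogate-endpoint arguments. Methods
for analyzing such data — joint longitudinal–survival models, landmarking,
MRD-negativity thresholds, power calculations — need benchmark datasets
where the truth is known. mrdsim generates them.

## The model

Each subject's true MRD level follows a three-phase piecewise trajectory

```
mu_i(t) = beta0_i * exp(-ln(beta0_i/beta1_i)/te * t)   t < te      (decay)
        = beta1_i                                      te <= t <= tr (plateau)
        = beta1_i * exp(beta2 * (t - tr))              t > tr      (relapse)
```

with lognormal baseline (`beta0`) and plateau (`beta1`) levels, per-subject
Bernoulli relapse with normal onset times truncated above `te`, and
Gaussian measurement error. Event times are drawn from a Cox hazard tied to
the trajectory:

```
h_i(t) / h0(t) = exp( gamma' x_i + alpha1 * g(mu_i(t))
                      + alpha2 * g'(t) + alpha3 * G(t) )
```

where `g` is the identity or log10 link, `g'` the trajectory slope, and
`G(t)` the running integral (cumulative burden), all in closed form.
Sampling inverts the cumulative hazard (adaptive quadrature + Brent root
finding, with exact analytic shortcuts where the hazard admits them); an
independent Lewis–Shedler thinning sampler cross-validates it in the test
suite. On top of the generator sit assessment schedules with jitter and
missingness, limit-of-detection (LoD) flagging, Kaplan–Meier and log-rank
summaries, Monte-Carlo power analysis, and a versioned JSON/CSV dataset
format with ground-truth export (see `inst/schema/dataset-schema.json`).

## Worked example

```r
library(mrdsim)
cfg <- example_config()          # illustrative CR/PR/SD/PD ctDNA-style study
ds  <- simulate_cohort(cfg, seed = 1)
ds
#> <mrd_dataset> 100 subjects, 518 observations, 4 subgroup(s)
#>   events: 72, censored: 28; time unit: months; seed: 1

summary(ds)$subgroups
#>   subgroup  n events censored median_followup km_median_event_time    mean_mrd
#> 1       CR 40     18       22       26.597040                   NA 0.007599698
#> 2       PD 10     10        0        2.471479             1.751232 0.150814075
#> 3       PR 30     24        6        8.121397             8.239607 0.021594383
#> 4       SD 20     20        0        5.983589             5.354017 0.083499433

mrd_negativity_rate(ds, lod = 1e-4, landmark_time = 6)
#>   subgroup n_eligible n_negative      rate n_excluded
#> 1       CR         26         18 0.6923077         14
#> 2       PD          3          0 0.0000000          7
#> 3       PR         17          8 0.4705882         13
#> 4       SD         10          0 0.0000000         10
```

Complete responders keep long follow-up, never reach their median event
time, and are mostly MRD-negative at the month-6 landmark; progressive
disease shows the opposite on every column — the joint association at
work. `n_excluded` counts subjects without a qualifying (non-missing,
in-window) landmark visit, mostly those whose follow-up ended before
month 6.

Datasets round-trip through a self-describing JSON document
(`write_dataset_json()` / `read_dataset_json()`, with a `blinded = TRUE`
export that withholds ground truth) and tidy CSVs
(`export_dataset_csv()`). A thin command-line launcher in `inst/cli/mrdsim`
exposes `simulate`, `power`, `summarize`, and `plot`.

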