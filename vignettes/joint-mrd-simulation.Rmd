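---
title: "Joint simulation of MRD trajectories and survival outcomes"
author: "mrdsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint simulation of MRD trajectories and survival outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdsim)
```

## The model

Minimal residual disease (MRD) assays quantify the small tumor burden that
persists after treatment — by flow cytometry, NGS clonality assays, or
circulating tumor DNA (ctDNA). Longitudinal MRD series carry more prognostic
information than single time points, but methods for analyzing them (joint
models, landmarking, surrogate-endpoint evaluation) need benchmark datasets
with known truth. mrdsim generates such datasets by coupling a mechanistic
biomarker trajectory to a Cox hazard.

**Trajectory.** Each subject's true MRD level follows a three-phase
piecewise curve,

$$
\mu_i(t) \;=\;
\begin{cases}
\beta_{0i}\, e^{-\ln(\beta_{0i}/\beta_{1i})\,t/t_e} & t < t_e \\
\beta_{1i} & t_e \le t \le t_{r,i} \\
\beta_{1i}\, e^{\beta_2 (t - t_{r,i})} & t > t_{r,i},
\end{cases}
$$

an exponential decay from the baseline level $\beta_{0i}$ to the plateau
$\beta_{1i}$ at end of treatment $t_e$, a flat plateau (often below the
assay's limit of detection), and, for relapsing subjects, exponential
regrowth at rate $\beta_2$ from the relapse onset $t_{r,i}$. The decay rate
is fully determined by $(\beta_{0i}, \beta_{1i}, t_e)$, so it is
individualized through the subject-level levels rather than drawn
separately. Observations add Gaussian measurement error,
$y_i(t) = \mu_i(t) + \epsilon_i(t)$, $\epsilon_i \sim N(0, \sigma^2)$.

**Hazard.** The event intensity is a Cox model driven by three features of
the current trajectory,

$$
\frac{h_i(t)}{h_0(t)} \;=\; \exp\!\big(\gamma^\top x_i
  + \alpha_1\, g(\mu_i(t)) + \alpha_2\, g'(t) + \alpha_3\, G(t)\big),
$$

where $x_i$ are baseline covariates with log-hazard ratios $\gamma$, and
$\alpha_1, \alpha_2, \alpha_3$ weight the current level, the instantaneous
slope, and the cumulative burden $\int_0^t \mu_i(s)\,ds$. Both the slope
and the cumulative burden have closed forms for the piecewise trajectory
(`traj_slope()`, `traj_auc()`), which is what makes exact event-time
sampling feasible.

## Design choices

Several aspects of the framework are genuinely open; the package fixes them
as follows.

- **Baseline hazard.** Exponential by default, with Weibull and
  piecewise-constant options. The exponential default gives closed-form
  null distributions, which anchor the test suite.
- **Link scale.** `link_scale = "raw"` enters $\mu$, $d\mu/dt$ and
  $\int \mu$ untransformed. Because raw MRD fractions span orders of
  magnitude, a `"log10"` option transforms all three consistently (the
  slope becomes $d\log_{10}\mu/dt$, the integral
  $\int \log_{10}\mu$). The two scales are never mixed within one dataset.
  A hazard exponent above 700 raises an overflow error rather than
  returning `Inf` — it almost always means raw-scale association
  parameters applied to relapse-phase values.
- **Boundary derivatives.** The trajectory is not differentiable at $t_e$
  and $t_r$; `traj_slope()` returns the right-hand derivative there, so a
  hazard evaluated exactly at a boundary reflects the phase being entered.
  When $\beta_0 = \beta_1$ the decay phase degrades continuously to a
  constant, the parameter-continuity limit of the rate formula.
- **Negative observations.** Additive Gaussian noise on a positive
  biomarker can produce negative draws; the reported value is floored at 0
  and the raw draw kept in `raw_value`. A multiplicative (log-normal)
  noise mode is available where strictly positive observations are wanted.
- **Censoring.** The framework itself does not dictate censoring;
  administrative censoring at `t_max` plus optional independent
  exponential dropout is used, with the reason recorded per subject.
  Observations after follow-up end are discarded.
- **Relapse occurrence.** Bernoulli per subject with a subgroup-level
  probability; the relapse time is normal, truncated above $t_e$ by
  rejection (at most 1000 draws, then an error, which signals a
  `relapse_mean` far below $t_e$). $\beta_2$ and $t_e$ are subgroup
  constants.
- **LoD semantics.** `below_lod` is a strict `value < lod` flag; equality
  counts as detectable. Values are not altered unless `censor_at_lod` is
  set, which left-censors them at the LoD.
- **Time-variant covariates** are generated as piecewise-constant tracks
  for export and visualization; the hazard uses baseline covariates only.

## Event-time sampling

The production sampler inverts the cumulative hazard: $T$ solves
$H(T) = -\log U$, $U \sim \mathrm{Unif}(0,1)$. $H$ is computed by adaptive
quadrature (relative tolerance $10^{-8}$) split at the integrand's phase
boundaries, and the root is bracketed on $[0, t_{\max}]$ by Brent's method,
then polished to $|H(T) + \log U| < 10^{-8}$. Two exact analytic shortcuts
are taken automatically when available: under null association the baseline
cumulative hazard inverts in closed form for all three families, and under
an exponential baseline with the log10 link and level-only association the
log-hazard is piecewise *linear* in $t$, so $H$ is a sum of exponential
segments that invert exactly. `method = "quadrature"` forces the generic
path; the test suite verifies all paths agree to $10^{-7}$.

An independent Lewis–Shedler thinning sampler
(`sample_event_time_thinning()`) serves as a distributional oracle: it
proposes from a homogeneous Poisson process at the majorizing rate
$\sup_t h(t)$ — found per smooth piece by endpoint evaluation plus
univariate maximization, exploiting that the per-phase log-hazard has at
most one interior extremum — and accepts with probability $h(t)/h_{\sup}$.
Inversion and thinning samples are checked for Kolmogorov–Smirnov
indistinguishability on non-null specifications.

## Reproducibility

One master seed drives everything. Subject $k$ of a cohort is generated
from `child_seed(seed, k)` (a fixed affine-multiplicative hash modulo
$2^{31}-1$), with a documented per-subject draw order: baseline level,
plateau level, relapse occurrence, relapse time, covariates, event uniform,
dropout uniform, visit jitter, visit missingness, then one noise draw per
retained non-missing visit. Power-analysis replicates derive per-arm seeds
the same way. Consequently a fixed `(config, seed)` yields byte-identical
JSON output, and any subject or replicate can be regenerated in isolation.

## What the generator does and does not emulate

The defaults in `example_config()` sketch a ctDNA-style study: MRD as a
variant-allele fraction with LoD $10^{-4}$, monthly time unit, quarterly
assessments over 36 months with visit jitter (SD 0.2 months) and 5%
missed visits, four response subgroups (CR/PR/SD/PD) with progressively
higher plateaus and relapse probabilities, an exponential baseline hazard
and a log10 level association ($\alpha_1 = 0.6$). These values are
illustrative, chosen to produce clinically plausible orderings (CR
subjects MRD-negative and long-lived, PD subjects relapsing early); they
are not estimates from any study.

Features of real data the generator deliberately does not model:
informative missingness (missed visits are independent of MRD level),
assay batch effects and heteroscedastic error, treatment switching,
competing risks, and measurement-frequency changes triggered by clinical
events. Passing tests therefore demonstrate correctness of the simulator's
own model, not fidelity to any particular trial.

## Numerical checks behind the test suite

The suite validates each layer against an independent route: closed-form
trajectory integrals against adaptive quadrature (relative $10^{-6}$),
slopes against central finite differences, cumulative hazards against a
$10^5$-point trapezoid rule, the inversion sampler against closed-form
exponential nulls (Kolmogorov–Smirnov and moment checks at $n = 5000$) and
against the thinning oracle on non-null hazards ($n = 2000$ per arm),
Kaplan–Meier output against hand-computed product limits and Greenwood
bands at $n = 2000$, log-rank calibration over 1000 null replicates, and
association recovery by a counting-process Cox fit (50 replicates of 500
subjects on a 0.25-month assessment grid, 95% CI coverage of the true
$\alpha_1$). Those problem sizes keep the default test run at a few
minutes on a single core while leaving Monte-Carlo noise well below the
tolerances tested.

## A worked example

```{r example, eval = FALSE}
cfg <- example_config()
ds <- simulate_cohort(cfg, seed = 1)
ds
summary(ds)$subgroups
mrd_negativity_rate(ds, lod = 1e-4, landmark_time = 6)

# files: versioned JSON (with ground truth) + tidy CSVs
write_dataset_json(ds, "dataset.json")
export_dataset_csv(ds, "csv_out")

# two-arm power for a baseline hazard ratio of 0.5
trt <- cfg
trt$hazard$baseline_params$rate <- cfg$hazard$baseline_params$rate / 2
power_analysis(cfg, trt, n_reps = 200, alpha_level = 0.05, seed = 1)
```

The same workflow is available from a shell through the launcher in
`inst/cli/` (`simulate`, `power`, `summarize`, `plot`).

## Limitations

The simulator samples from the joint model; it does not fit joint models
to real data. Closed-form survival functions do not exist under non-null
association, so all distributional guarantees are backed by quadrature
tolerances and Monte-Carlo tests rather than algebra. The JSON schema is
this package's own versioned contract — documented in
`inst/schema/dataset-schema.json` — and adapters may be needed for other
tools' readers.
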