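---
title: "Evaluating pediatric valproate popPK models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating pediatric valproate popPK models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpaeval)
```

This vignette is the package's account of the science it implements: the
models, the diagnostics, the tunable parameters, the numerical choices,
and what the synthetic-data results do and do not show about real data.

## The problem

Valproic acid (VPA) binds extensively (90–95 %) and saturably to plasma
albumin. Because clinical assays measure *total* concentration while only
the unbound drug is cleared and pharmacologically active, total VPA
kinetics are non-linear: doubling the dose less than doubles the total
trough. Pediatric therapeutic drug monitoring (TDM) data are sparse —
typically one steady-state trough per visit — so dose individualization
relies on population pharmacokinetic (popPK) models plus Bayesian
forecasting. A model developed at one center may transfer poorly to
another; this package implements the full battery used to quantify that
transferability, and the five protein-binding modeling strategies whose
influence on predictive ability it probes.

## The model library

Ten published pediatric VPA popPK models are encoded from their printed
equations (`model_registry()` and `export_model_registry()` expose every
constant). All are one-compartment with first-order absorption except
`ogungbenro` (two-compartment). Conventions:

* **Typical parameters.** The covariate equations are evaluated exactly as
  printed: allometric weight scaling (reference 70 kg where printed),
  age or postmenstrual-age maturation terms, daily dose (total, `DD`
  mg/day, or weight-normalized, `DDW` mg/kg/day) and co-medication
  multipliers (carbamazepine, phenobarbital, phenytoin, lamotrigine,
  clobazam) applied only when the corresponding flag is set.
* **Between-subject variability.** Printed CV% values become lognormal
  etas with `omega = CV/100`, the usual pharmacometric reading. The exact
  alternative `omega = sqrt(log(1 + CV^2))` differs by under 3 % at these
  magnitudes and is available via
  `options(vpaeval.bsv_convention = "exact")`. Two entries of the
  `nakashima` model are printed as eta variances and are used as such.
  The `ogungbenro` model prints eta covariances for CL–Vc, CL–Vp and
  Vc–Vp; read as an OMEGA block they form a valid positive-definite matrix
  (implied correlations 0.56, 0.21, 0.72), and draws honor it.
* **Residual error.** Entries printed in mg/L are additive; entries
  printed in % are proportional — exactly as the source column prints
  them.
* **Absorption.** Six models fix the absorption constant by formulation.
  Where a model provides no constant for a formulation present in a
  dataset (e.g. a sustained-release tablet under a model that lists only
  syrup and enteric-coated rates), the package assigns by release class:
  liquid forms take the model's fastest printed rate,
  sustained/delayed-release its slowest, immediate-release solids an
  intermediate one. The registry records which entries are printed and
  which are class-mapped. An unrecognized formulation errors rather than
  guesses.
* **Two reconstructed equations.** The `jiang` clearance is implemented in
  the internally consistent multiplicative form
  `CL = 0.106·0.98^CO + 0.0157·AGE` (CO = 1 with any co-medication), which
  reproduces the model's documented typical clearance of 0.18 L/h at the
  reference age 4.92 y; the literal rendering `0.106^(0.98·CO)` (which
  yields ≈1.08 L/h) is available behind
  `options(vpaeval.jiang_literal = TRUE)`. The `ding` weight exponent is an
  age-dependent Hill function `0.791 − 0.096·AGE^8.63/(th50^8.63 +
  AGE^8.63)` with `th50` defaulting to 0.802 years
  (`options(vpaeval.ding_th50 = )`), the best reconstruction of a
  typographically damaged source equation.
* **Unbound-scale models.** The `gu` model's structural parameters
  describe unbound drug — hence its apparent volume of 1680 L — and its
  observation function maps unbound to total concentration through the
  linear non-saturable binding equation. This same construction carries
  over to binding strategies I, II and IV below.

## Structural kinetics

Steady-state concentrations use the closed-form geometric accumulation of
the single-dose solution; `conc_superposition()` is the brute-force oracle
the closed forms are tested against (agreement to 1e-6 relative over
random parameter draws, and to 1e-5 against an ODE integration for the
two-compartment model). Numerical choices:

* When `|ka − ke|/ke < 1e-8` the solution switches to the analytic
  `t·exp(−kt)` limit, avoiding catastrophic cancellation at the
  absorption–elimination degeneracy; the same guard (an invisible relative
  nudge) separates `ka` from the two-compartment hybrid constants.
* A lag time shifts the absorption clock; within a steady-state interval,
  times before the lag evaluate the previous interval's tail (modulo-tau
  wraparound), so the trough at `t = 0` equals the value at `t = tau`.
* All parameters are apparent (CL/F, V/F): bioavailability is absorbed,
  matching how the source models are parameterized.
* Steady-state trough records are represented as one dose event flagged
  steady-state with an interdose interval, not an explicit dose history —
  the natural encoding for TDM troughs drawn under maintenance dosing.
  The time scale of the event table is clock-agnostic: only time after
  the (steady-state) dose matters for prediction.

## Protein-binding strategies

Five strategies relate dose or unbound concentration to observations, with
literature-fixed constants (`binding_params()`):

| Strategy | Equation | Fixed constants | Estimated |
|---|---|---|---|
| I, one binding site | `Cb = N·K·Cu·ALB/(1 + K·Cu)` | N = 1.98, K = 15.5 /mM | CLu, Vu, ω, σ |
| II, Langmuir | `Cb = Bm·Cu/(Kd + Cu)` | Kd = 7.8, Bm = 130 mg/L | CLu, Vu, ω, σ |
| III, dose-dependent Emax | `CL = CLp·(1 + Emax·DDW^γ/(DD50^γ + DDW^γ))` | Emax = 2.8, γ = 1.68 | CLp, V, DD50, ω, σ |
| IV, linear non-saturable | `Cb = Bm·Cu/(Kd + Cu) + NS·Cu` | Kd = 2.12, Bm = 67.3 mg/L, NS = 2.25 | CLu, Vu, ω, σ |
| V, simple exponent | `CL = CLp·(DDW/25)^k` | reference dose 25 mg/kg/day | CLp, V, k, ω, σ |

The one-binding-site association constant is printed per mM while
concentrations are handled in mg/L; the package converts through molar
masses of 144.21 g/mol (VPA) and 66 500 g/mol (albumin) — a choice the
source constants force but do not spell out. `unbound_from_total()`
inverts the strictly monotone observation functions by safeguarded
bisection to 1e-10 mg/L; the round trip holds to 1e-8 over the clinical
range. Strategies I/II/IV track unbound drug in the structural compartment
(the Gu construction); III and V act on total-concentration clearance with
the weight-normalized daily dose as the driver (model III's printed DD50 of
37.4 mg/kg/day and model V's divisor of 25 — the cohort's median dose —
both indicate that dose metric).

In `binding_model()` / `fit_binding_model()`, clearance scales
allometrically (exponent 0.75) and volume linearly on weight, referenced
to 19 kg — the cohort's median weight — so `clp` is the typical value for
the median child; typical defaults (`clp` 0.31 L/h total-scale, ~3 L/h
unbound-scale) reflect a base-model clearance of 0.31 L/h for such a
cohort. Absorption is fixed by formulation (syrup 2.64/h, sustained
release 0.46/h): trough-only data carry no absorption information.

### Estimation

`fit_binding_model()` maximizes a Laplace approximation of the marginal
likelihood. Per subject, the inner problem MAP-estimates a scalar
clearance eta (safeguarded, damped Newton iterations run vectorized across
all subjects; derivatives by central differences with step 1e-4), and the
objective adds the log-curvature Laplace correction. The outer problem is
bounded quasi-Newton (L-BFGS-B) on log-transformed parameters (the model V
exponent stays untransformed) with 5 multi-starts jittered by the seed;
the best short run is polished until the objective change falls below
1e-6. The optimizer works inside a box of ±2.5 log units around the
starting values — a ~12-fold span each way — and the objective is capped
at 1e10 because far outside that region the inner interpolation penalty
grows astronomically and destabilizes line searches. A terminal
line-search warning from L-BFGS-B (its code 52) is accepted as converged
when the polished value did not lose ground against the multi-start
optimum, a behavior characteristic of finite-difference gradients near a
flat optimum. Any parameter can be held fixed (`fix =`), which is also how
variance components are profiled and how noiseless identifiability is
exercised. With one trough per subject, ω and σ are only jointly
identified (a single variance split); estimates of their sum are stable
while the split is data-dependent.

## Prediction-based diagnostics

`PE% = (PRED − OBS)/OBS × 100` with population predictions (random
effects at zero). MDPE measures accuracy (bias), MAPE precision, F20/F30
the fraction of errors within ±20 %/±30 % (boundary values count as
within; even-length medians average the two central order statistics).
The verdict requires all of |MDPE| ≤ 15 %, MAPE ≤ 30 %, F20 > 35 %,
F30 > 50 %. PE values are pooled across samples (each observation
contributes one PE). `published_performance()` ships the reported
benchmark rows for the ten models and five strategies; feeding the ten
population rows to `check_criteria()` classifies exactly six models as
acceptable — the package's cheapest end-to-end consistency check.

## Simulation-based diagnostics

`simulate_replicates()` redraws etas per subject and residual errors per
observation, holding the design fixed (2000 replicates for production
use; calibration studies in the tests use 500). NPDE decorrelates each
subject's observed and simulated vectors with the lower-triangular
Cholesky factor of the empirical simulated covariance — the standard
published construction — and maps the observation's rank among the
decorrelated simulations through the normal quantile function, with the
rank fraction clamped to `[1/(2K), 1 − 1/(2K)]`. The battery tests zero
mean (Wilcoxon signed-rank), unit variance (two-sided chi-square on the
sample variance — the construction used for the "exact variance test" in
reference NPDE software; the name is retained as a naming decision), and
normality (Shapiro–Wilk), combined by Bonferroni: reject when
`min(p) < alpha/3`. A rejection statement phrased with an inverted
inequality in parts of the surrounding literature is implemented in the
standard direction — reject for small p.

The pcVPC normalizes each observation and simulation by
`median(PRED in bin)/PRED`, bins on time after dose with quantile-based
automatic binning (duplicate edges merge, which with trough-only designs
correctly collapses to few bins), and compares observed
2.5th/50th/97.5th percentiles with the simulated band of each percentile.

## MAP Bayesian forecasting

`map_estimate()` minimizes the standard MAP objective — weighted residual
sum of squares plus `eta' Omega^-1 eta` — with the proportional residual
SD evaluated at IPRED (not OBS), which keeps the estimator consistent
under the simulation model. One-dimensional etas use golden-section
search on `[-15, 15]`; multi-dimensional etas use BFGS from zero, and the
result is never allowed to exceed the objective at `eta = 0`. The
forecasting protocol uses the *earliest* observation as the single prior
and predicts the *last* observation (with more than two observations the
choice of prior is a convention; first-observation order matches how TDM
accrues). Shrinkage is reported as `1 − SD(eta_hat)/omega` per eta.

## The synthetic cohort

`cohort_config()` encodes the virtual pediatric TDM population the
package's stochastic checks run on: age lognormal (median 4.92 y, log-SD
0.555 — chosen so mean and SD match a 5.74 ± 3.67 y population) truncated
to 0.17–15 y; weight from the coarse growth rule `2·age + 9` kg with 15 %
lognormal noise, truncated to 4–70 kg; weight-normalized daily dose
lognormal (median 23.44, log-SD 0.31) truncated to 8.7–57.69 mg/kg/day,
rounded to 10-mg total strengths and split into 1–3 daily administrations
(probabilities 0.15/0.70/0.15 — twice daily dominating pediatric VPA
practice); formulations 76 % syrup / 24 % sustained release; albumin
normal (42.21 ± 3.65 g/L, truncated 29.7–70.5); co-medication at the
observed per-sample prevalences (carbamazepine 3/255, lamotrigine 10/255,
newer agents pooled as `other_comed` 82/255; classical inducers
phenobarbital/phenytoin/clobazam absent by default); 69 % male; 26 % of
subjects contribute a second trough (255 samples from 202 children); and
a 1 mg/L limit of quantification with flag-and-keep handling (no
imputation — the flag lets analysts decide). Observations are steady-state
troughs at the end of an interval. Negative additive-error draws (well
under 1 % at cohort-typical concentrations) are redrawn rather than
truncated so observations stay positive, as percent prediction errors
require.

What the generator does *not* emulate: real growth charts (the age–weight
rule is deliberately coarse, adequate for exercising covariate equations
but non-physiologic), TDM-feedback dose titration (doses are drawn
independently of simulated exposure, so dose–clearance confounding present
in real TDM data is absent), assay bias between laboratories, and
adherence noise. Passing the package's stochastic checks therefore shows
the machinery is correct and calibrated under its own assumptions — it
does not certify any model's real-world transferability.

## Design choices in the open

* **Self-evaluation bounds.** Simulating a cohort from a model and
  evaluating the same model should pass the acceptability criteria —
  and does, for models whose printed variances allow it. Two library
  models cannot pass their own simulation by construction: with a 57.7 %
  proportional residual on top of 26.8 % BSV (`serrano2022`), or
  34.8 % on 35.9 % (`ogungbenro`), the self-simulated MAPE exceeds 30 %
  as a matter of arithmetic. The tests assert unbiasedness (MDPE ≈ 0) for
  all models and the full verdict only where the variances are
  compatible. That these models nonetheless passed on the real cohort
  simply reflects that real data variability is smaller than their
  printed error terms.
* **Forecasting-improvement check.** The improvement of MAIPE over MAPE
  is demonstrated on the `rodrigues` model (33.9 % BSV, 15.4 % residual):
  the prior-informative regime, since one observation identifies the
  clearance eta when BSV dominates residual noise. Models with additive
  residuals of ~30 % of a typical trough (e.g. `serrano2019`) improve
  less — shrinkage keeps the eta estimate conservative — which is the
  expected behavior, not a defect.
* **Problem sizes.** The stochastic suites use the cohort sizes the
  checks state: 202–500 subjects for cohort and self-evaluation checks,
  200 subjects × 100 repetitions at 500 replicates for NPDE calibration
  and power, 300 subjects for binding-fit recovery. These sizes put
  Monte-Carlo error comfortably inside the stated tolerances.
* **PMA derivation.** Only the `gu` model needs postmenstrual age; when
  absent it is derived as postnatal age (weeks) + 40, i.e. a term-birth
  default, and the derivation is reported. The Hill constant 33.7 in that
  maturation function is consistent with weeks.

## Known limitations

* The binding-strategy fits use a Laplace approximation with a single
  clearance eta; no FOCE-with-interaction parity with commercial
  estimation software is claimed, and published parameter estimates for
  those five strategies are not reproduced (they were estimated on data
  that are not public).
* Multi-prior forecasting (`n_priors > 1`) is available in the API but
  carries no benchmark: the motivating dataset could not support it.
* No covariate-by-time interactions, transit-compartment absorption or
  nonlinear-elimination structural models: no library model uses them.
* `eldesoky`'s additive covariate model cannot go negative for physical
  covariates, but a defensive floor at 1e-6 L/h (with a warning) guards
  pathological inputs.
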