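---
title: "Methods: early health economic evaluation of clinical analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: early health economic evaluation of clinical analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earlyhta)
```

## The decision problem

Developers of data-driven clinical analytics face a staged go/no-go
decision long before any trial exists: is the candidate development
dataset good enough, are the barriers to implementation surmountable,
and — if so — could the analytics plausibly generate enough health and
economic benefit to justify continued investment? `earlyhta` implements
that staged assessment: a quantitative data audit, a PICO-structured
barrier ledger, and a cohort-level early economic evaluation with a full
uncertainty toolkit.

An *early* evaluation differs from a reimbursement dossier: many inputs
are assumptions or expert guesses, so the point of the model is less the
base-case number than the sensitivity machinery around it — which
parameters dominate, at what price the technology stops paying for
itself, and how the business case moves with the epidemiology of the
target market.

## Data audit and scope

`audit_dataset()` computes the fitness metrics the development decision
turns on: sample size, median follow-up (last contact minus enrolment),
per-field missingness, site count and outcome capture. Thresholds are
deliberately **not** package defaults — they encode clinical judgement and
always arrive through `data_requirement()` rows; the overall verdict is
`not-feasible` iff at least one requirement fails. Two numerical choices
matter:

* patients whose follow-up cannot be computed (missing or unparseable
  dates) are excluded from the median and reported in a separate
  *follow-up unknown* fraction — including them as zeros would bias the
  median and dropping them silently would hide the problem;
* unparseable dates are counted as missing and noted, never fatal, since
  real EHR extracts routinely contain malformed fields.

Site heterogeneity is handled descriptively (per-site stratification of
the same metrics); no formal heterogeneity statistic is computed, and
selection bias is explicitly reported as "not assessed".

`scope_ledger()` captures Population, Intervention, Comparator and
Outcomes plus a barrier list; `evaluate_scope()` proceeds to evaluation
iff no barrier is graded insurmountable. Surmountable barriers are
returned so they can seed scenario analyses.

## The evaluation engine

The engine is a discrete-time Markov cohort simulation, optionally fed by
a decision tree. A `state_model()` holds health states with per-cycle
costs and utilities and a transition matrix $P$ (or a sequence $P_t$ for
time-dependent transitions, e.g. a digitised time-to-event curve);
`run_cohort()` propagates the entry occupancy $\pi_0$ as
$\pi_t = \pi_{t-1} P_t$. `rollback_tree()` collapses a finite acyclic
decision tree into an entry distribution and an expected upfront cost by
probability-weighting every root-to-terminal path — the standard
construction when a short-term care-pathway tree (infection, detection
timing) feeds a long-term state-transition model.

`accumulate_outcomes()` converts a trace into discounted totals:

$$\text{cost} = C_0 + \sum_{t=1}^{T} \delta_c(t)\,\tilde\pi_t c, \qquad
  \text{QALY} = \sum_{t=1}^{T} \delta_e(t)\,\tilde\pi_t u \,\Delta, \qquad
  \delta(t) = (1+r)^{-t_\ast}$$

with $c$ the per-cycle state costs, $u$ the state utilities, $\Delta$ the
cycle length in years, and life-years the same sum over non-absorbing
occupancy with $u \equiv 1$.

Numerical and modelling choices:

* **Half-cycle correction** (default on): transitions happen throughout a
  cycle, not at its end, so $\tilde\pi_t = (\pi_{t-1}+\pi_t)/2$
  (trapezoidal) and payoffs are discounted at the cycle midpoint
  $t_\ast = (t-\tfrac12)\Delta$. With the flag off, end-of-cycle
  occupancy and end-of-cycle discounting are used — the convention the
  naive spreadsheet-style oracle in the test suite implements.
* **Row-sum tolerance**: transition rows must sum to 1 within $10^{-9}$;
  smaller drift (accumulated floating-point error in derived
  probabilities) is renormalised silently, larger deviations are
  rejected with the offending state named. Absorbing rows are forced to
  exact identity.
* **Hazard ratios** are applied on the rate scale,
  $p' = 1-(1-p)^{\text{HR}}$ (`hr_adjust_probability()`), the standard
  transform between a published hazard ratio and a per-cycle
  probability. $\text{HR}=1$ returns $p$ bit-exactly (the naive
  expression loses an ulp, which would break exact null-intervention
  identities downstream); $p = 1$ with $\text{HR}\neq 1$ is rejected
  because the underlying rate is infinite.
* **Cohort mixtures**: when an arm is a probabilistic mixture of
  pathways (e.g. only the high-risk fraction is treated early),
  `mix_arms()` computes $x_1 + \sum_{i>1} w_i (x_i - x_1)$ — algebraically
  the weighted mean, but exactly equal to the common value when all
  pathways coincide, again preserving exact nulls.

`compare_arms()` performs exact subtraction (intervention minus
comparator), reports ICERs only where the effect denominator is nonzero
(`NA`, never $\pm\infty$; a dominance label carries the interpretation),
and `headroom()` implements $\text{headroom} = N + \lambda Q$: the saving
at zero technology cost plus the monetised health gain, i.e. the maximum
justifiable price of the technology including validation and
implementation.

## Uncertainty toolkit

* `owsa()` re-evaluates the full model at each parameter's low and high
  bound with everything else at base; bars are drawn around the
  base-case outcome and sorted by swing (the tornado convention).
* `scenario()` applies named overrides simultaneously, leaving the base
  set untouched.
* `psa()` draws all parameters independently from their distributions and
  pushes each joint draw through the model. Defaults follow standard
  practice: beta for probabilities and utilities (method of moments via
  `beta_from_moments()`), gamma for costs, lognormal for hazard ratios
  (median + 95% interval via `lognormal_from_interval()`), uniform as a
  fallback; $n = 1000$ draws by default. Draws are bit-reproducible
  under a fixed seed. Parameter correlations are **not** modelled — a
  known limitation of independent-draw PSA; rank-correlation or copula
  sampling is out of scope.
* `ceac()` reports, per willingness-to-pay $\lambda$, the fraction of
  draws with strictly positive net monetary benefit
  $\lambda\,\Delta Q - \Delta C$; a tie (NMB exactly zero) counts as not
  cost-effective. The default $\lambda$ grid is 0–200,000 in steps of
  1,000, covering the thresholds discussed in European practice.
* `threshold_search()` bisects a single parameter until a boolean
  criterion on the outcome flips, to an absolute tolerance of 0.01
  currency units by default. Bisection (rather than a continuous root
  finder) is used because the criterion is a predicate, not a smooth
  function; monotonicity over the range is checked empirically on a
  coarse grid and a non-monotone criterion triggers a warning. A range
  with no flip returns a no-threshold result, not an error.
* `parameter_sweep()` evaluates the model over a grid of one parameter —
  the construction behind the prevalence-vs-savings curve.

## The two case models

Both case configurations are **illustrative instantiations**: the
published material prints only a handful of inputs (the best-case
scenario values) and the per-patient results, not the full input tables,
and the four-state structures are reconstructions declared in config.
Every non-printed value carries `source_tag = "assumption"`. The models
therefore support the *pattern* of the analysis — directions, limits,
thresholds, sensitivity structure — not reproduction of absolute
published totals.

Shared conventions (design choices, configurable per call): monthly
cycles (drug costs are quoted per cycle), a 40-year horizon as the
lifetime approximation, 3% annual discounting of both costs and effects
(common European practice), healthcare-payer perspective with direct
medical costs only.

**CLL stratification** (`build_cll_model()`): states watch-and-wait →
first-line treatment → relapse → dead. The comparator manages everyone
expectantly; the intervention pays an upfront analytics-plus-testing
cost, and the identified high-risk fraction starts ibrutinib early:
the watch-and-wait→treatment transition is scaled by the
time-to-next-treatment hazard ratio and the drug cost accrues while in
watch-and-wait. The early-treatment utility defaults to the
watch-and-wait utility so that a null intervention (HR 1, zero analytics
and drug cost) leaves the arms *exactly* identical — the best-case
scenario then raises it explicitly to 0.78.

**CRBSI early detection** (`build_crbsi_model()`): a decision tree on
infection occurrence and detection timing carries the acute episode
(ICU days at a per-day cost, an infection-attributable extra stay that
early detection shortens, antibiotics, ICU death); survivors enter a
four-state Markov model (ICU, post-ICU ward, discharged, dead) for the
remaining lifetime. The technology is priced per bed and divided by
`patients_per_bed`, the annual bed throughput — exposed as an explicit
parameter (default 21.7 patients/bed/year, i.e. a ~17-day mean
occupancy, a realistic ICU figure) because the published per-bed
threshold depends on it. At base the technology price is zero, so the
base-case saving *is* the headroom numerator $N$, and the price
threshold per bed equals the per-patient saving times throughput.

## Synthetic data

`generate_parameter_set()` emulates the statistical shape of an
early-HTA input table (beta probabilities/utilities, gamma costs,
lognormal hazard ratios, ranges containing the base);
`generate_patient_table()` emulates EHR extracts: uniform enrolment over
a recruitment window, exponential follow-up with administrative
censoring, site labels, and missing-completely-at-random masking per
field. What it does **not** emulate: informative missingness, correlated
covariates, measurement error, or site-level outcome heterogeneity — so
green audit round-trips demonstrate metric correctness, not robustness
to real-world missingness mechanisms.

## Problem sizes and verification

The test suite verifies the engine against independent naive oracles
(explicit-loop matrix propagation, spreadsheet-style accumulation,
exhaustive tree-path enumeration) on 100 random 3–5-state models over
100 cycles at $10^{-12}$; PSA mean recovery uses a closed-form linear
model with $n = 10{,}000$ draws against analytic Monte-Carlo standard
errors; the bundled analyses use $n = 1000$ PSA draws and 480-cycle
(40-year monthly) cohort runs. These sizes were chosen so the whole
pipeline re-runs in seconds while keeping Monte-Carlo noise well below
the effects being checked.

## Known limitations

Cohort-level only (no microsimulation or patient-level heterogeneity
beyond the risk-stratified mixture); discrete time (no continuous-time
processes); survival inputs must arrive pre-digitised as per-cycle
probabilities; independent PSA draws; no value-of-information analysis;
no budget-impact or societal-perspective costing; the case parameter
sets are illustrative and should be replaced wholesale before any
real-world use.
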