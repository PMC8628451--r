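# earlyhta

Early health economic evaluation of data-driven clinical analytics.

Developers of clinical prediction and detection analytics must decide,
long before clinical evidence exists, whether continued development is
worth the investment. `earlyhta` implements that staged decision as
code, for health economists and analytics developers:

1. **Data audit** — is the candidate development dataset fit for purpose?
   (`audit_dataset()`: sample size, median follow-up, per-field
   missingness, site count, outcome capture, checked against
   user-supplied requirements.)
2. **Scope and barriers** — a PICO ledger (`scope_ledger()`) with a
   go/no-go verdict: development proceeds only when no barrier is
   insurmountable (`evaluate_scope()`).
3. **Early economic evaluation** — decision trees rolled back into Markov
   cohort models, with discounted costs, life-years and QALYs per arm,
   incremental results and a full uncertainty toolkit.

## The model

A strategy arm is an optional decision tree feeding a discrete-time
Markov cohort model. The tree collapses to an entry distribution and an
expected upfront cost; the cohort then evolves as π<sub>t</sub> =
π<sub>t−1</sub>P<sub>t</sub>, and discounted outcomes accumulate per
cycle (trapezoidal half-cycle correction by default):

- cost = C₀ + Σ<sub>t</sub> (1+r)<sup>−t</sup> π̃<sub>t</sub>·c
- QALY = Σ<sub>t</sub> (1+r)<sup>−t</sup> π̃<sub>t</sub>·u · Δ

Two arms compare as ΔC, ΔE, ICER = ΔC/ΔE, net monetary benefit
NMB(λ) = λ·ΔQALY − ΔC, and the **headroom** for pricing a technology is

> headroom = N + λ·Q

with N the savings at zero technology cost and Q the QALYs gained.
Hazard ratios map onto per-cycle probabilities on the rate scale,
p′ = 1 − (1−p)<sup>HR</sup>.

The uncertainty toolkit covers one-way/tornado analysis (`owsa()`),
scenario analysis (`scenario()`), probabilistic sensitivity analysis
(`psa()`, seed-reproducible, beta/gamma/lognormal distributions by
parameter kind), acceptability curves (`ceac()`), bisection threshold
search (`threshold_search()`) and parameter sweeps
(`parameter_sweep()`). Synthetic-data generators
(`generate_parameter_set()`, `generate_patient_table()`) produce every
input the pipeline needs, so the whole framework is testable without
patient data.

Two worked case models ship with the package: risk stratification of
newly diagnosed watch-and-wait chronic lymphocytic leukaemia
(`build_cll_model()`) and early detection of catheter-related
bloodstream infection in the ICU (`build_crbsi_model()`). Their
parameter tables (`inst/extdata/*.tsv`) are illustrative assumptions,
not published input tables; see the methods vignette.

## Worked example

```r
library(earlyhta)

params <- crbsi_parameter_set()
res <- build_crbsi_model(base_values(params))
cat(render_comparison_report(res, "CRBSI base case (technology price 0)",
    c("late detection", "early detection")), sep = "\n")
#> == CRBSI base case (technology price 0) ==
#>                                   cost   life years        QALYs
#> late detection                  23,518        12.70         9.52
#> early detection                 22,642        12.77         9.57
#> incremental                       -876         0.07         0.05
#> ICER                                 -      -12,278      -16,388
#> dominance: dominant
```

Per ICU patient, early detection saves €876 and gains 0.05 QALYs —
a dominant strategy at zero technology price, so the saving is the
headroom numerator N:

```r
headroom(N = -res$delta_cost, lambda = 20000, Q = res$delta_qaly)
#> headroom = N + lambda * Q = 876.12 + 20000 * 0.0535 = 1945.37

threshold_search(build_crbsi_model, params, "price_per_bed",
                 function(cr) cr$delta_cost < 0, lower = 0, upper = 50000,
                 tol = 0.5)
#> criterion flips at 19011.8790 (searched [0.0000, 50000.0000])
```

At €20,000 per QALY the technology is worth up to €1,945 per patient;
purely on cost-neutrality it can charge up to ≈ €19,012 per bed per year
(per-patient saving × 21.7 patients/bed/year). A prevalence sweep
(`parameter_sweep(..., "p_crbsi", ...)`) shows the savings scale
linearly with the infection rate — the key market consideration.

The numbered scripts under `analysis/` run the full workflow (audit →
scope → CLL base/best case, tornado and PSA → CRBSI thresholds and
prevalence sweep) and write tables under `results/`.

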