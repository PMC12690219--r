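---
title: "Methods: a fracture-prevention cost-effectiveness microsimulation for women on aromatase inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fracture-prevention cost-effectiveness microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The decision problem

Aromatase inhibitors (AIs) are standard adjuvant endocrine therapy for
postmenopausal women with hormone receptor–positive early breast cancer.
They roughly double the pace of bone-mineral-density (BMD) loss — on the
order of 10% over a 5-year course — and with it the risk of hip, vertebral
and other fragility fractures. A health system can screen with DXA and
treat selectively (osteoporosis, T-score ≤ −2.5, or osteopenia,
T-score ≤ −1.0), treat everyone, or do nothing. `osteocea` quantifies that
trade-off as discounted lifetime cost and quality-adjusted life years
(QALYs) per woman, compared through incremental cost-effectiveness ratios
(ICERs) against a willingness-to-pay (WTP) threshold of $38 223/QALY
(three times 2022 GDP per capita, converted at 6.7321 CNY/USD).

## Model structure

Women enter at age 60 (or an older band in scenarios), disease-free, with
a baseline femoral-neck T-score drawn from the age band's distribution,
and start a 5-year AI course. Time advances in 1-year cycles to age 100 or
death. Each cycle applies, in this fixed order:

1. **Strategy decision.** Screening fires per schedule (cycle 0 for
   one-time; every k years for periodic) while the woman has never started
   treatment; screening measures the current model T-score without error.
   Treatment starts if the strategy is universal (cycle 0) or the measured
   T-score meets the threshold. At initiation an all-or-nothing adherence
   draw decides whether the course takes effect; non-adherent women incur
   one cycle of drug cost and no effect. One course per lifetime;
   screening stops once treatment starts.
2. **Cancer transition.** Disease-free → locoregional/contralateral
   recurrence → distant metastasis, with per-cycle probabilities
   1 − S(t)/S(t−1) from parametric survival fits evaluated on a
   time-in-state clock that resets on entry to each state. Distant
   metastasis is absorbing among cancer states.
3. **Fractures.** Unless bedridden, each site (hip, vertebral, other) can
   fracture at most once per cycle, drawn independently; two or more sites
   in one cycle count as a complex fracture. A hip fracture triggers a
   bedridden draw (p = 0.10/event by default); the bedridden state blocks
   all further fracture events.
4. **Death.** Women with distant metastasis die through the fitted
   all-cause survival curve of that state (step 2); everyone else faces
   the age-specific background probability, multiplied by an age-indexed
   hazard ratio after a hip fracture. Layering background mortality on top
   of the metastatic curve would double-count deaths, so the engine uses
   the fitted curve alone in that state.
5. **BMD update.** T-score falls by a constant 0.12 SD/year during the AI
   course, then by the age-specific natural rate (0.04–0.06 SD/year).
6. **Accrual.** Costs and utilities are discounted at 5%/year with cycle 0
   undiscounted and no half-cycle correction (full-cycle accrual, the
   convention of the microsimulation tooling this model family comes
   from). Death during a cycle forfeits that cycle's utility and
   continuing costs but keeps event costs (DXA, drug, acute fracture)
   incurred before it.

### Fracture risk model

The annual rate for site *s* at age *a* and age-matched Z-score *Z* is

    r = a_s exp(b_s a) × scale_s × g_s^(−Z) × RR_repeat × RR_treatment

where `a_s exp(b_s a)` is the incidence at the age-matched mean BMD,
`g_s` the gradient of risk per SD of BMD (2.6 hip, 1.8 vertebral, 1.5
other — the standard osteoporosis-epidemiology convention, used because
published incidence models are age- and BMD-specific without agreeing on
a single functional form),
`RR_repeat` the repeat-fracture multiplier applied when any prior fracture
exists except for vertebral events, and `RR_treatment` the drug effect.
Z-scores come from T-scores via the age-specific population mean and SD in
T-score units, so the two scales coincide at the young-adult reference
age. Rates convert to per-cycle probabilities as p = 1 − e^(−rt), which is
bounded by r·t and first-order equal to it for small risks.

After a bisphosphonate course ends, the relative risk returns to 1
linearly over a residual period equal to the treatment duration
(alendronate 5 y, zoledronate 3 y); the decay shape is a modelling choice
— the evidence says only that the effect fades gradually — and linearity
makes the effect continuous at the stop time and exactly 1 at the offset
end. Denosumab has no residual effect by default (its discontinuation
physiology is debated; the parameter is configurable).

### Utilities and costs

Cycle utility is the age-specific general-population utility times a
cancer-state multiplier (disease-free 0.95 down to distant metastasis
0.68) times fracture multipliers — first-year values in the fracture
cycle, subsequent-year values afterwards, multiplied across sites.
Multiplicative combination is the default (an additive variant is
configurable; the evidence does not pin the combination rule down).
Bedridden women accrue an absolute utility of 0.28. Costs cover drug
courses, DXA scans, acute fracture treatment, annual post-fracture
management, long-term care while bedridden, and — under the societal
perspective — non-medical attendant costs in the fracture year plus an
annual caregiver lost-work value during the first post-fracture year and
bedridden years. Breast-cancer treatment costs are deliberately out of
scope; osteoporosis-related costs are modelled as independent of them.

## Survival-curve pipeline

Cancer transition probabilities are meant to be estimated from published
Kaplan–Meier figures. `km_curve()` holds a digitized curve plus its
numbers-at-risk table; `reconstruct_ipd()` recovers pseudo-individual
patient data by interval-wise allocation of events and censorings
consistent with the risk table (a Guyot-type algorithm). Two numerical
details matter: the digitized survival value at a grid point already
includes events at that instant, so published at-risk counts are compared
net of the boundary click's events; and reconstructed event times are
placed at interval midpoints, because snapping them to the right edge of
each digitization interval shifts the whole distribution by half a grid
step and systematically distorts AIC-based family selection (the
generalized gamma then wins against the true generating family). The
reconstruction is validated through its contract: the KM curve re-estimated
from the pseudo-data must match the input within 0.02 everywhere.

`fit_parametric()` fits the six candidate families by maximum likelihood
(via `flexsurv`), `select_best()` takes the minimum AIC with ties broken
by parsimony and then a fixed family order. The generalized gamma uses the
(μ, σ, Q) parameterization, fixed and tested against its special cases
(Q = 1 is Weibull with shape 1/σ and scale e^μ). Both the staying
probability S(t)/S(t−1) and its complement are exposed; the engine
consumes the complement, since the modelled transitions are events.

## The synthetic fixture

A complete real-world parameter workbook for such an analysis is not
redistributable, so the package ships a synthetic stand-in
(`inst/extdata/default_params.yaml`) generated by `make_default_params()`
with a provenance manifest tagging every field. Headline constants of the modelled setting are exact: 5% discounting, WTP $38 223 and $50 964/QALY,
5-year AI course, drug durations 5/5/3 years, adherence scenario values
72%/54%, the 2022 exchange rate. Everything else was chosen once, before
any result-chasing, to be epidemiologically plausible and to reproduce the
modelled population's qualitative structure:

* the breast-cancer transition fits (log-normal, a family AIC selection
  commonly favours for these endpoints) were calibrated against overall
  survival reported for AI-treated early breast cancer in trial
  meta-analyses (≈95.8% at 5 years, ≈88.0% at 10 years), with recurrence
  hazards peaking in the first years;
* fracture-rate curves were set so the 10-year any-fracture incidence of
  an untreated AI cohort lands in the 12–15% range reported for such
  cohorts;
* costs sit at plausible 2022 Chinese price levels (branded-level
  alendronate $230/year, DXA $26, hip/vertebral/other acute care
  $5 500/$3 000/$1 500, long-term care $8 910/year), chosen so that
  prevention spends money rather than saving it, the cost structure
  reported for this setting.

PSA distributions follow health-economics convention where families are
unstated: beta for probabilities and utilities, gamma for costs and rates,
log-normal for relative risks, hyperparameters moment-matched to the point
estimate and range. Tail draws of a treatment RR may exceed 1; they are
accepted as genuine parameter uncertainty.

What the fixture does **not** emulate: the supplement's actual parameter
values, correlations between parameters, measurement error in DXA, drug
switching or sequential therapy, and country-specific cost heterogeneity.
Passing tests therefore demonstrate that the machinery is correct and that
the model reproduces the qualitative epidemiology, not that the shipped
numbers equal any particular real-world analysis; the acceptance script
reports what this fixture computes, and several of those values
legitimately differ from results obtained with real parameter sets (for
instance, screening
becomes cost-saving at the oldest starting ages and under the societal
perspective here).

## Monte Carlo design and problem sizes

The engine is vectorized over patients; because everyone enters at the
same age, all age-indexed lookups are per-cycle scalars. Random streams
are pre-generated per event channel (cancer, three fracture sites,
bedridden, death, adherence) and keyed by patient index, so changing only
the strategy leaves every pre-decision draw identical — incremental
QALY differences of order 0.01 would otherwise drown in Monte Carlo noise.
The cohort seed and stream seed are derived separately from the one
user-supplied seed so baseline T-scores and event draws never share
generator state.

Default sizes, chosen as the package's own accuracy/runtime trade-off:
100 000 first-order trials for base-case and scenario runs (ICER Monte
Carlo error well under the decision margins), 50 000 for the
oracle-equivalence test, 200 outer × 2 000 inner trials for the PSA in the
acceptance script and 40 × 2 000 in the test suite (second-order analyses conventionally use 1 000 outer iterations; the
CEAC here stabilizes to within a few percentage points at 200). The deterministic cohort-Markov oracle used in
testing disables heterogeneity (degenerate baseline BMD, memoryless
exponential cancer transitions, no history effects) so that expected
values have a closed matrix-iteration form; the microsimulation must match
it within three standard errors.

## Known limitations

* Screening measures the model T-score without error, so screening
  strategies are slightly flattered relative to reality.
* The repeat-fracture multiplier uses a single any-prior flag per site
  group rather than a full event-history model.
* Mortality after vertebral and other fractures carries no excess hazard;
  only hip fractures and distant metastasis do.
* The within-cycle event order (decision → cancer → fracture → death →
  BMD → accrual) is a documented convention; results at the margin depend
  on it, as in any discrete-cycle model without half-cycle correction.
* Scenario "prior fracture" both seeds the fracture-history flag and
  applies a configurable rate multiplier (default 1, so the effect flows
  through the repeat-fracture RRs; a separate multiplier would
  double-count by default).
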