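---
title: "Model and methods: cost-utility of sequential osteoporosis therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: cost-utility of sequential osteoporosis therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteocea)
```

## The decision problem

`osteocea` implements a Markov cohort cost-utility model for pharmacological
treatment of postmenopausal women at very high risk of fragility fracture
(femoral-neck BMD T-score at or below −2.5 with a prior fragility fracture,
baseline age 74). It compares a bone-forming sequence — one year of
romosozumab followed by four years of alendronate — against five years of
alendronate or risedronate alone, from a Canadian public-payer perspective
(societal in a scenario), over a lifetime horizon with 6-month cycles and
1.5%/year discounting of both costs and QALYs.

## Model structure

Seven health states are modelled: *at risk*, *hip fracture*, *post-hip*,
*clinical vertebral fracture*, *post-vertebral*, *"other" fragility
fracture* (non-hip, non-vertebral), and *dead*. Acute hip/vertebral states
last one year (two cycles) before moving to their post states; the "other"
state lasts one year and returns to *at risk*. States are ordered by
severity (hip > vertebral > other) and transitions are only allowed towards
equal-or-greater severity, so long-term consequences are carried by the
post-hip/post-vertebral states. Because this hierarchy undercounts
lower-severity events, a correction term adds, each cycle, the product of
higher-state occupancy and the lower-severity incidence to the fracture
ledger. Corrected events attract first-year costs and a one-year
disutility stream but, by construction, do not move occupancy; whether they
should also carry excess mortality is not identifiable from the model
description we follow, and they do not here.

Internally each post state carries a year-since-event tunnel clock at cycle
resolution (depth: the excess-mortality window, 8 years by default), so
mortality risk bands, subsequent-year costs and multipliers can depend on
time since the event. Re-fracture of the same type re-enters the acute
state and resets the clock; post-vertebral patients may still sustain hip
fractures (upward moves allowed).

### Transition mechanics

Within a cycle, fracture and death compete. Competing risks are resolved on
the rate scale: annual hazards are summed, converted to a per-cycle exit
probability `1 − exp(−R/2)`, and allocated proportionally to each cause.
This avoids order-of-application bias; the model description we follow is
silent on the within-cycle mechanism. There is no half-cycle correction in
the reference case (none is described for the source model); accruals use
start-of-cycle occupancy. The horizon runs to age 100 with fracture and
death transitions, then a mortality-only run-off until cohort extinction
(occupancy of living states below 10⁻⁶ per 1000) or age 110.

## Baseline risk

General-population fracture incidence is age-interpolated linearly between
table knots (linear extrapolation beyond, floored at zero) and scaled to
the very-high-risk cohort as

```
rate × RR_prior-fracture × RR_per-SD-BMD ^ T-score-gap
```

with defaults `RR_prior = 2.0`, per-SD RRs of 2.6 (hip), 1.8 (vertebral),
1.5 (other), and a BMD gap of 0.7 SD between the target cohort and
age-matched women. The prior-fracture mix (50% single, 50% multiple) is
represented by the single blended RR; fracture-history granularity beyond
that is out of scope.

## Treatment efficacy

Oral bisphosphonates carry constant relative risks versus placebo during
the 5-year treatment period (hip/vertebral/non-vertebral: alendronate
0.61/0.57/0.84, risedronate 0.73/0.61/0.78, each with published 95% CIs).
The sequence arm is time-dependent: per-cycle RRs versus the active
comparator (declining for hip, rising above 1 late for non-vertebral;
vertebral stepping 0.64 → 0.38 at cycle 3) are multiplied by the
comparator's constant RR versus placebo — the indirect composition
implemented by `compose_vs_placebo()`.

When per-subject time-to-event data are available (`simulate_trial()`
provides a synthetic stand-in), `derive_rr_schedule()` fits all six
parametric families (exponential, Weibull, Gompertz, log-logistic,
log-normal, generalized gamma) per arm and endpoint by maximum likelihood
with right censoring (via `flexsurv`), selects by AIC (BIC and
second-smallest-AIC are scenario options), and forms per-cycle conditional
incidences `(S(t₋₁) − S(t))/S(t₋₁)` whose ratio is the cycle RR. Fits are
per arm, unadjusted; degenerate fits (survival collapsing to zero inside
the treatment horizon) are excluded before selection, and selection ties
break by parsimony then family name for determinism.

### Offset of benefit

After treatment stops, the *risk reduction* `1 − RR` (not the RR itself)
declines linearly to zero over the offset period, equal to the 5-year
treatment duration by default:
`RR_eff(t) = 1 − (1 − RR_end)·max(0, 1 − t/offset)`. This applies
symmetrically when the end-of-treatment RR exceeds 1.

## Mortality

All-cause mortality comes from a female life table (annual probabilities,
age-interpolated). After hip and vertebral fractures, mortality is elevated
for 8 years (first-year band, then a "second and following years" band);
"other" fractures carry excess mortality in the first year only. Only 30%
of the observed excess is attributed to the fracture itself: the hazard is
multiplied by `1 + 0.3·(RR − 1)`. Attribution acts on the rate scale
(probabilities are converted to hazards, scaled, and converted back), which
keeps per-cycle probabilities in [0, 1]; whether the source model applied
RRs to rates or probabilities is not stated, and the rate scale is the
standard choice.

## Utilities and costs

QALYs accrue as occupancy × age-band utility × state multiplier × ½ year.
Multipliers: hip 0.55 (first year) / 0.86 (later), vertebral 0.68/0.85,
other 0.83 (first year only). All costs are 2020 CAD. Drug and monitoring
costs accrue to alive persons during the 10 treatment cycles (full
persistence is assumed): romosozumab $7881 + $310/year in year 1, oral
bisphosphonates $109 or $103 + $119/year. The published annual monitoring
sums are consumed verbatim ($310/$119) rather than re-derived from the
visit schedule, and likewise the $191 nurse-visit component, whose printed
value does not reproduce from the wage arithmetic; the printed sums are
treated as authoritative.

First-year fracture costs attach to events (direct and corrected) at
age-banded rates, spread over the event cycle and the next; subsequent-year
costs ($5171 hip, $235 vertebral, per year) attach to post-state occupancy.
Long-term care is a scalar side-stream rather than an extra state: 37% of
the surviving hip-branch occupancy accrues $184.96/day from the fracture
onward, additive to the subsequent-year medical cost (whether LTC replaces
or adds to that cost is not stated; additive is exposed as the
implementation and the entry proportion/price are sensitivity parameters).
The societal perspective adds productivity losses per event (hours off work
× wage) and $20 out-of-pocket per scheduled monitoring visit.

## Uncertainty analysis

The probabilistic analysis (5000 iterations in the reference configuration)
samples all parameters simultaneously and independently:

* relative risks — lognormal with the point estimate as the **median**
  (`log-sd = (ln upper − ln lower)/(2·1.96)` from the CI), the standard
  parameterisation for CI-derived RRs;
* survival-model coefficients — jointly normal on the estimation scale
  using the fit covariance, when the sequence schedule is fit-derived;
  otherwise a lognormal schedule factor per fracture type;
* utilities, multipliers, proportions — beta, moment-matched;
* costs — gamma, moment-matched;
* parameters without published uncertainty use ±25% of the point estimate
  as a 95% interval.

Baseline incidence and life tables are held fixed (population statistics).
The sequence arm's schedule is recomposed from the *same* comparator draw,
preserving the indirect-comparison correlation. CEACs report, per
willingness-to-pay value on a $0–200,000 grid (step $1,000), the fraction
of iterations in which each regimen maximises net monetary benefit, with
exact ties resolved towards the cheaper regimen.

One-way sensitivity uses CI bounds where published and ±25% otherwise, and
ranks parameters by the width of the resulting INMB interval at $50,000 per
QALY (the threshold the CEAC is quoted at; the tornado's threshold is
otherwise unspecified upstream). Scenario analyses cover the
romosozumab→risedronate sequence (efficacy equal to the alendronate
sequence while on romosozumab, then sequence RRs applied to risedronate's
RR versus placebo), societal perspective, 0%/3% discounting, BIC and
second-best-AIC survival selection, 1-year offset, excess-mortality
duration 5/10 years, attributable fraction 10%/50%, hip-only first-year
excess mortality, more severe (Canadian-style) disutility multipliers, and
the higher risedronate DR price ($617/year).

## Synthetic stand-in inputs

Several inputs of the source analysis exist only in unpublished appendices;
`make_epi_tables()` generates stand-ins with the statistical structure the
analysis assumes, and every run using them is watermarked:

* **Fracture incidence**: exponential age gradients at 5-year knots,
  anchored to Canadian figures — hip 0.30/1000 at 50 doubling every 7 years
  (≈3/1000 at 74, ≈10/1000 at 85, the shape of women's hip-fracture
  hospitalization rates), clinical vertebral 1.2/1000 doubling every 9
  years, other 10/1000 doubling every 22 years; together consistent with a
  crude rate of roughly 16 fragility fractures per 1000 persons 50+.
* **Mortality**: Gompertz hazard `0.0015·exp(0.105·(age − 50))`, matching
  the shape of the female life table (life expectancy ≈15 years at 74).
* **Post-fracture mortality RRs**: age-declining first-year RRs (hip 4.0 →
  1.6, vertebral 3.0 → 1.4 across 50→90+) and flat subsequent-year RRs
  (1.8/1.5), the qualitative pattern of Canadian cohort estimates.
* **Societal resource use**: wage $28.50/h and hours off work per fracture
  (120/80/40) are plausible placeholders.
* **Trial time-to-event data**: `simulate_trial()` draws Weibull event
  times per arm and endpoint with independent exponential dropout; default
  hazards are calibrated so the derived per-cycle RR schedules show the
  published pattern (hip ≈0.9 falling to ≈0.6; non-vertebral ≈0.7 rising
  past 1), at trial-typical incidence.

What passing tests therefore show: the *mechanics* — hierarchy, tunnels,
competing risks, accrual, discounting, composition, offset, sampling — are
correct against closed forms and a 200,000-subject microsimulation oracle,
and results have the published qualitative structure (the sequence dominates
both oral bisphosphonates; scenario directions match). What they cannot
show: agreement of absolute totals with the source analysis, which depends
on the unpublished appendix tables; with the stand-ins, lifetime fracture
totals land below the published count and incremental costs are more
favourable to the sequence than printed.

## Numerical choices and problem sizes

Cycle conversions use exact exponential forms; rate↔probability round-trips
are tested to 10⁻¹². Mass conservation holds to 10⁻⁹ per 1000 on every
cycle. Survival fits use years internally (cycle boundaries are exact
half-year multiples, so conditional incidences are unit-invariant). The
test suite exercises the microsimulation oracle at n = 200,000 (three Monte
Carlo SE agreement on all seven aggregated states), parameter recovery at
n = 50,000 (within 2%), Kaplan–Meier convergence at n = 50,000 (sup-norm
< 0.02), and a 500-iteration PSA; the acceptance script runs the full
5000-iteration PSA. These sizes were chosen so each property is measured
well inside its Monte Carlo noise floor.

## Limitations

No treatment non-persistence, no patient-level heterogeneity beyond the
validation oracle, no parameter correlation matrix (independent sampling),
no EVPI, no male or mixed-sex populations, no recency-of-fracture risk
stratification, and no currency machinery beyond accepting pre-inflated
2020 CAD. Stand-in tables are placeholders for unavailable inputs, not
reconstructions of them.
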