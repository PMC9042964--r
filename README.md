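# osteocea

Markov cohort cost-utility modelling of sequential osteoporosis therapy.

## What this is for

Health economists evaluating osteoporosis treatments need a transparent,
re-runnable implementation of the standard cohort framework used for these
decisions: a hierarchical fracture state-transition model with
time-dependent treatment effects, waning benefit after discontinuation,
post-fracture excess mortality, and full probabilistic uncertainty
analysis. `osteocea` implements that framework for the canonical
very-high-risk decision problem — one year of romosozumab sequenced to
alendronate versus alendronate or risedronate alone (5 years of treatment
in all arms) in postmenopausal women aged 74 with prior fragility fracture
— as a config-driven pipeline, so every input can be audited and replaced.

## The model in brief

Seven health states — at risk, hip, post-hip, clinical vertebral,
post-vertebral, "other" fracture, dead — on a 6-month cycle over a
lifetime horizon, with severity-ordered transitions
(hip > vertebral > other; moves only towards equal-or-greater severity)
and a ledger correction for undercounted lower-severity events. Fracture
risk is general-population incidence *r(a)* scaled to the cohort,

> r(a) · RR_prior-fracture · RR_per-SD^ΔT · RR_treatment(t),

where RR_treatment follows the regimen's per-cycle schedule during the 10
treatment cycles and then wanes linearly: RR(t) = 1 − (1 − RR_end)(1 −
t/t_offset). Post-fracture mortality applies 1 + f·(RR − 1) on the hazard
scale with attributable fraction f = 0.30 for up to 8 years. Costs (2020
CAD: drug/monitoring, age-banded first-year fracture, subsequent-year,
long-term care, societal) and QALYs (age-band utilities × fracture-state
multipliers) are discounted at 1.5%/year. Uncertainty: 5000-iteration PSA
(lognormal RRs from CIs, beta utilities/proportions, gamma costs, normal
survival coefficients) with CEACs; one-way INMB tornado (±25% or CI
bounds); fourteen scenario analyses. Unpublished appendix inputs
(incidence tables, life table, mortality RRs) ship as clearly watermarked
synthetic stand-ins; see `vignette("osteocea-methods")`.

## Worked example

```r
library(osteocea)

cfg <- make_reference_fixture()    # published tables + synthetic stand-ins
cfg
#> <osteo_config>
#>   population : mean age 74 | T-score -2.5
#>   regimens   : romo_aln, alendronate, risedronate
#>   perspective: payer | discount 0.015 (costs) 0.015 (QALYs)
#>   note       : epidemiological tables are synthetic stand-ins

res <- purrr::map(names(cfg$regimens), ~accrue_outcomes(cfg, .x))
compare_regimens(res)
#> <osteo_cea> fully incremental comparison (wtp = 50,000 CAD/QALY)
#>      regimen  comparator d_cost d_qalys icur   status  nmb
#>  alendronate risedronate  -3696   0.021   NA dominant 4744
#>     romo_aln alendronate   -519   0.096   NA dominant 5296
```

Reading this: per patient over a lifetime, the romosozumab→alendronate
sequence costs $519 less and yields 0.096 more QALYs than alendronate
alone (discounted), so it *dominates* — no ICUR is defined; the net
monetary benefit at $50,000/QALY is $5,296. Risedronate is dominated in
turn. Lifetime fracture burden drives this: `accrue_outcomes(cfg,
"romo_aln")` reports 2099 fractures per 1000 patients versus 2178 under
alendronate. Absolute magnitudes depend on the synthetic stand-in tables
(hence the watermark); the qualitative structure does not.

Probabilistic and scenario layers chain the same way:

```r
psa <- run_psa(cfg, n = 5000, seed = 1)
ceac_at(psa, "romo_aln", wtp = 50000)   # probability cost-effective
plot_ceac(psa)                          # ggplot CEAC
run_dsa(cfg) |> plot_tornado()          # one-way INMB tornado
run_scenarios(cfg) |> tidy()            # scenario table
```

A thin command-line wrapper (`inst/cli/osteocea-run.R`) drives
`run_model()` for deterministic/PSA/DSA/scenario runs against a YAML
configuration (`inst/extdata/reference_config.yaml` is a complete
example); outputs are tab-separated reports plus a run manifest with a
config digest and seeds.

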