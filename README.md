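# peanutCEA

Cost-effectiveness modeling of commercial peanut immunotherapy.

Two commercial peanut-allergy treatments — an epicutaneous patch (EPIT)
and an oral immunotherapy (POIT) — reduce the risk that an accidental
exposure triggers a reaction, but neither is curative, both carry their
own anaphylaxis risk, and their prices were unknown ahead of approval.
`peanutCEA` implements a decision-analytic Markov model with
individual-level microsimulation that asks, from a societal perspective
in 2018 US dollars: *at what annual price is each therapy worth it?*

The package is written for health-economics researchers and methods
students: every published model input ships as a validated, editable
parameter set, every analysis layer (state machine, engines, economics,
sensitivity machinery) is an exported, documented function, and a
deterministic cohort engine serves as a closed-form-checkable oracle for
the stochastic microsimulation.

## The model

Children with peanut allergy enter at age 4 and are followed in 1-year
cycles for 80 years through the states
*Allergic* → *OnTherapy (year 1 / maintenance)* → *Tolerant* / *Dead*.
Each year, a person may die (all-cause life-table mortality, or rare
food-allergy fatality at 3.25 per million person-years under age 20 and
1.81 per million above), suffer an accidental ED-level anaphylaxis
(1%/yr, 35% hospitalized), a mild accidental reaction (7%/yr, tracked),
or — while on therapy — a therapy-associated anaphylaxis (EPIT 3.4%/yr,
POIT 14.2%/yr). After the first therapy year a responder assessment
(biomarker or oral food challenge) plus first-year discontinuation
decides who continues.

Utilities: living with untreated peanut allergy is worth u = 0.91
(decrement d = 0.09), and each anaphylaxis episode costs a one-cycle
toll of 0.09. Therapy shrinks the decrement in proportion to the
protection buffer *b* (mg of peanut protein tolerated):

    d(b) = 0.09 x max(0, 1 - 0.057 * b / 100)

so EPIT (300 mg) lives at utility 0.93 and POIT (600 mg) at 0.94. Costs
and QALYs are discounted at 3%/yr; incremental value is judged by the
ICER ΔC/ΔE against a willingness-to-pay λ = $100,000/QALY, and the
value-based ceiling price solves ICER(price) = λ by bisection.

## Worked example

```r
library(peanutCEA)

# three-arm base case: 10,000 persons/arm, 80 annual cycles, paired
# (common-random-number) streams for sharp incremental contrasts
rep <- scenario_report("base", engine = "microsim",
                       n = 10000, seed = 2026, crn = TRUE)
rep$table
#>   strategy mean_cost sd_cost mean_qaly sd_qaly     nmb all_anaphylaxis_mean ...
#> 1     none    114606 11620.2   26.4377 2.65733 2529169               0.7281
#> 2     epit    171817 58188.4   26.6835 2.69259 2496530               1.9534
#> 3     poit    181632 62533.0   26.7112 2.69688 2489491               6.2845
#>   incremental_cost incremental_effectiveness   icer
#> 1               NA                        NA     NA
#> 2          57211.6                  0.245731 232822
#> 3          67026.2                  0.273482 245085

as.numeric(ceiling_price("epit"))   # 1599.426
as.numeric(ceiling_price("poit"))   # 1329.651
```

Reading the output: strict avoidance costs ≈ $115k over a discounted
lifetime and yields ≈ 26.44 QALYs with 0.73 anaphylaxis episodes per
person. At the caregiver willingness-to-pay price of $3,839/yr, both
therapies add cost faster than QALYs — ICERs of ≈ $233k (EPIT) and
≈ $245k (POIT) per QALY, far above the $100,000/QALY threshold — so
neither is cost-effective at that price. The bisection solver puts the
value-based ceiling prices at ≈ $1,599/yr (EPIT) and ≈ $1,330/yr (POIT).

Scenario presets (`scenario_presets()`) cover sustained
unresponsiveness grids, oral-food-challenge responder models,
front-loaded pricing, spontaneous tolerance, delayed benefit, and a
short horizon; `tornado()`, `utility_cost_surface()`,
`risk_reduction_sweep()` and `run_psa()` drive the sensitivity
machinery, e.g.:

```r
scenario_report("su75", engine = "cohort")$comparisons$epit$status
#> "dominant"   # with 75% sustained unresponsiveness, therapy wins outright
run_psa(spec = psa_spec(n_iter = 1000, seed = 1))$prop_therapy_cost_effective
#> 0            # at base prices no sampled parameter set is cost-effective
```

A command-line interface wraps the same functions
(`inst/cli/peanutcea run --preset base --seed 7 --out results/`); see
`?cea_cli`.

## Layout

- `R/inputs.R` — published parameter set, validation, config round trip
- `R/life_table.R` — Gompertz–Makeham synthetic life table + CSV loader
- `R/utility.R` — health-state utilities and the protection mapping
- `R/strategy.R` — arms as annual stochastic state machines
- `R/engines.R` — microsimulation and deterministic cohort oracle
- `R/economics.R` — ICER, NMB, dominance, ceiling-price bisection, frontier
- `R/sensitivity.R` — tornado, surfaces, risk grids, PSA, scenario presets
- `R/report.R` — summary tables, manifests, CLI
- `vignettes/peanut-immunotherapy-cea.Rmd` — methods and design notes
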