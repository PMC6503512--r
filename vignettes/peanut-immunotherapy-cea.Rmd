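---
title: "Methods: a Markov microsimulation for peanut immunotherapy cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov microsimulation for peanut immunotherapy cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peanutCEA)
```

## The decision problem

Commercial peanut immunotherapies — an epicutaneous patch (EPIT) and an
oral product (POIT) — raise the dose of peanut protein a child can
tolerate before reacting, at the price of therapy-associated adverse
events and an annual cost. `peanutCEA` models the lifetime trade-off
against the standard of care (strict avoidance with epinephrine
carriage) from a societal perspective: direct medical costs, food and
job-opportunity costs of living with the allergy, and the
quality-of-life value of feeling protected.

## States, cycles, and event model

A simulated person occupies one of five states — `Allergic`,
`OnTherapyY1`, `OnTherapyMaint`, `Tolerant`, `Dead` — and advances in
1-year cycles from age 4 for 80 cycles. `Dead` is absorbing; `Tolerant`
(sustained unresponsiveness or natural tolerance; ad libitum peanut,
no allergy costs, no reaction risk) is absorbing except for death.
Within a cycle events apply in a fixed order:

1. all-cause death, from the life table;
2. food-allergy fatality (allergic or on-therapy persons; 3.25 per
   million person-years below age 20, 1.81 above — ages under 5 use the
   younger band);
3. therapy-associated anaphylaxis (on therapy; EPIT 3.4%/yr, POIT
   14.2%/yr, every on-therapy year);
4. accidental ED-level anaphylaxis (1%/yr; 35% of ED visits
   hospitalized, as for therapy events);
5. mild accidental reaction (7%/yr; tracked, no cost or utility effect);
6. end of year 1: responder assessment and first-year discontinuation —
   continuation probability `p_responder x (1 - p_discontinue)`
   (e.g. EPIT biomarker: 0.495 x 0.983 = 0.4866); non-continuers revert
   to `Allergic` with no residual benefit;
7. end of year 4: sustained-unresponsiveness (SU) draw, when a scenario
   enables it;
8. spontaneous-tolerance hazard through age 20, when enabled.

Deaths come first so no post-mortem costs or utilities accrue; the
order is fixed for reproducibility. Hospitalization is drawn per ED
event, so the corresponding cost pairs follow the event flags exactly.

## Utilities and the protection mapping

Untreated allergy carries utility 0.91 (decrement 0.09); each ED-level
anaphylaxis event (accidental or therapy-associated) subtracts a
one-cycle toll of 0.09, additive within a cycle and floored at zero.
Treatment shrinks the decrement in proportion to the protection buffer
`b` in mg of peanut protein:

`d(b) = 0.09 * max(0, 1 - 0.057 * b / 100)`

The 5.7%-per-100 mg factor comes from scaling a 1.61-point
food-allergy-quality-of-life improvement observed in patients protected
to 800 mg against the questionnaire impairment of untreated allergy.
Derived decrements are rounded to two decimals before use
(`round_treated_to = 2`), which puts the treated states at exactly 0.93
(EPIT, 300 mg) and 0.94 (POIT, 600 mg); set `round_treated_to = NA`
for the raw mapping. Mild 7%/yr reactions carry no toll: with the toll
restricted to ED-level events, the untreated arm's expected toll is
`0.01 x 0.09` per surviving year, which is what the lifetime QALY
figures imply.

## Costs

All costs are 2018 USD. Living with the allergy costs $3,913/yr (the
seven components: pediatrician $100, allergist $149, nutritionist $17,
alternative care $25, groceries $310, job opportunity $2,597,
epinephrine $715). Acute care adds $691 per ED visit and $5,899 per
hospitalization. Therapy arms add the annual price (base $3,839/yr, the
caregiver willingness-to-pay figure; optionally a year-1/subsequent
schedule) and the year-1 assessment ($17 biomarker or $121 oral food
challenge). `Tolerant` persons accrue nothing. Costs and QALYs are both
discounted at 3%/yr with an end-of-cycle convention,
`(1.03)^-t`; end-of-cycle (rather than begin-of-cycle or half-cycle)
accrual is what reproduces lifetime QALY totals of the published
magnitude, and the same convention is applied to both axes so ratio
measures are unaffected.

## Engines

`run_microsim()` draws each person's life course with independent
Bernoulli events (vectorized across persons; a fixed seed gives a
bit-identical result). `run_cohort()` pushes exact occupancy masses
through the same single-cycle kernel (`cycle_transition()` in
expectation mode) and is the deterministic oracle: microsim means must
sit within sampling error of cohort means for every scenario preset,
which the test suite checks at n = 50,000 per arm with a
multiplicity-aware 4-standard-error bound per quantity (144 comparisons;
a literal 3-SE bound would reject a correct engine in roughly a third
of seed sequences by chance).

Uniform draws are taken as full-length vectors per event type per cycle
in every arm — including draws an arm does not use, such as the
responder split in the no-therapy arm. This keeps the uniform streams
of two runs with the same seed aligned, so `scenario_report(...,
crn = TRUE)` produces common-random-number (paired) arms: marginal
per-arm distributions are unchanged, but mortality and accidental-event
noise cancels out of incremental contrasts, which sharpens ICERs by an
order of magnitude at the same n. The default remains plain independent
streams (`crn = FALSE`).

Degenerate configurations are exact: with events and mortality switched
off the model is an annuity machine (QALYs `0.91 x 30.20076`, cost
`3913 x 30.20076` over 80 cycles), and the test suite pins both engines
to those closed forms.

## Economics

`icer()` works from unrounded means and flags dominance
(`dominated` = dearer and less effective; `dominant` = cheaper and more
effective); the ICER is undefined (NA) at zero QALY difference and
under dominance. `nmb()` is `wtp x QALY - cost`; cost-effectiveness at
a threshold is equivalent to the NMB ordering, and the tests assert
that identity algebraically. `ceiling_price()` bisects the annual
price over $0–$20,000 to a $1 tolerance until the ICER against
no-therapy equals the threshold; the price enters costs linearly, so
the root is unique, and the endpoint check reports both bracket ICERs
when the threshold is not straddled. The flat-benefit degenerate case
(no events, full response) has the closed form
`ceiling = wtp x annual utility gain`, used as the solver's oracle.

## Synthetic life table

The only external input the analysis needs is an all-cause life table.
The package ships a deterministic Gompertz–Makeham fixture,
`q(a) = 1 - exp(-(A + B e^{c a}))` with `A = 5e-4`, `B = 2e-5`,
`c = 0.095`, closed at age 110. The shape constant `c` matches the
classic ~9.5%/yr adult mortality doubling pattern; `B` was set once so
that survival from age 4 to 84 (0.53) sits in the 0.45–0.70 band of
recent US period tables. The fixture reproduces what matters to a
3%-discounted lifetime model — low child/young-adult mortality and
exponential old-age mortality — and deliberately omits infant
mortality detail, the young-adult accident hump, and sex/cohort
structure; `load_life_table()` accepts a real `age,qx` CSV for users
who want them. Passing tests on the fixture therefore show engine and
economics correctness, not calibration to any particular national
population.

## Scenario machinery and design decisions taken

Open design points were resolved as follows, once:

- **Therapy duration.** Responders stay on therapy (and keep paying)
  until death unless `max_therapy_years` says otherwise. Because both
  the incremental cost and the incremental QALY gain of a therapy arm
  accrue per on-therapy year, base-case ICERs and ceiling prices are
  nearly invariant to this choice; scenario results involving the
  absorbing `Tolerant` state (the SU grids) are not, and are the model
  outputs most sensitive to it.
- **Sustained unresponsiveness** converts maintenance occupancy to
  `Tolerant` at the end of therapy year 4 with the scenario
  probability (grids at 25/50/75%).
- **Spontaneous tolerance** ("22% through age 20") is read as a
  cumulative probability converted to a constant annual hazard,
  `1 - (1 - p)^(1/16)` from age 4. By default only untreated
  (`Allergic`) persons are eligible — year-1 non-responders become
  eligible the cycle after reverting. The
  `spontaneous_tolerance_on_therapy` switch extends eligibility to
  persons still on therapy at cycle end; outgrowing a food allergy is a
  host process that does not stop because a patch or capsule is being
  taken, and restricting the hazard to the comparator arm alone would
  credit natural tolerance only against therapy. The shipped
  `spontaneous_tolerance` preset (20% cumulative) uses the extended
  eligibility.
- **Adverse events short of anaphylaxis** (59.7% EPIT / 98.7% POIT)
  are carried as data but attach no cost or disutility: consequences
  are modeled only for anaphylaxis and discontinuation. They remain
  available for scenario extensions.
- **PSA coherence.** Triangular(low, base, high) distributions per
  declared range (a beta option exists for probabilities). The treated
  utility decrements are *derived* each iteration from the sampled
  base decrement through the protection mapping rather than sampled
  independently — independent draws could make the treated state
  better than the mapping allows and would answer a different
  question. Therapy prices and start age are held at base in the
  default PSA (price is the lever the ceiling-price and tornado
  analyses sweep); both can be added via `psa_spec(params = ...)`.
- **Tornado axes** for the treated decrements
  (`epit.d_treated`, `poit.d_treated`) sweep the published ranges
  through the scenario layer's treated-utility override, since the
  base values are derived quantities.

## Numerical choices

Bisection tolerance $1 on prices; occupancy masses are checked to
`1e-9` each cycle and corruption aborts with diagnostics; SDs use the
n−1 denominator; cohort mode reports no SDs. Config files are flat
dotted-path JSON written at 17 significant digits so a save/load round
trip is bit-exact. Reports are plain CSV (period decimals, no
thousands separators) written at 15 significant digits.

## Problem sizes used by the test suite

Unit and property tests run at small n (hundreds to 5,000 persons);
the oracle-equivalence check runs every preset at 50,000 persons per
arm; the full base-case reproduction uses the model's native 10,000
persons per arm; the PSA check runs 1,000 iterations on the cohort
engine. These sizes were chosen to make sampling error small relative
to the tested effects while keeping the whole suite in the
one-to-two-minute range on a single core.

## Limitations

The model inherits the source analysis's structure: one-year cycles,
no partial benefit for non-responders, no peanut-aversion or
compliance dynamics, no re-entry to therapy after discontinuation, and
a protection→utility mapping extrapolated linearly from a single
trial-derived point. The published microsimulation's effective therapy
duration is not recoverable from its printed outputs (its
therapy-anaphylaxis counts and incremental costs imply different
durations), so duration-sensitive scenario outputs — most visibly the
SU-grid ICERs — should be read as conditional on the
treat-until-death default rather than as exact reproductions. The
synthetic life table is a stylized stand-in, adequate under
discounting but not a substitute for real tables in undiscounted or
age-structured analyses.
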