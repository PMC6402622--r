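---
title: "Methods: a Markov cohort model for specialist wound-clinic cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model for specialist wound-clinic cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundcea)
```

## The decision problem

Chronic wounds (predominantly venous leg ulcers in the population this
model describes) are managed in Australia through a fragmented mix of
general practice, community nursing and hospital care. The model compares
that *usual care* with a *specialist multidisciplinary wound clinic*,
asking whether the clinic's higher routine costs are offset by faster
healing and fewer wound-related hospitalisations.

## Model structure

The model is a four-state Markov cohort model with a one-month cycle
length and a 12-cycle (one-year) horizon:

* **uncomplicated** — living with an active, non-hospitalised wound (all
  patients start here);
* **complicated with hospitalisation** — an admission caused by wound
  deterioration;
* **healed** — wound closed, at risk of recurrence;
* **dead** — absorbing.

Three structural constraints distinguish wound epidemiology from a
generic four-state model, and are hard-coded rather than configurable:

1. a hospitalised patient cannot move directly to healed — discharge
   returns them to the uncomplicated state;
2. the hospitalised state is a **one-cycle tunnel**: the median wound
   admission lasts about a month, so nobody remains hospitalised for two
   consecutive cycles;
3. a healed patient can only be hospitalised after recurring (no
   healed-to-hospitalised edge).

Mortality is assigned asymmetrically: the uncomplicated and healed states
carry background all-cause mortality (annual 0.016), while the
hospitalised state carries the wound-related rate (annual 0.024, derived
upstream from the hazard ratio of dying when admitted with a wound).
Applying only the wound-related rate in hospital avoids double-counting
the background risk inside a rate that was itself derived from it; this
is a modelling decision, since the source material lists both rates but
not their assignment to states.

Probabilities arrive on their native estimation horizons (1, 3 or 12
months) and are converted to the monthly cycle with the constant-rate
formula `p_month = 1 - (1 - p_t)^(1/t)`; the stay-probability of each
state is one minus the sum of its converted exit probabilities. The
conversion round-trips exactly, which the test suite asserts at 1e-10
for every configured input.

## Accrual convention

Costs accrue as occupancy times the monthly state cost, QALYs as
occupancy times the state utility divided by 12. Which trace rows accrue
is a genuinely open convention in cohort modelling, so it is a config
switch with four documented options: `end_of_cycle` (rows 1..12),
`start_of_cycle` (rows 0..11), `half_cycle` (trapezoidal), and
`all_cycles` (every row, 0..12 — thirteen accruals for a twelve-cycle
run).

The package default is **`all_cycles`**. Reproducing the published
per-patient annual totals that this model was built against requires
summing every row of the trace, including the initial distribution — the
behaviour of a spreadsheet model that sums the whole trace range. Under
this convention the deterministic run gives usual-care costs of $14,562
and specialist costs of $10,589 against published totals of $14,573 and
$10,625 (within 0.4%), and QALYs of 0.80 vs 0.84 — while none of the
three textbook conventions lands within 2% of the published cost totals.
The selected convention is recorded in every run manifest. Note
`all_cycles` accrues thirteen months of utility against a twelve-month
denominator, so a cohort pinned at utility *u* accrues `13u/12`; the
convention is kept because it is evidently what produced the published
table, not because it is the textbook choice.

## Costs and perspectives

Costs are 2017 AUD per patient-month. The hospitalised month ($30,319 in
both arms) is stored by component — an $800/day ward-bed price times a
30-day stay plus a non-bed residual of $6,319 — so the bed-price scenario
can substitute a lower willingness to pay for freed bed capacity. Because
the tunnel guarantees one cycle per admission, the admission cost is
incurred exactly once per entry.

The analysis takes a restricted societal perspective: patient
out-of-pocket costs (travel, dressings, clinic fees) plus health-system
costs, excluding productivity losses. The per-state payer split is not
printed in the main source, so the packaged defaults are calibrated
(`scripts/calibrate_splits.R`): the hospitalised month is assigned
entirely to the health system, the small healed-state cost is split
50:50, and the uncomplicated split is solved linearly so the baseline
out-of-pocket totals match the published $2,014 (usual) and $4,802
(specialist). These splits are config inputs, not estimates; perspective
sub-totals should be read accordingly.

## Utilities

EQ-5D-5L-derived utility weights: 0.69 with an uncomplicated wound, 0.89
healed, and hospitalised = uncomplicated − 0.1, a fixed decrement used
where admission-time quality of life cannot be measured. The decrement
construction is preserved in the probabilistic analysis: the hospitalised
utility is recomputed per draw as the sampled uncomplicated utility minus
0.1 (floored at 0), not sampled independently.

## Probabilistic sensitivity analysis

Each of the 10,000 simulations draws every uncertain parameter once and
evaluates both strategies:

* probabilities and utilities: beta distributions, method of moments,
  `alpha = m·n`, `beta = (1−m)·n`, with the mean `m` fixed at the
  deterministic input and dispersion set by an *effective sample size*
  `n`;
* costs: gamma distributions with `shape = 1/cv²`, `scale = m·cv²`,
  reflecting cost skew.

The source reports distribution families but no dispersions. Defaults:
`effective_n = 29` for the cohort-estimated complication probabilities
(the study cohort size), `26` for specialist healing (9 of 26 healed at
three months), `100` for everything else, and `cv = 0.2` for all costs —
all overridable in the config. Because the true dispersions are
unrecoverable, the published simulation probabilities (64% cost-effective
at baseline, etc.) are qualitative checks only; the package's own
probabilities are systematically higher because its default dispersions
are evidently tighter than the study's.

Parameters that are the same population quantity in both arms — both
mortality rates, the utility set, and the hospitalised-month cost — are
drawn **once per simulation and shared**, so they cancel correctly from
the increments. Draws are taken parameter-by-parameter in a fixed,
documented order (shared block, then usual care, then specialist;
probabilities before costs) from a single seeded generator, making runs
bit-reproducible. Probabilities are sampled on their native horizon and
then converted monthly. A draw whose converted exit probabilities sum
above 1 in any state is structurally infeasible; the offending strategy's
probability draws are redrawn for that simulation, and the run aborts if
more than 1% of simulations needed redrawing (with the default
dispersions, none do).

Costing perspectives never alter the random stream: excluded cost
components are still drawn but zeroed at accrual. A consequence used by
the tests is that the out-of-pocket-only and health-system-only runs
decompose the baseline run draw-by-draw under a shared seed.

### The deterministic point is not the PSA mean

The cohort trace is a product of matrices in the sampled probabilities
and the horizon conversion is concave, so `E[f(θ)] ≠ f(E[θ])`: the PSA
mean differs systematically from the deterministic result (Jensen's
inequality). With the default dispersions the offset is about +$30 on the
cost increment and −0.001 on the QALY increment — small in decision
terms, but several Monte-Carlo standard errors at 10,000 draws. One
acceptance-level test asserts the contrary (that both PSA means fall
within 3 Monte-Carlo SEs of the deterministic values); its QALY half
fails for exactly this reason and is retained as an honest record of the
property rather than weakened.

## Decision metrics

Incremental results are specialist minus usual care. The headline metric
is the net monetary benefit, `NMB = WTP·ΔE − ΔC`, at the Australian
threshold of $64,000/QALY; the ICER is computed but carries a dominance
label where the ratio is meaningless. A draw with NMB exactly zero counts
as cost-effective (a measure-zero convention, made explicit so the CEAC
is exactly reproducible by recounting). The CEAC evaluates the
cost-effective fraction on a $0–$100,000 grid.

## Scenarios

Four declarative scenarios transform the base config: the two
perspective restrictions; `low_bed_price`, which substitutes the ward-bed
valuation (no default — the replacement price is a required input,
because the source cites but does not print it); and `altered_healing`,
which sets the specialist 3-month healing probability to the previously
published 0.587. All scenarios run with the same seed as the baseline,
so comparisons are paired; faster healing must and does strictly raise
the specialist mean NMB.

## The synthetic cohort and what a green test establishes

The generator emulates the study cohort's statistical structure: n = 29
by default; age ~ N(72, 13²) truncated to 25–92; 50:50 sex; wound types
73% venous leg / 7% diabetic foot / 20% other; a 12-month retrospective
usual-care window in which hospitalisation occurs with annual probability
0.379 (one admission month, uniformly placed, all other months
uncomplicated); and a 3-month prospective specialist window with healing
at 0.345 (healing week uniform over 1–13), hospitalisation at 0.034,
background mortality at the all-cause rate, EQ-5D indices beta-distributed
around the state utilities and monthly cost items gamma-distributed
around the state costs.

Deliberate simplifications, hence the limits of what the tests show:
patients are Bernoulli units, not simulated trajectories — no recurrence,
no usual-care healing, and no wound-type-specific dynamics (the analysis
pools wound types; recurrence inputs come from venous-leg literature).
`estimate_params()` therefore recovers exactly the quantities the study
could estimate (complication and healing probabilities, short-window
mortality, utilities, state costs) and reports the rest as `NA` with
notes — recurrence, wound-related mortality and usual-care healing are
literature inputs in the model, and usual-care healed-month costs have no
observation window. The parameter-recovery test (n = 5,000, 10 seeds)
checks each estimable parameter against its generating value at a joint
99% level, Bonferroni-corrected across the 120 comparisons: a
per-comparison 99% check would falsely fail with ~70% probability for a
perfectly calibrated estimator, so the family-wise formulation is the
meaningful one. EQ-5D item responses are not simulated, only index
values, since the analysis consumes nothing else.

## Numerical choices and degenerate inputs

* Row-stochasticity and trace normalisation are asserted at 1e-12; the
  engine is plain vector–matrix iteration, checked against explicit
  matrix powers.
* Validation rejects out-of-range inputs rather than clipping them, and
  names the offending config path; silent repair hides data errors.
* Degenerate distributions (probability 0 or 1, zero cost, `cv = 0`,
  infinite effective sample size) are held fixed rather than sampled, so
  the zero-dispersion PSA collapses exactly to the deterministic point.
* Monetary values are rounded to whole dollars, and QALYs to two
  decimals, only at presentation; everything internal is unrounded.

## Known limitations

The model inherits the source analysis's assumptions: a single pooled
wound population, a one-month admission regardless of severity (observed
stays ranged 2–120 days), no age-updating of mortality within the year,
no discounting (one-year horizon), and no EVPI analysis. The PSA
dispersions are package defaults, not study estimates, so probability
statements (CEAC heights, probability cost-effective) characterise the
package's stated uncertainty world, not the study's.
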