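# woundcea

Cost-effectiveness analysis of specialist wound-care clinics versus usual
care for chronic wounds, for health economists and health-service
decision-makers evaluating wound-care service models.

Chronic wounds — mostly venous leg ulcers in elderly patients — are
expensive to treat and badly served by fragmented care. This package
implements a decision-analytic evaluation of a specialist
multidisciplinary wound clinic against usual care in the Australian
setting: a four-state Markov cohort model (uncomplicated wound,
complicated with hospitalisation, healed, dead) with monthly cycles over
a one-year horizon, probabilistic sensitivity analysis, the net monetary
benefit framework with cost-effectiveness acceptability curves, scenario
analyses, and a synthetic patient-cohort generator with a matching
parameter estimator so the whole pipeline can be exercised without
patient data.

## The model in brief

A cohort starts with an uncomplicated wound and moves monthly through a
row-stochastic transition matrix `P`; occupancy after `k` cycles is
`x_k = x_0 P^k`. Probabilities estimated on other horizons are converted
to monthly via `p = 1 − (1 − p_t)^{1/t}`. Structural constraints:
hospitalisation is a one-cycle tunnel (median stay ≈ 1 month), discharge
returns to the uncomplicated state (never directly to healed), healed
patients must recur before they can be hospitalised, and death is
absorbing.

Costs (2017 AUD per patient-month, split patient out-of-pocket vs health
system) and utility weights (EQ-5D-5L-derived: 0.69 uncomplicated, 0.59
hospitalised, 0.89 healed) accrue per cycle:

```
cost  = Σ_k Σ_s x_k(s) · c(s)          QALYs = Σ_k Σ_s x_k(s) · u(s) / 12
```

Decisions use the net monetary benefit at willingness to pay
λ = $64,000/QALY:

```
NMB = λ · ΔE − ΔC        (Δ = specialist − usual care)
```

The PSA draws probabilities and utilities from method-of-moments beta
distributions and costs from gamma distributions (means fixed at the
deterministic inputs), evaluates both strategies on shared draws of
common parameters, and summarises the 10,000 incremental pairs as a mean
NMB, a probability of cost-effectiveness, and a CEAC. See the methods
vignette (`vignettes/wound-clinic-cea-methods.Rmd`) for conventions,
calibrated defaults and limitations.

## Worked example

```r
library(woundcea)

cfg <- default_config()          # packaged model inputs
det <- run_deterministic(cfg)
det
#> Deterministic results (per patient, per year; total perspective, all_cycles accrual)
#>
#>                      Usual Care Specialist Clinics
#>  Out of pocket costs      2,013              4,800
#>  Health system costs     12,549              5,789
#>          Total costs     14,562             10,589
#>          Total QALYs       0.80               0.84
#>
#> Total incremental costs:  -3,973 AUD
#> Total incremental QALYs:  0.04
#> ICER: dominant
#> Net monetary benefit at WTP 64,000 AUD/QALY: 6,568 AUD
```

Specialist clinics cost about $3,973 less per patient per year and add
0.04 QALYs — they *dominate* usual care (cheaper and more effective), so
the ICER is a label rather than a ratio and the NMB at $64,000/QALY is
positive.

```r
psa <- run_psa(cfg, seed = 1)    # 10,000 Monte-Carlo simulations
psa
#> PSA: 10000 simulations (seed 1, total perspective, all_cycles accrual)
#>   mean incremental cost:       -3942 AUD
#>   mean incremental QALYs:     0.0394
#>   mean NMB at WTP 64000:         6461 AUD
#>   probability cost-effective: 89.6%

plot(ceac(psa))                  # acceptability curve, $0-$100k/QALY
```

Scenario analyses (perspective restrictions, a lower ward-bed valuation,
a literature healing rate) run paired on one seed:

```r
run_all_scenarios(cfg, seed = 1, bed_day_price = 300)
```

Synthetic cohorts close the loop between patient-level data and model
inputs:

```r
coh <- generate_cohort(29, seed = 7)   # study-sized cohort
estimate_params(coh)                   # estimator behind the model inputs
```

A thin CLI over the same functions is installed at
`inst/cli/woundcea.R` (`run`, `scenarios`, `synth` subcommands).

## Acceptance script

`scripts/acceptance.R` recomputes the headline deterministic results
from scratch — it loads the packaged configuration, builds both
transition matrices, runs the 12-cycle cohort model and the full
analysis bundle, and writes the per-patient annual totals (both
strategies' costs and QALYs, and the net monetary benefit at
$64,000/QALY) as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

`scripts/calibrate_splits.R` documents how the packaged out-of-pocket /
health-system cost splits were derived.
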