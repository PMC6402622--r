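#!/usr/bin/env Rscript
# Calibrates the per-state out-of-pocket / health-system cost splits that
# ship in the packaged default configuration.
#
# The per-state monthly TOTals are fixed inputs (usual care $521 / $30,319
# / $68; specialist $1,169 / $30,319 / $84) but their payer decomposition
# is not printed in the main text. This script chooses the packaged
# defaults: the hospitalised month is carried entirely by the health
# system, the healed-state cost is split 50:50, and the uncomplicated
# split is then solved linearly so the baseline run's out-of-pocket totals
# match the published per-patient figures ($2,014 usual care, $4,802
# specialist) under the default accrual convention.
#
# Usage: Rscript scripts/calibrate_splits.R

suppressPackageStartupMessages(library(woundcea))

cfg <- default_config()
target_oop <- c(usual_care = 2014, specialist_clinic = 4802)
state_total <- list(
  usual_care = c(uncomplicated = 521, healed = 68),
  specialist_clinic = c(uncomplicated = 1169, healed = 84))

for (snm in names(target_oop)) {
  sp <- strategy_params_from_config(cfg, snm)
  tr <- run_cohort(build_transition_matrix(sp), cfg$settings$cycles)
  occ <- colSums(tr)  # all_cycles convention: every trace row accrues
  healed_oop <- state_total[[snm]][["healed"]] / 2
  unc_oop <- (target_oop[[snm]] - occ[["healed"]] * healed_oop) /
    occ[["uncomplicated"]]
  cat(sprintf("%s:\n", snm))
  cat(sprintf("  occupancy-months: uncomplicated %.4f, healed %.4f\n",
              occ[["uncomplicated"]], occ[["healed"]]))
  cat(sprintf("  healed split: %.0f oop / %.0f health system\n",
              healed_oop, state_total[[snm]][["healed"]] - healed_oop))
  cat(sprintf("  uncomplicated oop (solved): %.2f -> packaged %.0f / %.0f\n",
              unc_oop, round(unc_oop),
              state_total[[snm]][["uncomplicated"]] - round(unc_oop)))
}
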