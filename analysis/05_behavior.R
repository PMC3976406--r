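#!/usr/bin/env Rscript
# Behavioural analysis of the simulated VAS ratings: pool the tiredness
# and reversed restedness scales, z-standardise per subject, and run the
# 2 x 2 (day x time-of-day) exhaustion ANOVA with Bonferroni-adjusted
# simple effects of day at each time point.
#
# Usage: Rscript analysis/05_behavior.R [seed]

library(rsnica)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
out <- file.path("results", sprintf("study_seed%d", seed))
dir.create(out, recursive = TRUE, showWarnings = FALSE)

study <- simulate_reference_study(seed = seed, include_wdt2 = TRUE,
                                  n_vol = 120)
tab <- prepare_exhaustion_table(study$behavior)
got <- exhaustion_anova(tab)

message("Two-way exhaustion ANOVA (z-standardised pooled VAS):")
print(got$anova, digits = 4)
message("Simple effects of day per time point (Bonferroni x2):")
print(got$simple_effects, digits = 4)

utils::write.csv(got$anova, file.path(out, "exhaustion_anova.csv"),
                 row.names = FALSE)
utils::write.csv(got$simple_effects,
                 file.path(out, "exhaustion_simple_effects.csv"),
                 row.names = FALSE)
message("Wrote behavioural ANOVA tables under ", out)
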