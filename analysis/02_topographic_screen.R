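#!/usr/bin/env Rscript
# Re-derive the study group labels from the simulated eyes' axial power
# maps: I-S >= 1.4 D, central power >= 47.2 D, KISA >= 100%, plus slit-lamp
# status.  Checks the group-construction property that every fellow eye
# (topographically normal by definition) screens negative.
#
# Reads:  the cohort simulated by 01_simulate_cohort.R (regenerated here
#         from the same seed so each script stands alone)
# Writes: results/screening.csv

library(kcmaps)

seed <- as.integer(Sys.getenv("KCMAPS_SEED", "1"))
dir.create("results", showWarnings = FALSE)

eyes <- generate_cohort(cohort_spec(52, 22, seed = seed, rho = 0.5))
screening <- screen_cohort(eyes)
write.csv(screening, "results/screening.csv", row.names = FALSE)

tab <- table(truth = screening$group_true, label = screening$label)
print(tab)
fellow_ok <- all(screening$label[screening$group_true == "fellow"] == "fellow")
cat(sprintf("All fellow eyes screen non-keratoconic: %s\n", fellow_ok))
cat(sprintf("I-S >= 1.4 in %.0f%% of keratoconic vs %.0f%% of normal eyes\n",
            100 * mean(screening$flag_IS[screening$group_true == "keratoconic"]),
            100 * mean(screening$flag_IS[screening$group_true == "normal"])))
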