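#!/usr/bin/env Rscript

# Step 1 — synthesize the study cohort.
#
# Generates 534 heart-failure encounters with planted risk-trajectory
# archetypes (decreasing / high / moderate / low at the reported mix),
# ~20% 30-day readmission prevalence, 1-14 day stays with a 4-day median,
# and per-lab missingness, then writes the cohort CSVs plus the held-back
# ground truth to results/cohort/.

suppressMessages(library(hftraj))

cfg <- generator_config(n_encounters = 534, seed = 20130901)
gen <- generate_cohort(cfg)
paths <- write_cohort(gen$cohort, "results/cohort", truth = gen$truth)

y <- gen$cohort$outcomes$readmitted_30d
days <- sum(ceiling(as.numeric(difftime(gen$cohort$static$discharge_time,
                                        gen$cohort$static$admission_time,
                                        units = "days"))))
cat("cohort:", nrow(gen$cohort$static), "encounters,", days,
    "patient days\n")
cat("readmitted:", format_fraction(sum(y), length(y)), "\n")
print(table(gen$truth$archetype))
cat("files:", paste(basename(paths), collapse = ", "), "\n")
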