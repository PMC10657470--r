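#!/usr/bin/env Rscript
# Generate the synthetic study cohort used by the downstream analyses:
# 51 subjects, 200 species (5 planted effectors), stratified arginine
# pathways, covariates and APNS outcomes at weeks 2/8/12.
#
# Writes: results/synthetic_{species,pw_pathways}.tsv,
#         results/synthetic_{cohort,outcomes}.csv, results/truth.csv

library(gutapns)

cfg <- sim_config(seed = 0)
study <- simulate_study(cfg)
dir.create("results", showWarnings = FALSE)

write_tables(list(synthetic = study$species, synthetic_pw = study$pathways),
             "results")
write.csv(study$cohort, "results/synthetic_cohort.csv", row.names = FALSE)
write.csv(study$panel, "results/synthetic_outcomes.csv", row.names = FALSE)
write.csv(data.frame(effector = study$truth$effectors,
                     effect_size = study$truth$effect_sizes),
          "results/truth.csv", row.names = FALSE)

cat("Cohort:", nrow(study$cohort), "subjects,",
    length(study$species$species), "species,",
    nrow(study$panel), "outcome observations\n")
cat("Planted effectors (coefficient per arcsine-sqrt unit):\n")
print(study$truth$effect_sizes)
cat("Zero fraction of the abundance table:",
    round(mean(study$species$values == 0), 3), "\n")
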