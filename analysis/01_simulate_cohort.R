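#!/usr/bin/env Rscript

# Stage 1 — simulate the synthetic study cohort.
#
# Generates the default 200-patient cohort (bilaterally symmetric
# 10-territory atlas, unilateral infarct + hypoperfusion lesions, five
# parametric maps with planted lesion/severity/HT effects,
# published-prevalence clinical covariates) and writes it under scratch/cohort/ as NIfTI + CSV
# (volumes are bulky, so they live outside results/), so later stages —
# and any outside tool — can work from files.

suppressPackageStartupMessages(library(htradiomics))

out_dir <- "scratch/cohort"
cfg <- cohort_config(n_patients = 200L, seed = 20240100L)
cohort <- simulate_cohort(cfg)
manifest <- write_cohort(cohort, out_dir, overwrite = TRUE)

cat("Simulated", length(cohort$patients), "patients (",
    sum(cohort$labels), "HT-positive ) on a",
    paste(cfg$grid_shape, collapse = "x"), "grid\n")
cat("Lesion territories drawn from:", paste(cfg$lesion_territories, collapse = ", "), "\n")
cat("Cohort written to", out_dir, "( config hash", manifest$config_hash, ")\n")
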