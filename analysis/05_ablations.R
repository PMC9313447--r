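#!/usr/bin/env Rscript

# Stage 5 — ablation studies.
#
# (a) five single-sequence models (features from one parametric map at a
#     time, 1080 candidates each) and (b) the feature-count sweep
#     (k = 5..20 top-ranked All-ROIs features), both evaluated on the
#     same held-out validation cohort as stage 4.

suppressPackageStartupMessages(library(htradiomics))

cfg <- study_config(seed = 20240100L,
                    conditions = c("single_sequence", "sweep"))
res <- run_study(cfg, out_dir = "results/study", quiet = FALSE)

cat("\nSingle-sequence models:\n")
print(format_metric_table(res$suite$single_sequence_table), row.names = FALSE)
cat("\nFeature-count sweep (k = 5..20):\n")
print(format_metric_table(res$suite$sweep_table), row.names = FALSE)

best <- res$suite$sweep_table$n_features[which.max(res$suite$sweep_table$AUC)]
cat("\nBest validation AUC at k =", best, "features\n")
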