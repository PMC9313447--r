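#!/usr/bin/env Rscript

# Stage 3 — LASSO feature ranking and clinical factor screening.
#
# On the primary (training) cohort only: rank the 5400 radiomics columns
# by LASSO coefficient magnitude (all-ROIs and abnormal-ROIs-only), screen
# the 16 clinical factors by exact tests + univariate AUC, and run the
# second-stage fusion selection. Writes results/selections.json and a
# coefficient table for bar plots.

suppressPackageStartupMessages(library(htradiomics))

ft <- read_feature_table("results/features.csv")
cfg <- cohort_config(n_patients = 200L, seed = 20240100L)
cohort <- simulate_cohort(cfg)

sp <- split_cohort(ft$labels, split_spec(seed = 20240200L))
Xp <- ft$features[sp$primary, , drop = FALSE]
yp <- ft$labels[sp$primary]

sel_all <- lasso_rank(Xp, yp, lasso_spec(top_k = 14L))
sel_abn <- lasso_rank(Xp[, grep("_abnormal_", colnames(Xp)), drop = FALSE],
                      yp, lasso_spec(top_k = 14L), stage = "abnormal-only")
screen <- screen_clinical(cohort$clinical[sp$primary, , drop = FALSE], yp)
fusion <- fuse_and_reselect(sel_all, screen$selected, Xp,
                            cohort$clinical[sp$primary, , drop = FALSE], yp)

cat("All-ROIs selection (", sum(grepl("_normal_", sel_all$names)),
    "features from normal-side ROIs of", length(sel_all$names), "):\n")
print(round(sel_all$coefficients, 4))
cat("\nClinical screening selected:", paste(screen$selected, collapse = " + "), "\n")
print(screen$table, digits = 3)
cat("\nFusion reselection kept", length(fusion$names), "features\n")

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(
  list(all = sel_all[c("names", "coefficients")],
       abnormal = sel_abn[c("names", "coefficients")],
       fusion = fusion[c("names", "coefficients")],
       clinical_pair = screen$selected),
  "results/selections.json", auto_unbox = TRUE, digits = NA, pretty = TRUE
)
coef_tab <- rbind(
  data.frame(stage = "all", feature = sel_all$names, coefficient = sel_all$coefficients),
  data.frame(stage = "abnormal", feature = sel_abn$names, coefficient = sel_abn$coefficients),
  data.frame(stage = "fusion", feature = fusion$names, coefficient = fusion$coefficients)
)
data.table::fwrite(coef_tab, "results/selection_coefficients.csv")
cat("Selections written to results/selections.json\n")
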