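#' Validation AUCs of selected models on one simulated cohort
#'
#' Convenience runner for calibration experiments: simulates a cohort from
#' `config` (with its seed replaced by `seed`), extracts the
#' multiparametric feature table, and runs the model-comparison condition
#' for the requested models, returning their validation-cohort mean AUCs.
#' Used for the null-calibration, signal-recovery and All-vs-Abnormal
#' ordering properties.
#'
#' @param config a [cohort_config()].
#' @param seed cohort/split/suite seed for this replicate.
#' @param models model conditions (subset of clinical/abnormal/all/
#'   combined).
#' @return named numeric vector of validation mean AUCs.
#' @export
cohort_model_aucs <- function(config, seed, models = c("clinical", "abnormal", "all", "combined")) {
  config$seed <- as.integer(seed)
  cohort <- simulate_cohort(config)
  ft <- extract_cohort(cohort)
  suite <- run_model_suite(
    ft, cohort$clinical,
    split = split_spec(seed = derive_seed(seed, 5L)),
    conditions = "models", models = models,
    seed = derive_seed(seed, 6L)
  )
  setNames(suite$models_table$AUC, suite$models_table$Model)
}
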