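#' Full-study configuration
#'
#' One object configures the whole experiment: cohort generation, feature
#' extraction, selection, split, rebalancing, random forest and which
#' conditions to run. A single global seed fans out to per-stage seeds by
#' fixed offsets (see [derive_seed()]). The default study simulates 200
#' patients with the default effect sizes, large enough for stable model
#' comparison at desk scale.
#'
#' @param cohort a [cohort_config()] (default: 200 patients).
#' @param disc a [disc_spec()].
#' @param glcm a [glcm_spec()].
#' @param lasso a [lasso_spec()].
#' @param split a [split_spec()].
#' @param smote a [smote_spec()].
#' @param rf an [rf_spec()].
#' @param conditions which suite conditions to run.
#' @param models model conditions for the comparison table.
#' @param published_order SMOTE before folding?
#' @param seed global seed; overrides the nested cohort/split seeds.
#' @return object of class `study_config`.
#' @export
study_config <- function(cohort = cohort_config(n_patients = 200L),
                         disc = disc_spec(), glcm = glcm_spec(),
                         lasso = lasso_spec(), split = split_spec(),
                         smote = smote_spec(), rf = rf_spec(),
                         conditions = c("models", "single_sequence", "sweep", "roc"),
                         models = c("clinical", "abnormal", "all", "combined"),
                         published_order = FALSE, seed = 1L) {
  cohort$seed <- derive_seed(seed, 1000L)
  split$seed <- derive_seed(seed, 2000L)
  structure(
    list(cohort = cohort, disc = disc, glcm = glcm, lasso = lasso,
         split = split, smote = smote, rf = rf, conditions = conditions,
         models = models, published_order = published_order, seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Run the full synthetic study
#'
#' Executes simulate -> ROI construction -> feature extraction -> selection
#' -> training -> evaluation in order and returns the suite results plus a
#' run manifest. When `out_dir` is given, stage outputs (feature CSV,
#' metric CSVs, selection JSON, manifest) are written there, and the
#' extracted feature table is cached keyed on the configuration hash:
#' re-running with an unchanged configuration reloads the cache, changing
#' the configuration invalidates it.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory.
#' @param quiet suppress stage messages?
#' @return object of class `study_result`: list with `suite`
#'   (`model_suite`), `feature_table`, `clinical`, `manifest`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (!quiet) message(...)
  hash <- config_hash(list(
    cohort = config$cohort[setdiff(names(config$cohort), "clinical_prevalences")],
    prev = unname(as.matrix(config$cohort$clinical_prevalences[, c("ht", "no_ht")])),
    disc = unclass(config$disc), glcm = unclass(config$glcm), seed = config$seed
  ))

  cache_path <- if (!is.null(out_dir)) file.path(out_dir, sprintf("features_%s.csv", hash))
  cohort <- NULL
  if (!is.null(cache_path) && file.exists(cache_path)) {
    say("stage extract: reusing cached feature table (", basename(cache_path), ")")
    ft <- read_feature_table(cache_path)
    cohort <- simulate_cohort(config$cohort)  # clinical table must match the cache
  } else {
    say("stage simulate: ", config$cohort$n_patients, " patients")
    cohort <- simulate_cohort(config$cohort)
    say("stage extract: ", length(cohort$patients), " patients x ",
        length(.sequences()) * 20 * 54, " features")
    ft <- extract_cohort(cohort, disc = config$disc, glcm = config$glcm)
    if (!is.null(cache_path)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_feature_table(ft, cache_path)
    }
  }

  say("stage select/train/evaluate: conditions ",
      paste(config$conditions, collapse = ", "))
  suite <- run_model_suite(
    ft, cohort$clinical, lasso = config$lasso, split = config$split,
    smote = config$smote, rf = config$rf, conditions = config$conditions,
    models = config$models, published_order = config$published_order,
    seed = derive_seed(config$seed, 3000L)
  )

  manifest <- list(
    config_hash = hash, seed = config$seed,
    n_patients = length(cohort$patients),
    n_features = ncol(ft$features),
    conditions = config$conditions,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(suite$models_table)) {
      data.table::fwrite(suite$models_table, file.path(out_dir, "models_table.csv"))
    }
    if (!is.null(suite$single_sequence_table)) {
      data.table::fwrite(suite$single_sequence_table,
                         file.path(out_dir, "single_sequence_table.csv"))
    }
    if (!is.null(suite$sweep_table)) {
      data.table::fwrite(suite$sweep_table, file.path(out_dir, "sweep_table.csv"))
    }
    if (!is.null(suite$roc)) {
      for (sd_name in names(suite$roc)) {
        for (m in names(suite$roc[[sd_name]])) {
          data.table::fwrite(suite$roc[[sd_name]][[m]],
                             file.path(out_dir, sprintf("roc_%s_%s.csv", sd_name, m)))
        }
      }
    }
    if (!is.null(suite$selections$all)) {
      jsonlite::write_json(
        lapply(suite$selections[c("all", "abnormal", "fusion")], function(s) {
          list(stage = s$stage, names = s$names, coefficients = s$coefficients)
        }),
        file.path(out_dir, "selections.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
    }
    manifest$files <- list.files(out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  structure(list(suite = suite, feature_table = ft, clinical = cohort$clinical,
                 manifest = manifest),
            class = "study_result")
}

#' Human-readable study report
#'
#' Markdown summary with the publication-style "mean ± std" tables and
#' the selection coefficient listing (bar-chart-ready).
#'
#' @param result a `study_result` (or `model_suite`).
#' @return character vector of Markdown lines (invisibly printed with
#'   `cat`).
#' @export
report_study <- function(result) {
  suite <- if (inherits(result, "study_result")) result$suite else result
  done <- intersect(c("models_table", "single_sequence_table", "sweep_table"),
                    names(suite))
  done <- done[!vapply(suite[done], is.null, TRUE)]
  if (length(done) == 0) stopf("no completed conditions to report")
  lines <- character(0)
  fmt_tab <- function(tab) {
    f <- format_metric_table(tab)
    c(paste(names(f), collapse = " | "),
      paste(rep("---", ncol(f)), collapse = " | "),
      apply(f, 1, paste, collapse = " | "))
  }
  if ("models_table" %in% done) {
    lines <- c(lines, "## Model comparison (validation cohort)", "",
               fmt_tab(suite$models_table), "")
  }
  if ("single_sequence_table" %in% done) {
    lines <- c(lines, "## Single-sequence models", "",
               fmt_tab(suite$single_sequence_table), "")
  }
  if ("sweep_table" %in% done) {
    lines <- c(lines, "## Feature-count sweep", "",
               fmt_tab(suite$sweep_table), "")
  }
  if (!is.null(suite$selections$all)) {
    lines <- c(lines, "## Selected all-ROIs features (LASSO coefficients)", "",
               sprintf("- %s: %.4g", names(suite$selections$all$coefficients),
                       suite$selections$all$coefficients), "")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
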