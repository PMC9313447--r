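#' Assemble the design matrix of one model condition
#'
#' @param condition one of `"clinical"`, `"abnormal"`, `"all"`,
#'   `"combined"`.
#' @param ft `feature_table` (radiomics columns).
#' @param clinical clinical data.frame.
#' @param selections list with `all`, `abnormal`, `fusion`
#'   (`selection_result`s) and `screen` (`clinical_screen`).
#' @return numeric matrix with named columns.
#' @keywords internal
.model_matrix <- function(condition, ft, clinical, selections) {
  feats <- if (inherits(ft, "feature_table")) ft$features else ft
  switch(condition,
    clinical = as.matrix(clinical),
    abnormal = feats[, selections$abnormal$names, drop = FALSE],
    all = feats[, selections$all$names, drop = FALSE],
    combined = {
      nm <- selections$fusion$names
      rad <- intersect(nm, colnames(feats))
      cli <- intersect(nm, names(clinical))
      cbind(feats[, rad, drop = FALSE], as.matrix(clinical[, cli, drop = FALSE]))
    },
    stopf("unknown model condition '%s'", condition)
  )
}

#' Train and evaluate the full model comparison suite
#'
#' Reproduces the study design on one feature table: the cohort is split
#' into primary and validation sets; feature selections (all-ROIs LASSO,
#' abnormal-ROIs-only LASSO, clinical screening, fusion reselection) are
#' computed on the primary cohort only; each requested condition is
#' trained with SMOTE + five-fold cross-validated random forests on the
#' primary cohort and evaluated on the held-out validation cohort.
#'
#' Conditions: the four-model comparison (clinical / Abnormal-ROIs /
#' All-ROIs / combined), the five single-sequence models, the
#' feature-count sweep (k = 5..20 over the top-ranked all-ROIs features)
#' and ROC curves for the three robustness seeds (100, 200, 300).
#'
#' @param ft a `feature_table` with the multiparametric radiomics columns.
#' @param clinical data.frame of the 16 clinical factors (same row order).
#' @param lasso a [lasso_spec()] (`top_k` = 14 default).
#' @param split a [split_spec()].
#' @param smote a [smote_spec()].
#' @param rf an [rf_spec()].
#' @param conditions subset of `c("models", "single_sequence", "sweep",
#'   "roc")`.
#' @param models model conditions for the comparison table.
#' @param sweep_k feature counts for the sweep.
#' @param roc_seeds robustness seeds for the ROC curves.
#' @param published_order SMOTE before folding (published order)?
#' @param seed suite seed (fold assignment, SMOTE draws).
#' @return object of class `model_suite`: list with `models_table`,
#'   `single_sequence_table`, `sweep_table`, `roc`, `selections`,
#'   `split`, `evaluations`.
#' @export
run_model_suite <- function(ft, clinical,
                            lasso = lasso_spec(),
                            split = split_spec(),
                            smote = smote_spec(),
                            rf = rf_spec(),
                            conditions = c("models", "single_sequence", "sweep", "roc"),
                            models = c("clinical", "abnormal", "all", "combined"),
                            sweep_k = 5:20,
                            roc_seeds = c(100L, 200L, 300L),
                            published_order = FALSE,
                            seed = 1L) {
  stopifnot(inherits(ft, "feature_table"))
  conditions <- match.arg(conditions, several.ok = TRUE)
  y <- ft$labels
  sp <- split_cohort(y, split)
  prim <- sp$primary
  val <- sp$validation
  feats <- ft$features

  # ---- selections on the primary cohort only (no validation leakage)
  abnormal_cols <- grep("_abnormal_", colnames(feats), value = TRUE)
  need_rad <- any(models %in% c("abnormal", "all", "combined")) ||
    any(c("sweep", "roc") %in% conditions)
  selections <- list()
  if (need_rad) {
    lasso20 <- lasso
    lasso20$top_k <- max(lasso$top_k, max(sweep_k))
    sel_ranked <- lasso_rank(feats[prim, , drop = FALSE], y[prim], lasso20,
                             stage = "radiomics")
    sel_all <- sel_ranked
    sel_all$names <- head(sel_ranked$names, lasso$top_k)
    sel_all$coefficients <- head(sel_ranked$coefficients, lasso$top_k)
    sel_abn <- lasso_rank(feats[prim, abnormal_cols, drop = FALSE], y[prim],
                          lasso, stage = "abnormal-only")
    stopifnot(all(grepl("_abnormal_", sel_abn$names)))  # condition guard
    screen <- screen_clinical(clinical[prim, , drop = FALSE], y[prim])
    fusion <- fuse_and_reselect(sel_all, screen$selected, feats[prim, , drop = FALSE],
                                clinical[prim, , drop = FALSE], y[prim], lasso)
    selections <- list(all = sel_all, abnormal = sel_abn, screen = screen,
                       fusion = fusion, ranked = sel_ranked)
  } else if ("clinical" %in% models) {
    selections <- list(screen = screen_clinical(clinical[prim, , drop = FALSE], y[prim]))
  }

  fit_eval <- function(x, smote_ = smote, rf_ = rf, seed_ = seed) {
    cv <- crossval_train(x[prim, , drop = FALSE], y[prim], smote_, rf_,
                         published_order = published_order, seed = seed_)
    evaluate_models(cv, x[val, , drop = FALSE], y[val])
  }

  out <- list(selections = selections, split = sp, seed = seed)

  if ("models" %in% conditions) {
    evs <- lapply(models, function(m) {
      fit_eval(.model_matrix(m, ft, clinical, selections))
    })
    names(evs) <- models
    out$evaluations <- evs
    out$models_table <- .metric_table(evs, label_col = "Model")
  }

  if ("single_sequence" %in% conditions) {
    seqs <- ft$sequences
    rows <- lapply(seqs, function(s) {
      cols <- grep(paste0("^", s, "_"), colnames(feats), value = TRUE)
      sel <- lasso_rank(feats[prim, cols, drop = FALSE], y[prim], lasso,
                        stage = paste0("single-", s))
      keep <- sel$names[sel$coefficients != 0]
      if (length(keep) == 0) keep <- sel$names[1]
      ev <- fit_eval(feats[, keep, drop = FALSE])
      list(ev = ev, n_features = length(keep))
    })
    names(rows) <- seqs
    tab <- .metric_table(lapply(rows, `[[`, "ev"), label_col = "Sequence")
    tab$n_features <- vapply(rows, `[[`, 0L, "n_features")
    out$single_sequence_table <- tab
  }

  if ("sweep" %in% conditions) {
    ranked <- selections$ranked$names
    evs <- lapply(sweep_k, function(k) {
      fit_eval(feats[, head(ranked, k), drop = FALSE])
    })
    names(evs) <- as.character(sweep_k)
    tab <- .metric_table(evs, label_col = "n_features")
    tab$n_features <- sweep_k
    out$sweep_table <- tab
  }

  if ("roc" %in% conditions) {
    roc_models <- intersect(c("abnormal", "all", "combined"), models)
    if (length(roc_models) == 0) roc_models <- "all"
    out$roc <- lapply(setNames(roc_seeds, paste0("seed", roc_seeds)), function(sd) {
      lapply(setNames(roc_models, roc_models), function(m) {
        rf_s <- rf; rf_s$seed <- as.integer(sd)
        sm_s <- smote; sm_s$seed <- as.integer(sd)
        ev <- fit_eval(.model_matrix(m, ft, clinical, selections),
                       smote_ = sm_s, rf_ = rf_s, seed_ = as.integer(sd))
        cbind(ev$roc, AUC = unname(ev$mean["AUC"]))
      })
    })
  }

  structure(out, class = "model_suite")
}

# mean/sd columns for each metric over a named list of evaluation_results
.metric_table <- function(evs, label_col = "Model") {
  metrics <- c("AUC", "ACC", "SEN", "SPEC", "F1")
  tab <- data.frame(label = names(evs), stringsAsFactors = FALSE)
  names(tab) <- label_col
  for (m in metrics) {
    tab[[m]] <- vapply(evs, function(e) unname(e$mean[m]), 0)
    tab[[paste0(m, "_sd")]] <- vapply(evs, function(e) unname(e$sd[m]), 0)
  }
  rownames(tab) <- NULL
  tab
}

#' Format a metric table in the publication's "mean ± std" style
#'
#' @param tab a table from [run_model_suite()] (mean and `_sd` columns).
#' @param digits decimals (default 3).
#' @return data.frame of formatted strings.
#' @export
format_metric_table <- function(tab, digits = 3) {
  metrics <- c("AUC", "ACC", "SEN", "SPEC", "F1")
  out <- tab[, setdiff(names(tab), c(metrics, paste0(metrics, "_sd"))), drop = FALSE]
  for (m in metrics) {
    out[[m]] <- sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
                        tab[[m]], tab[[paste0(m, "_sd")]])
  }
  out
}

#' @export
print.model_suite <- function(x, ...) {
  if (!is.null(x$models_table)) {
    cat("Model comparison (validation cohort):\n")
    print(format_metric_table(x$models_table), row.names = FALSE)
  }
  if (!is.null(x$single_sequence_table)) {
    cat("\nSingle-sequence models:\n")
    print(format_metric_table(x$single_sequence_table), row.names = FALSE)
  }
  if (!is.null(x$sweep_table)) {
    cat("\nFeature-count sweep:\n")
    print(format_metric_table(x$sweep_table), row.names = FALSE)
  }
  invisible(x)
}
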