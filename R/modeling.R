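#' Rank-statistic AUC
#'
#' Mann-Whitney AUC of `scores` against 0/1 `labels`, ties handled by
#' average ranks. Constant scores give 0.5 with a warning.
#'
#' @param scores numeric predicted scores or probabilities.
#' @param labels 0/1 outcome vector.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  if (length(unique(scores)) == 1) {
    warning("constant scores: AUC defined as 0.5")
    return(0.5)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from a confusion table
#'
#' @param pred 0/1 predictions (probability threshold already applied).
#' @param labels 0/1 truth.
#' @return named vector: ACC, SEN, SPEC, F1.
#' @export
confusion_metrics <- function(pred, labels) {
  tp <- sum(pred == 1 & labels == 1)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sen > 0 && !is.na(sen)) 2 * prec * sen / (prec + sen) else 0
  c(ACC = (tp + tn) / length(labels), SEN = sen, SPEC = spec, F1 = f1)
}

#' Cohort split specification
#'
#' Defaults reproduce the source design: 71 patients randomly allocated to
#' a primary training cohort of 49 and a validation cohort of 22. For
#' other cohort sizes the same 49:22 proportion is applied. Stratified by
#' HT label by default.
#'
#' @param n_primary,n_validation cohort sizes (`NULL` = proportional
#'   default).
#' @param stratified stratify the split by label?
#' @param seed split seed.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(n_primary = NULL, n_validation = NULL,
                       stratified = TRUE, seed = 1L) {
  structure(list(n_primary = n_primary, n_validation = n_validation,
                 stratified = stratified, seed = as.integer(seed)),
            class = "split_spec")
}

#' Split a cohort into primary and validation sets
#'
#' @param labels 0/1 HT labels of the whole cohort.
#' @param spec a [split_spec()].
#' @return list with integer index vectors `primary` and `validation`
#'   (disjoint, exhaustive) and the resolved sizes.
#' @export
split_cohort <- function(labels, spec = split_spec()) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (n < 4) stopf("cohort must have >= 4 patients")
  n_primary <- spec$n_primary %||% round(n * 49 / 71)
  n_validation <- spec$n_validation %||% (n - n_primary)
  if (n_primary + n_validation != n) {
    stopf("n_primary + n_validation must equal the cohort size (%d)", n)
  }
  val <- with_seed(spec$seed, {
    if (spec$stratified) {
      if (length(unique(labels)) < 2) stopf("stratified split needs both classes")
      idx1 <- sample(which(labels == 1))
      idx0 <- sample(which(labels == 0))
      k1 <- round(length(idx1) * n_validation / n)
      k1 <- max(1L, min(k1, length(idx1) - 1L, n_validation - 1L))
      k0 <- n_validation - k1
      c(idx1[seq_len(k1)], idx0[seq_len(k0)])
    } else {
      if (length(unique(labels)) < 2) {
        warning("cohort has a single class; unstratified split proceeds")
      }
      sample(n, n_validation)
    }
  })
  val <- sort(val)
  list(primary = setdiff(seq_len(n), val), validation = val,
       n_primary = n_primary, n_validation = n_validation)
}

#' SMOTE specification
#'
#' @param k_neighbors neighbours considered per minority sample (default
#'   5).
#' @param target_ratio minority/majority ratio to reach (default 1,
#'   balanced).
#' @param seed RNG seed (`NULL` = use the current stream).
#' @return object of class `smote_spec`.
#' @export
smote_spec <- function(k_neighbors = 5L, target_ratio = 1.0, seed = NULL) {
  if (k_neighbors < 1) stopf("k_neighbors must be >= 1")
  if (target_ratio <= 0) stopf("target_ratio must be > 0")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 target_ratio = target_ratio, seed = seed),
            class = "smote_spec")
}

#' SMOTE minority oversampling
#'
#' Generates synthetic minority points `x_new = x_i + u (x_nn - x_i)` with
#' `u ~ Uniform(0, 1)` and `x_nn` one of the `k` nearest minority
#' neighbours of `x_i` (Euclidean), until
#' `minority + synthetic = target_ratio * majority`. The majority class is
#' untouched. All synthetic points are convex combinations of minority
#' pairs and therefore lie inside the minority bounding box.
#'
#' @param x_minority,x_majority numeric matrices (rows = samples).
#' @param spec a [smote_spec()].
#' @param u optional fixed interpolation weights (length = number of
#'   synthetic points) for deterministic testing; default random.
#' @return list with `synthetic` (matrix, possibly 0 rows) and
#'   `augmented_minority` (minority + synthetic).
#' @export
smote_oversample <- function(x_minority, x_majority, spec = smote_spec(),
                             u = NULL) {
  x_minority <- as.matrix(x_minority)
  n_min <- nrow(x_minority)
  if (n_min <= spec$k_neighbors) {
    stopf("minority count (%d) must exceed k_neighbors (%d); choose a smaller k",
          n_min, spec$k_neighbors)
  }
  n_new <- round(spec$target_ratio * nrow(as.matrix(x_majority))) - n_min
  if (n_new <= 0) {
    return(list(synthetic = x_minority[0, , drop = FALSE],
                augmented_minority = x_minority))
  }
  gen <- function() {
    dmat <- as.matrix(dist(x_minority))
    diag(dmat) <- Inf
    nn <- matrix(0L, n_min, spec$k_neighbors)
    for (i in seq_len(n_min)) nn[i, ] <- order(dmat[i, ])[seq_len(spec$k_neighbors)]
    base <- sample.int(n_min, n_new, replace = TRUE)
    pick <- nn[cbind(base, sample.int(spec$k_neighbors, n_new, replace = TRUE))]
    w <- if (is.null(u)) runif(n_new) else rep_len(u, n_new)
    x_minority[base, , drop = FALSE] +
      w * (x_minority[pick, , drop = FALSE] - x_minority[base, , drop = FALSE])
  }
  synth <- if (is.null(spec$seed)) gen() else with_seed(spec$seed, gen())
  list(synthetic = synth, augmented_minority = rbind(x_minority, synth))
}

#' Random forest specification
#'
#' Defaults follow the published hyperparameters: 70 trees of maximum
#' depth 5.
#'
#' @param n_estimators number of trees.
#' @param max_depth maximum tree depth.
#' @param seed forest seed.
#' @return object of class `rf_spec`.
#' @export
rf_spec <- function(n_estimators = 70L, max_depth = 5L, seed = 1L) {
  if (n_estimators < 1 || max_depth < 1) stopf("n_estimators and max_depth must be >= 1")
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth), seed = as.integer(seed)),
            class = "rf_spec")
}

.fit_rf <- function(x, y, spec) {
  ranger::ranger(
    x = as.data.frame(x, check.names = FALSE), y = factor(y, levels = c(0, 1)),
    num.trees = spec$n_estimators, max.depth = spec$max_depth,
    probability = TRUE, seed = spec$seed, num.threads = 1
  )
}

.predict_rf <- function(model, x) {
  p <- predict(model, data = as.data.frame(x, check.names = FALSE),
               num.threads = 1)$predictions
  p[, "1"]
}

# stratified fold assignment: class-sorted deal keeps global fold sizes at
# floor/ceil(n/k) (e.g. 10,10,10,10,9 for n = 49) while spreading each class
.make_folds <- function(labels, k = 5L, seed = 1L) {
  with_seed(seed, {
    for (attempt in 1:20) {
      ord <- c(sample(which(labels == 1)), sample(which(labels == 0)))
      folds <- integer(length(labels))
      folds[ord] <- rep_len(seq_len(k), length(labels))
      train_ok <- vapply(seq_len(k), function(f) {
        length(unique(labels[folds != f])) == 2
      }, TRUE)
      if (all(train_ok)) return(folds)
    }
    stopf("could not build folds with both classes in every training portion")
  })
}

#' Train the five cross-validation fold models
#'
#' Five-fold stratified cross-validation on the primary cohort. By default
#' SMOTE is fitted and applied inside each training fold only, so no
#' synthetic copy of a held-out sample can leak into its own fold's
#' training data; `published_order = TRUE` instead rebalances the whole primary
#' cohort once before folding, reproducing the published order of
#' operations.
#'
#' @param x numeric feature matrix of the primary cohort.
#' @param y 0/1 labels of the primary cohort.
#' @param smote a [smote_spec()].
#' @param rf an [rf_spec()].
#' @param folds number of folds (default 5).
#' @param published_order apply SMOTE before folding (published order)?
#' @param seed fold-assignment / SMOTE seed.
#' @return object of class `cv_models`: list with `models` (five ranger
#'   fits), `fold_metrics` (per held-in fold), `fold_metrics_mean`,
#'   `columns`.
#' @export
crossval_train <- function(x, y, smote = smote_spec(), rf = rf_spec(),
                           folds = 5L, published_order = FALSE, seed = 1L) {
  x <- as.matrix(x)
  y <- assert_binary_labels(y)
  minority <- as.integer(names(which.min(table(y))))

  if (published_order && sum(y == minority) >= 2) {
    sm_all <- with_seed(derive_seed(seed, 77L), {
      sp <- smote
      sp$k_neighbors <- min(sp$k_neighbors, sum(y == minority) - 1L)
      smote_oversample(x[y == minority, , drop = FALSE],
                       x[y != minority, , drop = FALSE], sp)
    })
    x <- rbind(x, sm_all$synthetic)
    y <- c(y, rep(minority, nrow(sm_all$synthetic)))
  }

  fold_id <- .make_folds(y, folds, seed = derive_seed(seed, 11L))
  models <- vector("list", folds)
  fm <- matrix(NA_real_, folds, 5, dimnames = list(NULL, c("AUC", "ACC", "SEN", "SPEC", "F1")))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    xt <- x[tr, , drop = FALSE]
    yt <- y[tr]
    if (!published_order && sum(yt == minority) >= 2) {
      aug <- with_seed(derive_seed(seed, 100L + f), {
        sp <- smote
        sp$k_neighbors <- min(sp$k_neighbors, sum(yt == minority) - 1L)
        smote_oversample(xt[yt == minority, , drop = FALSE],
                         xt[yt != minority, , drop = FALSE], sp)
      })
      xt <- rbind(xt, aug$synthetic)
      yt <- c(yt, rep(minority, nrow(aug$synthetic)))
    }
    rf_f <- rf
    rf_f$seed <- derive_seed(rf$seed, f)
    models[[f]] <- .fit_rf(xt, yt, rf_f)
    # held-in fold metrics ("classification result in the primary cohort")
    pv <- .predict_rf(models[[f]], x[!tr, , drop = FALSE])
    yv <- y[!tr]
    if (length(unique(yv)) == 2) {
      fm[f, ] <- c(AUC = suppressWarnings(auc_rank(pv, yv)),
                   confusion_metrics(as.integer(pv >= 0.5), yv))
    }
  }
  structure(
    list(models = models, fold_metrics = as.data.frame(fm),
         fold_metrics_mean = colMeans(fm, na.rm = TRUE),
         columns = colnames(x), folds = fold_id, published_order = published_order),
    class = "cv_models"
  )
}

#' Evaluate fold models on the held-out validation cohort
#'
#' Scores each of the five fold models on the untouched validation cohort
#' and reports per-metric mean and standard deviation over the fold
#' models (the published "mean +/- std" convention), plus ROC points from
#' the fold-averaged probabilities. Classification threshold 0.5.
#'
#' @param cv a `cv_models`.
#' @param x_val validation feature matrix (same columns as training).
#' @param y_val validation 0/1 labels.
#' @return object of class `evaluation_result`: `per_fold` data.frame,
#'   `mean`, `sd`, `roc` (data.frame fpr/tpr), `mean_scores`.
#' @export
evaluate_models <- function(cv, x_val, y_val) {
  y_val <- assert_binary_labels(y_val)
  x_val <- as.matrix(x_val)[, cv$columns, drop = FALSE]
  scores <- vapply(cv$models, .predict_rf, numeric(nrow(x_val)), x = x_val)
  per_fold <- t(apply(scores, 2, function(s) {
    c(AUC = auc_rank(s, y_val), confusion_metrics(as.integer(s >= 0.5), y_val))
  }))
  mean_scores <- rowMeans(scores)
  thr <- sort(unique(c(-Inf, mean_scores, Inf)), decreasing = TRUE)
  roc <- data.frame(
    fpr = vapply(thr, function(t) mean(mean_scores >= t & y_val == 0) / mean(y_val == 0), 0),
    tpr = vapply(thr, function(t) mean(mean_scores >= t & y_val == 1) / mean(y_val == 1), 0)
  )
  structure(
    list(per_fold = as.data.frame(per_fold),
         mean = colMeans(per_fold), sd = apply(per_fold, 2, sd),
         roc = roc, mean_scores = mean_scores),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(paste(sprintf("%s %.3f ± %.3f", names(x$mean), x$mean, x$sd),
            collapse = "  "), "\n")
  invisible(x)
}
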