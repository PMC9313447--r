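#' LASSO ranking specification
#'
#' The selection stage ranks features by the magnitude of their L1
#' penalized squared-loss regression coefficients against the 0/1 HT
#' label. The default penalty `alpha = 1e-6` barely shrinks, so ranking is
#' effectively by near-OLS coefficient magnitude on standardized columns;
#' the penalty remains configurable.
#'
#' @param alpha L1 penalty weight (same parameterization as the classical
#'   `1/(2n) RSS + alpha * |beta|_1` objective).
#' @param standardize z-score columns before fitting (default `TRUE`).
#' @param max_iter coordinate-descent pass cap (default 1000, the common
#'   default of the reference ecosystem). With `p >> n` and a near-zero
#'   penalty the unpenalized limit is ill-posed; the cold start from zero
#'   plus this cap is what keeps the fit deterministic and the
#'   coefficient ranking stable, so hitting the cap is expected there and
#'   recorded rather than treated as failure.
#' @param tol convergence threshold on the largest absolute coefficient
#'   change per pass (default 1e-4).
#' @param top_k number of features to keep (by descending `|coef|`).
#' @param seed retained for provenance (the fit itself is deterministic).
#' @return object of class `lasso_spec`.
#' @export
lasso_spec <- function(alpha = 1e-6, standardize = TRUE, max_iter = 1000L,
                       tol = 1e-4, top_k = 14L, seed = NULL) {
  if (alpha < 0) stopf("alpha must be >= 0")
  if (top_k < 1) stopf("top_k must be >= 1")
  if (tol <= 0) stopf("tol must be > 0")
  structure(list(alpha = alpha, standardize = standardize,
                 max_iter = max_iter, tol = tol, top_k = as.integer(top_k),
                 seed = seed),
            class = "lasso_spec")
}

#' Rank features by LASSO coefficient magnitude
#'
#' Fits an L1-penalized squared-loss regression of the 0/1 labels on the
#' feature columns by cyclic coordinate descent, cold-started from zero
#' at the target penalty, and returns the `top_k` features by absolute
#' coefficient, ties broken by column name. Columns are z-scored first
#' when `spec$standardize`, so coefficient magnitudes are comparable
#' across features.
#'
#' @param x numeric matrix (patients x features) with unique column
#'   names, or a `feature_table`.
#' @param labels 0/1 outcome vector.
#' @param spec a [lasso_spec()].
#' @param stage provenance tag (`"radiomics"`, `"abnormal-only"`,
#'   `"fusion"`, ...).
#' @return object of class `selection_result`: list with `names`,
#'   `coefficients` (ordered by descending magnitude), `stage`, `spec`,
#'   `converged`, `n_nonzero`.
#' @export
lasso_rank <- function(x, labels, spec = lasso_spec(), stage = "radiomics") {
  if (inherits(x, "feature_table")) x <- x$features
  labels <- assert_binary_labels(labels)
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)) > 0) {
    stopf("x must have unique column names")
  }
  if (anyNA(x)) stopf("x contains NA columns; clean before selection")

  xs <- x
  if (spec$standardize) {
    mu <- colMeans(xs)
    sdev <- apply(xs, 2, sd)
    sdev[sdev == 0] <- Inf  # constant columns get coefficient 0
    xs <- sweep(sweep(xs, 2, mu, "-"), 2, sdev, "/")
  }

  y <- as.numeric(labels)
  yc <- y - mean(y)
  # visit coordinates by decreasing marginal correlation (ties by name):
  # the near-unpenalized objective is flat in many directions, so the
  # visiting order must not depend on the arbitrary column layout
  marg <- abs(as.vector(crossprod(xs, yc)))
  ord <- order(-marg, colnames(xs))
  fit <- .cpp_lasso_cd(xs[, ord, drop = FALSE], yc, spec$alpha, spec$tol,
                       as.integer(spec$max_iter))
  beta <- numeric(ncol(xs))
  beta[ord] <- fit$beta
  names(beta) <- colnames(xs)
  converged <- fit$converged

  ord <- order(-abs(beta), names(beta))
  nonzero <- sum(beta != 0)
  keep <- head(ord, min(spec$top_k, length(beta)))
  structure(
    list(names = names(beta)[keep], coefficients = beta[keep], stage = stage,
         spec = spec, converged = converged, n_nonzero = nonzero),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result [", x$stage, "]:", length(x$names), "features,",
      x$n_nonzero, "nonzero coefficients",
      if (!x$converged) "(non-convergence warning recorded)", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Screen clinical factors by exact tests and univariate AUC
#'
#' Binary factors are tested with a one-sided Fisher exact test on the
#' 2x2 group table (one-sided in the direction of the observed
#' association); continuous age uses the Wilcoxon rank-sum test. Each
#' factor's discriminative ability is summarized by the univariate AUC of
#' the factor used directly as a score (orientation-free:
#' `max(auc, 1 - auc)`). The selected pair is the two factors with the
#' highest AUC among those with `p < p_threshold`; if fewer than two pass,
#' the remaining slots are filled by AUC rank. Constant columns get
#' `p = 1`, `AUC = 0.5` and are never selected.
#'
#' @param clinical data.frame with the 16 factor columns.
#' @param labels 0/1 HT labels.
#' @param p_threshold significance gate (default 0.05).
#' @return object of class `clinical_screen`: list with `table`
#'   (factor/p_value/test/auc), `selected` (character pair),
#'   `p_threshold`.
#' @export
screen_clinical <- function(clinical, labels, p_threshold = 0.05) {
  labels <- assert_binary_labels(labels)
  if (ncol(clinical) < 2) stopf("clinical table must contain the factor columns")
  res <- lapply(names(clinical), function(nm) {
    x <- clinical[[nm]]
    if (length(unique(x)) < 2) {
      return(data.frame(factor = nm, p_value = 1, test = "constant", auc = 0.5,
                        stringsAsFactors = FALSE))
    }
    if (length(unique(x)) == 2) {
      tab <- table(factor(x, levels = sort(unique(x))), factor(labels, levels = c(1, 0)))
      # one-sided alternative oriented along the observed sample odds ratio
      alt <- if (tab[1, 1] * tab[2, 2] >= tab[1, 2] * tab[2, 1]) "greater" else "less"
      p <- fisher.test(tab, alternative = alt)$p.value
      test <- paste0("fisher.", alt)
    } else {
      p <- wilcox.test(x ~ labels, exact = FALSE)$p.value
      test <- "wilcoxon"
    }
    a <- auc_rank(x, labels)
    data.frame(factor = nm, p_value = p, test = test, auc = max(a, 1 - a),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  eligible <- tab$test != "constant"
  passed <- eligible & tab$p_value < p_threshold
  ord <- order(-tab$auc, tab$factor)
  ranked <- tab$factor[ord]
  sel <- ranked[ranked %in% tab$factor[passed]]
  if (length(sel) < 2) {
    filler <- ranked[ranked %in% tab$factor[eligible] & !(ranked %in% sel)]
    sel <- c(sel, filler)
  }
  structure(list(table = tab, selected = head(sel, 2), p_threshold = p_threshold),
            class = "clinical_screen")
}

#' @export
print.clinical_screen <- function(x, ...) {
  cat("clinical_screen: selected", paste(x$selected, collapse = " + "),
      sprintf("(p gate %.3g)\n", x$p_threshold))
  print(x$table, digits = 3)
  invisible(x)
}

#' Fuse selected radiomics features with clinical factors and reselect
#'
#' Concatenates the selected radiomics columns with the screened clinical
#' pair and reruns the LASSO ranking, keeping only features with nonzero
#' coefficients (capped at the input size).
#'
#' @param radiomics_selection a `selection_result` over radiomics columns.
#' @param clinical_pair character names of the screened clinical factors.
#' @param features radiomics feature matrix (or `feature_table`).
#' @param clinical clinical data.frame holding the pair columns.
#' @param labels 0/1 HT labels.
#' @param spec a [lasso_spec()]; `top_k` is overridden by the input size.
#' @return `selection_result` with `stage = "fusion"`.
#' @export
fuse_and_reselect <- function(radiomics_selection, clinical_pair, features,
                              clinical, labels, spec = lasso_spec()) {
  if (inherits(features, "feature_table")) features <- features$features
  if (length(radiomics_selection$names) == 0) stopf("radiomics selection is empty")
  if (any(clinical_pair %in% radiomics_selection$names)) {
    stopf("duplicate column names between radiomics and clinical features")
  }
  x <- cbind(features[, radiomics_selection$names, drop = FALSE],
             as.matrix(clinical[, clinical_pair, drop = FALSE]))
  if (anyDuplicated(colnames(x)) > 0) stopf("duplicate column names in fusion input")
  spec$top_k <- ncol(x)
  sel <- lasso_rank(x, labels, spec, stage = "fusion")
  keep <- sel$coefficients != 0
  if (any(keep)) {
    sel$names <- sel$names[keep]
    sel$coefficients <- sel$coefficients[keep]
  }
  sel
}
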