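test_that("rank AUC and confusion metrics match the textbook definitions", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_rank(c(0.2, 0.8, 0.4, 0.9), c(1, 1, 0, 0)), 0.25)
  expect_equal(auc_rank(c(0.5, 0.5, 0.5, 0.9), c(1, 1, 0, 0)), 0.25)  # ties
  expect_warning(a <- auc_rank(rep(0.3, 6), c(1, 0, 1, 0, 0, 0)), "constant")
  expect_equal(a, 0.5)
  # invariance under strictly monotone score transforms
  set.seed(1)
  s <- rnorm(50); y <- rbinom(50, 1, 0.4)
  expect_equal(auc_rank(exp(3 * s) + 7, y), auc_rank(s, y))

  # TP 3, FN 1, TN 16, FP 2
  pred <- c(rep(1, 3), 0, rep(0, 16), 1, 1)
  truth <- c(rep(1, 4), rep(0, 18))
  m <- confusion_metrics(pred, truth)
  expect_equal(unname(m["SEN"]), 0.75)
  expect_equal(round(unname(m["SPEC"]), 3), 0.889)
  expect_equal(round(unname(m["ACC"]), 3), 0.864)
  expect_equal(round(unname(m["F1"]), 3), 0.667)
})

test_that("the cohort split reproduces the 49/22 design and stratification", {
  labels <- c(rep(1L, 11), rep(0L, 60))
  sp <- split_cohort(labels, split_spec(seed = 4L))
  expect_length(sp$primary, 49L)
  expect_length(sp$validation, 22L)
  expect_identical(sort(c(sp$primary, sp$validation)), 1:71)
  expect_true(sum(labels[sp$validation]) %in% c(3L, 4L))

  sp2 <- split_cohort(labels, split_spec(seed = 4L))
  expect_identical(sp, sp2)
  sp3 <- split_cohort(labels, split_spec(seed = 5L))
  expect_false(identical(sp$validation, sp3$validation))

  expect_error(split_cohort(rep(1L, 20), split_spec()), "both classes")
})

test_that("SMOTE interpolates between minority neighbours", {
  two <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  maj <- matrix(rnorm(20), 10, 2)
  out <- smote_oversample(two, maj, smote_spec(k_neighbors = 1L, seed = 1L),
                          u = 0.5)
  expect_identical(nrow(out$synthetic), 8L)  # 10 - 2 at ratio 1
  expect_true(all(abs(out$synthetic[, 1] - 0.5) < 1e-12))  # midpoints
  expect_equal(out$synthetic[, 1], out$synthetic[, 2])     # on the segment

  set.seed(2)
  minority <- matrix(rnorm(16, 5, 2), 8, 2)
  majority <- matrix(rnorm(80), 40, 2)
  aug <- smote_oversample(minority, majority, smote_spec(seed = 9L))
  expect_identical(nrow(aug$synthetic), 32L)  # 40 - 8 at ratio 1
  for (j in 1:2) {
    expect_gte(min(aug$synthetic[, j]), min(minority[, j]))  # bounding box
    expect_lte(max(aug$synthetic[, j]), max(minority[, j]))
  }
  expect_error(
    smote_oversample(minority[1:3, ], majority, smote_spec(k_neighbors = 5L)),
    "smaller k"
  )
})

test_that("cross-validation trains five deterministic fold models", {
  set.seed(3)
  n <- 49L
  y <- c(rep(1L, 8), rep(0L, 41))
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  x[, 1] <- x[, 1] + 6 * y  # large margin: linearly separable
  cv <- crossval_train(x, y, seed = 11L)
  expect_length(cv$models, 5L)
  expect_identical(sort(as.integer(table(cv$folds))), c(9L, 10L, 10L, 10L, 10L))
  expect_true(all(cv$fold_metrics$ACC == 1))  # separable toy data

  probe <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  p1 <- vapply(cv$models, htradiomics:::.predict_rf, numeric(10), x = probe)
  cv2 <- crossval_train(x, y, seed = 11L)
  p2 <- vapply(cv2$models, htradiomics:::.predict_rf, numeric(10), x = probe)
  expect_identical(p1, p2)

  # published-order mode rebalances once before folding: more rows per fold
  cvp <- crossval_train(x, y, published_order = TRUE, seed = 11L)
  expect_gt(length(cvp$folds), length(cv$folds))
})

test_that("evaluation reports mean +/- sd over fold models on the validation set", {
  set.seed(4)
  n <- 120L
  y <- rbinom(n, 1, 0.3)
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  x[, 2] <- x[, 2] + 2 * y
  prim <- 1:80; val <- 81:120
  cv <- crossval_train(x[prim, ], y[prim], seed = 5L)
  ev <- evaluate_models(cv, x[val, ], y[val])
  expect_identical(nrow(ev$per_fold), 5L)
  expect_named(ev$mean, c("AUC", "ACC", "SEN", "SPEC", "F1"))
  expect_true(all(ev$mean >= 0 & ev$mean <= 1))
  expect_true(all(ev$sd >= 0))
  expect_gt(ev$mean["AUC"], 0.8)  # planted signal is recovered
  expect_identical(ev$roc$fpr[1], 0)  # ROC starts at (0,0), ends at (1,1)
  expect_identical(utils::tail(ev$roc$tpr, 1), 1)

  # permutation null: scores carry no information about shuffled labels
  set.seed(6)
  null_auc <- replicate(20, {
    suppressWarnings(mean(vapply(seq_len(5), function(k) {
      auc_rank(ev$mean_scores, sample(y[val]))
    }, 0)))
  })
  expect_lt(abs(mean(null_auc) - 0.5), 0.15)
})

test_that("leakage guards hold: selection and training never see validation rows", {
  co <- test_cohort_m2()
  ft <- extract_cohort(co)
  # constant-score AUC warnings are expected on a fixture this small
  suite <- suppressWarnings(
    run_model_suite(ft, co$clinical, lasso = lasso_spec(top_k = 5L),
                    split = split_spec(seed = 2L),
                    smote = smote_spec(k_neighbors = 1L),
                    conditions = "models", models = c("abnormal", "all"),
                    seed = 3L)
  )
  sp <- suite$split
  expect_length(intersect(sp$primary, sp$validation), 0L)
  expect_identical(sort(c(sp$primary, sp$validation)), seq_along(ft$labels))
  # the stored selection equals one recomputed from the primary rows alone
  resel <- lasso_rank(ft$features[sp$primary, , drop = FALSE],
                      ft$labels[sp$primary],
                      lasso_spec(top_k = 20L), stage = "radiomics")
  expect_identical(head(resel$names, 5L), suite$selections$all$names)
  # abnormal-only condition never selects a normal-side feature
  expect_false(any(grepl("_normal_", suite$selections$abnormal$names)))
})
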