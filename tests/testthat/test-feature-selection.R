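# orthonormal, mean-zero design with (1/n) X'X = I
orthonormal_design <- function(n, p) {
  H <- contr.helmert(n)[, seq_len(p)]
  X <- sweep(H, 2, sqrt(colSums(H^2) / n), "/")
  colnames(X) <- sprintf("f%02d", seq_len(p))
  X
}

test_that("LASSO on an orthonormal design equals soft-thresholded OLS", {
  set.seed(1)
  n <- 64L; p <- 20L
  X <- orthonormal_design(n, p)
  y <- as.vector(X %*% c(3, -2, 1.5, rep(0, p - 3))) + rnorm(n, 0, 0.5)
  lam <- 0.3
  fit <- htradiomics:::.cpp_lasso_cd(X, y - mean(y), lam, 1e-12, 1000L)
  b_ols <- as.vector(crossprod(X, y - mean(y))) / n
  soft <- sign(b_ols) * pmax(abs(b_ols) - lam, 0)
  expect_lt(max(abs(fit$beta - soft)), 1e-8)
  expect_true(fit$converged)
})

test_that("the unpenalized limit reproduces least squares on full-rank data", {
  set.seed(2)
  n <- 40L; p <- 5L
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("v%d", 1:p)))
  y <- rnorm(n)
  fit <- htradiomics:::.cpp_lasso_cd(scale(X, scale = FALSE), y - mean(y), 0,
                                     1e-13, 100000L)
  ls <- unname(coef(lm(y ~ X))[-1])
  expect_lt(max(abs(fit$beta - ls)), 1e-8)
})

test_that("LASSO ranking recovers planted informative columns", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 200L; p <- 100L
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("n%03d", 1:p)))
    y <- rbinom(n, 1, 0.5)
    for (j in 1:3) X[, j] <- X[, j] + 1.5 * y  # standardized effect 1.5
    colnames(X)[1:3] <- c("sig1", "sig2", "sig3")
    sel <- lasso_rank(X, y, lasso_spec(top_k = 3))
    all(c("sig1", "sig2", "sig3") %in% sel$names)
  }, TRUE)
  expect_gte(sum(hits), 9)
})

test_that("standardized selection is invariant to positive column scaling", {
  set.seed(3)
  n <- 80L; p <- 30L
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("c%02d", 1:p)))
  y <- rbinom(n, 1, plogis(X[, 1] - X[, 2]))
  sel1 <- lasso_rank(X, y, lasso_spec(top_k = 5))
  X2 <- X
  X2[, 1] <- X2[, 1] * 1000
  X2[, 7] <- X2[, 7] * 1e-4
  sel2 <- lasso_rank(X2, y, lasso_spec(top_k = 5))
  expect_identical(sel1$names, sel2$names)
  # and fully deterministic given the same table
  sel3 <- lasso_rank(X, y, lasso_spec(top_k = 5))
  expect_identical(sel1$coefficients, sel3$coefficients)
})

test_that("coordinate descent agrees with an independent solver at moderate penalty", {
  skip_if_not_installed("glmnet")
  set.seed(4)
  n <- 100L; p <- 50L
  X <- matrix(rnorm(n * p), n, p)
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(n)
  lam <- 0.1
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  mine <- htradiomics:::.cpp_lasso_cd(Xc, yc, lam, 1e-13, 100000L)
  ref <- glmnet::glmnet(Xc, yc, lambda = lam, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-14)
  expect_lt(max(abs(mine$beta - as.numeric(ref$beta))), 1e-6)
})

test_that("clinical screening reproduces the published SVS_1 exact test", {
  # the published 2x2: all 11 HT patients SVS-positive, 37 of 60 No-HT
  labels <- c(rep(1L, 11), rep(0L, 60))
  svs1 <- c(rep(1L, 11), rep(1L, 37), rep(0L, 23))
  set.seed(6)
  clinical <- data.frame(
    SVS_1 = svs1,
    age = round(runif(71, 40, 85)),
    noise = rbinom(71, 1, 0.5)
  )
  res <- screen_clinical(clinical, labels)
  p_svs <- res$table$p_value[res$table$factor == "SVS_1"]
  expect_equal(round(p_svs, 3), 0.009)  # printed precision
  expect_lt(abs(p_svs - 0.009), 5e-4)
  expect_true("SVS_1" %in% res$selected)

  # a factor identical to the label separates perfectly
  clinical$oracle <- labels
  res2 <- screen_clinical(clinical, labels)
  expect_equal(res2$table$auc[res2$table$factor == "oracle"], 1.0)
  expect_true("oracle" %in% res2$selected)
})

test_that("label-independent factors score at chance and constants are excluded", {
  set.seed(7)
  n <- 10000L
  labels <- rbinom(n, 1, 0.5)
  clinical <- data.frame(coin = rbinom(n, 1, 0.5), flat = rep(1L, n),
                         real = labels)
  res <- screen_clinical(clinical, labels)
  expect_lt(abs(res$table$auc[res$table$factor == "coin"] - 0.5), 0.02)
  expect_identical(res$table$p_value[res$table$factor == "flat"], 1)
  expect_identical(res$table$auc[res$table$factor == "flat"], 0.5)
  expect_false("flat" %in% res$selected)
})

test_that("fusion reselection keeps informative columns and drops dead weight", {
  set.seed(8)
  n <- 150L
  feats <- matrix(rnorm(n * 20), n, 20,
                  dimnames = list(NULL, paste0("ADC_a_abnormal_firstorder_F", 1:20)))
  y <- rbinom(n, 1, 0.5)
  feats[, 1] <- feats[, 1] + 1.2 * y
  rad <- lasso_rank(feats, y, lasso_spec(top_k = 14))

  # constant clinical pair: zero coefficients, fusion within radiomics set
  clinical <- data.frame(SVS_1 = rep(1, n), M2 = rep(0, n))
  fus <- fuse_and_reselect(rad, c("SVS_1", "M2"), feats, clinical, y)
  expect_true(all(fus$names %in% rad$names))
  expect_lte(length(fus$names), 16L)

  # a strongly informative clinical column ranks near the top
  top3 <- vapply(1:10, function(s) {
    set.seed(100 + s)
    y2 <- rbinom(n, 1, 0.5)
    f2 <- matrix(rnorm(n * 20), n, 20, dimnames = dimnames(feats))
    f2[, 2] <- f2[, 2] + 0.8 * y2
    cl2 <- data.frame(SVS_1 = y2 + rnorm(n, 0, 0.3), M2 = rnorm(n))
    rad2 <- lasso_rank(f2, y2, lasso_spec(top_k = 14))
    fus2 <- fuse_and_reselect(rad2, c("SVS_1", "M2"), f2, cl2, y2)
    "SVS_1" %in% head(fus2$names, 3)
  }, TRUE)
  expect_gte(sum(top3), 8)

  expect_error(
    fuse_and_reselect(rad, rad$names[1], feats, data.frame(x = rnorm(n)), y),
    "duplicate"
  )
})
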