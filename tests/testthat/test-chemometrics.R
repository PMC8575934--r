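test_that("PCA loadings are orthonormal with the sign convention applied", {
  set.seed(10)
  X <- matrix(rnorm(200), 20, 10)
  m <- pca_fit(X, 5)
  expect_equal(crossprod(m$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  for (j in 1:5) {
    expect_gt(m$loadings[which.max(abs(m$loadings[, j])), j], 0)
  }
  expect_true(all(diff(m$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(m$explained_variance_ratio), 1 + 1e-12)
  expect_error(pca_fit(X, 11), "n_components")
})

test_that("PCA reconstruction is lossless at full rank and monotone below", {
  set.seed(11)
  X <- matrix(rnorm(15 * 8), 15, 8)
  full <- pca_fit(X, 8)
  Xhat <- pca_inverse_transform(full, pca_transform(full, X))
  expect_equal(Xhat, X, tolerance = 1e-8, ignore_attr = TRUE)
  errs <- vapply(1:8, function(k) {
    m <- pca_fit(X, k)
    norm(X - pca_inverse_transform(m, pca_transform(m, X)), "F")
  }, 0)
  expect_true(all(diff(errs) <= 1e-10))
  # rank-1 matrix: single component explains everything
  r1 <- tcrossprod(rnorm(10), rnorm(6))
  expect_equal(pca_fit(r1, 1)$explained_variance_ratio, 1)
  # zero scores reconstruct the column means
  m <- pca_fit(X, 3)
  expect_equal(pca_inverse_transform(m, matrix(0, 2, 3)),
               matrix(colMeans(X), 2, 8, byrow = TRUE), ignore_attr = TRUE)
})

test_that("noiseless quaternary fused matrix is rank 4 and reconstructs", {
  ds <- quaternary_noiseless(8, 0)
  X <- cbind(ds$blocks$CD_DCE$matrix, ds$blocks$UV_DCE$matrix)
  m <- pca_fit(X, 4)
  expect_gt(sum(m$explained_variance_ratio), 0.9999)
  Xhat <- pca_inverse_transform(m, pca_transform(m, X))
  expect_lt(norm(X - Xhat, "F") / norm(X, "F"), 1e-6)
})

test_that("OLS matches the normal-equation oracle and rejects singularity", {
  set.seed(12)
  T <- matrix(rnorm(80), 20, 4)
  Y <- matrix(rnorm(40), 20, 2)
  m <- ols_fit(T, Y)
  A <- cbind(1, T)
  oracle <- solve(t(A) %*% A, t(A) %*% Y)
  expect_equal(unname(m$coef), unname(oracle), tolerance = 1e-10)
  # exact linear responses leave zero residuals
  B <- matrix(rnorm(8), 4, 2)
  Ylin <- T %*% B + 3
  mlin <- ols_fit(T, Ylin)
  expect_equal(ols_predict(mlin, T), Ylin, tolerance = 1e-9, ignore_attr = TRUE)
  # constant predictor column duplicates the intercept -> singular
  expect_error(ols_fit(cbind(T, 1), Y), "rank-deficient")
  expect_error(ols_fit(T[1:3, ], Y[1:3, ]), "more samples")
})

test_that("PCR recovers noiseless concentrations and falls back to means", {
  ds <- quaternary_noiseless()
  parts <- split_design(ds)
  fit <- fit_pipeline(pipeline("pcr"), parts$train, 4)
  pred <- predict_pipeline(fit, parts$test)
  expect_lt(max(abs(pred - parts$test$Y)), 1e-6)
  # n_pc = 0 predicts channel means
  prep <- preprocess_fit(parts$train, "uv")
  X <- preprocess_apply(prep, parts$train)$matrix
  m0 <- pcr_fit(X, parts$train$Y, 0)
  expect_equal(unname(pcr_predict(m0, X[1:2, ])),
               matrix(colMeans(parts$train$Y), 2, 4, byrow = TRUE))
  # scale invariance: multiplying raw X by a constant is absorbed by
  # unit-variance scaling
  ds2 <- ds
  for (bn in names(ds2$blocks)) {
    ds2$blocks[[bn]]$matrix <- ds2$blocks[[bn]]$matrix * 7
  }
  parts2 <- split_design(ds2)
  fit2 <- fit_pipeline(pipeline("pcr"), parts2$train, 4)
  expect_equal(predict_pipeline(fit2, parts2$test), pred, tolerance = 1e-8)
})

test_that("PCR equals OLS at full rank", {
  set.seed(13)
  X <- matrix(rnorm(20 * 6), 20, 6)
  Y <- matrix(rnorm(40), 20, 2)
  pcr <- pcr_fit(X, Y, 6)
  ols <- ols_fit(X, Y)
  Xn <- matrix(rnorm(5 * 6), 5, 6)
  expect_equal(pcr_predict(pcr, Xn), ols_predict(ols, Xn), tolerance = 1e-8)
})

test_that("PLS2 matches the frozen reference and the kernel oracle", {
  set.seed(123)
  X <- matrix(rnorm(20 * 50), 20, 50)
  B <- matrix(rnorm(50 * 3, sd = 0.5), 50, 3)
  Y <- X %*% B + matrix(rnorm(20 * 3, sd = 0.1), 20, 3)
  set.seed(456)
  Xn <- matrix(rnorm(5 * 50), 5, 50)
  m <- pls_fit(X, Y, 4)
  pred <- pls_predict(m, Xn)
  # frozen from an independent SVD-weight PLS2 reference implementation
  ref <- matrix(c(
    0.279504368250, 2.331619276439, -3.748070254575,
    -3.300535816999, -0.694162575370, -3.587475254376,
    4.035134129730, 0.700631898940, -2.111163850559,
    -1.075692940914, 2.674777520748, -2.520890147552,
    -2.134733513698, -2.281759065902, -0.205254346975), 5, 3, byrow = TRUE)
  expect_lt(max(abs(pred - ref)), 1e-6)
  # kernel (Dayal-MacGregor) oracle, computed in-suite
  ko <- kernel_pls2(X, Y, 4)
  expect_lt(max(abs(pred - ko$predict(Xn))), 1e-6)
  # scores orthogonal
  G <- crossprod(m$T)
  expect_lt(max(abs(G - diag(diag(G)))) / max(diag(G)), 1e-6)
  # B reproduces the training fit
  expect_equal(pls_predict(m, X),
               m$T %*% t(m$Q) + matrix(m$y_means, 20, 3, byrow = TRUE),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PLS saturates to OLS at full rank and training R2 grows with LVs", {
  set.seed(14)
  X <- matrix(rnorm(25 * 6), 25, 6)
  y <- X %*% rnorm(6) + rnorm(25, sd = 0.3)
  m <- pls_fit(X, y, 6)
  ols <- ols_fit(X, y)
  expect_equal(pls_predict(m, X), ols_predict(ols, X), tolerance = 1e-8)
  r2s <- vapply(1:6, function(k) r2(y, pls_predict(m, X, n_lv = k)), 0)
  expect_true(all(diff(r2s) >= -1e-10))
  # Y with zero covariance to X: first LV undefined
  expect_error(pls_fit(X, matrix(0, 25, 2), 2), "weight undefined")
})

test_that("LASSO matches OLS at lambda 0, zeroes out above lambda_max, and
           attains the oracle objective", {
  set.seed(15)
  X <- scale(matrix(rnorm(30 * 12), 30, 12))
  y <- X[, 1:4] %*% c(2, -1.5, 1, 0.5) + rnorm(30, sd = 0.2)
  # lambda = 0: OLS coefficients
  l0 <- lasso_fit(X, y, 0)
  ols <- ols_fit(X, y)
  expect_equal(l0$coef, unname(ols$coef[-1, 1]), tolerance = 1e-7)
  # above lambda_max: all zero
  lmax <- lasso_lambda_max(X, y)
  expect_equal(lasso_fit(X, y, lmax * 1.0001)$coef, rep(0, 12))
  # objective within 1e-8 of the independent FISTA oracle
  for (lam in c(0.01, 0.05, 0.2) * lmax) {
    cd <- lasso_fit(X, y, lam, tol = 1e-10)
    bo <- fista_lasso(X, y, lam)
    expect_lt(lasso_objective(X, y, cd$coef, lam) -
                lasso_objective(X, y, bo, lam), 1e-8)
    expect_lt(abs(lasso_objective(X, y, cd$coef, lam) -
                    lasso_objective(X, y, bo, lam)), 1e-8)
  }
  # support size non-increasing along the lambda path
  sizes <- vapply(lmax * 10^seq(-3, 0, length.out = 8), function(lam) {
    length(lasso_fit(X, y, lam)$selected)
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
  # multi-channel selection is the union across channels
  Y2 <- cbind(y, X[, 9] * 3 + rnorm(30, sd = 0.1))
  sel <- lasso_select(X, Y2, 0.1 * lmax)
  expect_true(9 %in% sel)
  expect_true(all(lasso_fit(X, y, 0.1 * lmax)$selected %in% sel))
})
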