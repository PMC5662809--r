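test_that("a single column equal to the response is fitted exactly", {
  y <- c(11, 12.5, 13, 14.2, 15.9, 16.4)
  m <- fit_pls(matrix(y), y, 1)
  expect_equal(predict(m, matrix(y)), y, tolerance = 1e-10)
})

test_that("full-rank PLS reaches the least-squares limit", {
  set.seed(10)
  for (rep in 1:5) {
    x <- matrix(rnorm(30), 10, 3)
    y <- rnorm(10, 13, 1)
    m <- fit_pls(x, y, 3)
    ols <- lm.fit(cbind(1, x), y)
    expect_equal(predict(m, x), unname(ols$fitted.values), tolerance = 1e-8)
  }
})

test_that("score columns are mutually orthogonal", {
  set.seed(11)
  x <- matrix(rnorm(40 * 12), 40, 12)
  y <- x %*% rnorm(12) + rnorm(40, 0, 0.2)
  m <- fit_pls(x, y, 6)
  g <- crossprod(m$x_scores)
  off <- g - diag(diag(g))
  expect_lt(max(abs(off)) / max(diag(g)), 1e-8)
})

test_that("score-space and collapsed-coefficient predictions agree", {
  set.seed(12)
  x <- matrix(rnorm(25 * 8), 25, 8)
  y <- as.numeric(x %*% rnorm(8)) + rnorm(25, 0, 0.5)
  m <- fit_pls(x, y, 5)
  # score path: t_a = deflated-x projections, prediction = sum t_a q_a + mean
  via_scores <- as.numeric(m$x_scores %*% m$y_loadings) + m$y_mean
  via_beta <- predict(m, x)
  expect_equal(via_scores, via_beta, tolerance = 1e-8)
})

test_that("training RMSEC never increases with more latent variables", {
  set.seed(13)
  x <- matrix(rnorm(30 * 10), 30, 10)
  y <- as.numeric(x %*% rnorm(10)) + rnorm(30)
  m <- fit_pls(x, y, 8)
  rmsec <- sapply(1:8, function(a)
    sqrt(mean((predict(m, x, n_lv = a) - y)^2)))
  expect_true(all(diff(rmsec) <= 1e-10))
})

test_that("adding a constant to y shifts predictions by that constant", {
  set.seed(14)
  x <- matrix(rnorm(20 * 5), 20, 5)
  y <- rnorm(20, 13)
  m1 <- fit_pls(x, y, 3)
  m2 <- fit_pls(x, y + 5, 3)
  expect_equal(predict(m2, x), predict(m1, x) + 5, tolerance = 1e-10)
})

test_that("sample order does not change the regression vector", {
  set.seed(15)
  x <- matrix(rnorm(24 * 6), 24, 6)
  y <- rnorm(24, 13)
  perm <- sample(24)
  m1 <- fit_pls(x, y, 4)
  m2 <- fit_pls(x[perm, ], y[perm], 4)
  expect_equal(m1$regression_vector, m2$regression_vector, tolerance = 1e-10)
})

test_that("degenerate inputs are refused", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_pls(x, rep(13, 10), 1), "variance")
  expect_error(fit_pls(x, rnorm(10), 5), "exceeds")
  m <- fit_pls(x, rnorm(10, 13), 2)
  expect_error(predict(m, matrix(1, 2, 3)), "columns")
})

test_that("predicting at the training centre returns the training mean", {
  set.seed(16)
  x <- matrix(rnorm(15 * 4), 15, 4)
  y <- rnorm(15, 13)
  m <- fit_pls(x, y, 3)
  expect_equal(predict(m, matrix(m$x_mean, 1)), mean(y), tolerance = 1e-10)
})

test_that("leave-one-out cross-validation matches a hand-looped oracle", {
  set.seed(17)
  x <- matrix(rnorm(6 * 3), 6, 3)
  y <- rnorm(6, 13)
  folds <- assign_folds(6, 6, 1)             # k = n: leave-one-out
  cv <- cross_validate(x, y, 2, folds)
  loo_pred <- matrix(NA_real_, 6, 2)
  for (i in 1:6) {
    for (a in 1:2) {
      m <- fit_pls(x[-i, ], y[-i], a)
      loo_pred[i, a] <- predict(m, x[i, , drop = FALSE])
    }
  }
  oracle <- sqrt(colMeans((loo_pred - y)^2))
  expect_equal(cv$rmsecv_by_lv, oracle, tolerance = 1e-10)
})

test_that("cross-validation recovers the true latent dimension on noiseless data", {
  set.seed(18)
  n <- 40
  latent <- matrix(rnorm(n * 3), n, 3)
  loadings <- matrix(rnorm(3 * 15), 3, 15)
  x <- latent %*% loadings
  y <- as.numeric(latent %*% c(1, -2, 0.5)) + 13
  folds <- assign_folds(n, 10, 2)
  cv <- cross_validate(x, y, 6, folds)
  expect_equal(cv$chosen_lv, 3L)
  expect_lt(cv$rmsecv_by_lv[3], 1e-6)
  expect_gt(cv$rmsecv_by_lv[2], cv$rmsecv_by_lv[3] + 1e-6)
})

test_that("lv_max = 1 yields a single candidate", {
  set.seed(19)
  x <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10, 13)
  cv <- cross_validate(x, y, 1, assign_folds(10, 5, 3))
  expect_equal(cv$chosen_lv, 1L)
  expect_length(cv$rmsecv_by_lv, 1)
})
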