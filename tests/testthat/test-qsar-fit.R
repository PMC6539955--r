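test_that("OLS on the training set reproduces the published equation", {
  fx <- fixture_data()
  m <- fit_ols(fx$X_train, fx$y_train)
  expect_equal(unname(m$coefficients),
               c(0.183, -0.359, -3.181, 10.627), tolerance = 0.01)
  expect_equal(m$intercept, -9.859, tolerance = 0.01)
})

test_that("OLS recovers exact linear data and matches the normal equations", {
  x <- matrix(1:10, ncol = 1, dimnames = list(NULL, "x"))
  m <- fit_ols(x, 2 * x[, 1] + 1)
  expect_equal(unname(m$coefficients), 2, tolerance = 1e-12)
  expect_equal(m$intercept, 1, tolerance = 1e-12)
  expect_equal(max(abs(m$residuals)), 0, tolerance = 1e-12)

  set.seed(3)
  X <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("d", 1:4)))
  y <- rnorm(50)
  m2 <- fit_ols(X, y)
  oracle <- ols_normal_equations(X, y)
  expect_equal(c(m2$intercept, unname(m2$coefficients)), oracle,
               tolerance = 1e-8)
})

test_that("OLS residuals sum to zero and are orthogonal to descriptors", {
  fx <- fixture_data()
  m <- fit_ols(fx$X_train, fx$y_train)
  expect_lt(abs(sum(m$residuals)), 1e-9)
  expect_lt(max(abs(crossprod(fx$X_train, m$residuals))), 1e-8)
})

test_that("degenerate designs are rejected", {
  X <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_ols(X, rnorm(3)), "n > k")
  X2 <- cbind(x1 = rnorm(10), x2 = 0)
  X2 <- cbind(X2, x3 = X2[, "x1"])
  expect_error(fit_ols(X2, rnorm(10)), "rank deficient")
  expect_error(fit_pls(X2[, c("x1", "x2")], rnorm(10)), "zero-variance")
})

test_that("full-component PLS coincides with OLS", {
  fx <- fixture_data()
  ols <- fit_ols(fx$X_train, fx$y_train)
  pls <- fit_pls(fx$X_train, fx$y_train, n_components = 4)
  expect_equal(pls$coefficients, ols$coefficients, tolerance = 1e-6)
  expect_equal(pls$intercept, ols$intercept, tolerance = 1e-6)

  set.seed(17)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    k <- sample(2:5, 1)
    X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("d", 1:k)))
    y <- rnorm(n)
    a <- fit_ols(X, y)
    b <- fit_pls(X, y, n_components = k)
    expect_equal(predict(b, X), predict(a, X), tolerance = 1e-6)
  }
})

test_that("one-component PLS finds a single dominant direction", {
  set.seed(9)
  n <- 40
  x1 <- rnorm(n)
  # noise columns orthogonalized against the signal (and centered), so the
  # first latent direction is exactly the signal axis
  orth <- function(z) resid(lm(z ~ x1))
  X <- cbind(signal = x1, n1 = orth(rnorm(n)), n2 = orth(rnorm(n)))
  y <- 3 * x1
  m <- fit_pls(X, y, n_components = 1)
  yhat <- predict(m, X)
  expect_gt(cor(y, yhat)^2, 0.99)
})

test_that("PLS on an orthonormal design equals the OLS closed form", {
  set.seed(21)
  Q <- qr.Q(qr(matrix(rnorm(30 * 3), 30, 3)))
  colnames(Q) <- paste0("q", 1:3)
  y <- rnorm(30)
  expect_equal(fit_pls(Q, y, n_components = 3)$coefficients,
               fit_ols(Q, y)$coefficients, tolerance = 1e-8)
})

test_that("predictions reproduce published per-compound values", {
  fx <- fixture_data()
  m <- fit_ols(fx$X_train, fx$y_train)
  x11 <- matrix(c(14.221, -5.762, 0.769, 1.275), 1,
                dimnames = list(NULL, colnames(fx$X_train)))
  expect_equal(predict(m, x11), 5.914, tolerance = 0.01)
  x12 <- fx$desc[fx$desc$compound_id == 12,
                 c("vsurf_DW23", "e_sol", "dipole", "vsurf_G")]
  expect_equal(predict(m, x12), 5.494, tolerance = 0.01)

  zero <- matrix(0, 1, 4, dimnames = list(NULL, colnames(fx$X_train)))
  expect_equal(predict(m, zero), m$intercept)
  expect_error(predict(m, matrix(0, 1, 3)), "descriptor")
})

test_that("predict is affine in the descriptor rows", {
  fx <- fixture_data()
  m <- fit_ols(fx$X_train, fx$y_train)
  x1 <- fx$X_train[1, , drop = FALSE]
  x2 <- fx$X_train[2, , drop = FALSE]
  for (alpha in c(0, 0.3, 0.5, 1)) {
    expect_equal(predict(m, alpha * x1 + (1 - alpha) * x2),
                 alpha * predict(m, x1) + (1 - alpha) * predict(m, x2),
                 tolerance = 1e-10)
  }
})

test_that("the rendered equation matches the published form", {
  fx <- fixture_data()
  m <- fit_ols(fx$X_train, fx$y_train)
  eq <- format_equation(m)
  expect_match(eq, "0.183vsurf_DW23", fixed = TRUE)
  expect_match(eq, "- 9.859", fixed = TRUE)
  expect_match(eq, "- 3.181dipole", fixed = TRUE)
  expect_match(format_equation(m, decimals = 1), "0.2vsurf_DW23", fixed = TRUE)

  m0 <- m
  m0$coefficients[["dipole"]] <- 0
  expect_match(format_equation(m0), "+ 0.000dipole", fixed = TRUE)
})
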