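# Shared fixture accessors and independent oracles.

fixture_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      desc <- load_fixture("descriptors")
      resp <- load_fixture("qsar_results")
      sp <- default_split()
      cache <<- list(
        desc = desc, resp = resp, split = sp,
        cytotox = load_fixture("cytotoxicity"),
        printed = load_fixture("reversal_printed"),
        X_train = flavoqsar:::.descriptor_matrix(desc, sp$train_ids),
        y_train = flavoqsar:::.response_vector(resp, sp$train_ids),
        X_test = flavoqsar:::.descriptor_matrix(desc, sp$test_ids),
        y_test = flavoqsar:::.response_vector(resp, sp$test_ids)
      )
    }
    cache
  }
})

# Independent OLS oracle: normal equations, no lm.
ols_normal_equations <- function(X, y) {
  A <- cbind(1, as.matrix(X))
  as.numeric(solve(crossprod(A), crossprod(A, y)))
}

# Independent LOO oracle: explicit refit loop through the normal equations.
loo_q2_oracle <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  press <- 0
  for (i in seq_len(n)) {
    b <- ols_normal_equations(X[-i, , drop = FALSE], y[-i])
    press <- press + (y[i] - (b[1] + sum(X[i, ] * b[-1])))^2
  }
  as.numeric(1 - press / sum((y - mean(y))^2))
}

# Numerical bisection oracle for the absolute-50% crossing of a 4PL curve.
bisect_ic50 <- function(top, bottom, ic50, hill,
                        lower = 1e-8, upper = 1e8, tol = 1e-12) {
  f <- function(c) flavoqsar:::.fourpl(c, top, bottom, ic50, hill) - 0.5
  stopifnot(f(lower) * f(upper) < 0)
  for (i in 1:200) {
    mid <- sqrt(lower * upper)  # bisect on the log axis
    if (f(lower) * f(mid) <= 0) upper <- mid else lower <- mid
    if (upper / lower - 1 < tol) break
  }
  sqrt(lower * upper)
}
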