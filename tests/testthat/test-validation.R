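test_that("training-fit statistics reproduce the published block", {
  fx <- fixture_data()
  m <- fit_ols(fx$X_train, fx$y_train)
  fs <- fit_statistics(m, fx$X_train, fx$y_train)
  expect_equal(fs$r2, 0.892, tolerance = 0.0005 / 0.892)
  expect_equal(fs$r2_adj, 0.869, tolerance = 0.0005 / 0.869)
  expect_equal(fs$rmse, 0.492, tolerance = 0.0005 / 0.492)
  expect_equal(fs$f_stat, 39.073, tolerance = 0.005 / 39.073)
  expect_lt(fs$p_value, 0.01)
})

test_that("fit statistics match a from-first-principles oracle", {
  set.seed(8)
  X <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, paste0("d", 1:3)))
  y <- X %*% c(1, -2, 0.5) + rnorm(30)
  m <- fit_ols(X, y)
  fs <- fit_statistics(m, X, y)
  b <- ols_normal_equations(X, y)
  yhat <- b[1] + X %*% b[-1]
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  n <- 30; k <- 3
  expect_equal(fs$r2, 1 - sse / sst, tolerance = 1e-10)
  expect_equal(fs$r2_adj, 1 - (1 - fs$r2) * (n - 1) / (n - k - 1),
               tolerance = 1e-10)
  expect_equal(fs$rmse, sqrt(sse / (n - k - 1)), tolerance = 1e-10)
  expect_equal(fs$f_stat, (fs$r2 / k) / ((1 - fs$r2) / (n - k - 1)),
               tolerance = 1e-10)
  expect_equal(fs$p_value, pf(fs$f_stat, k, n - k - 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # perfect linear data
  Xp <- matrix(1:12, ncol = 1, dimnames = list(NULL, "x"))
  mp <- fit_ols(Xp, 3 * Xp[, 1] - 2)
  fsp <- fit_statistics(mp, Xp, 3 * Xp[, 1] - 2)
  expect_equal(fsp$r2, 1, tolerance = 1e-12)
  expect_equal(fsp$rmse, 0, tolerance = 1e-10)
})

test_that("LOO Q2 reproduces the published value and the brute-force loop", {
  fx <- fixture_data()
  q2 <- q2_loo(fx$X_train, fx$y_train)
  expect_equal(q2, 0.829, tolerance = 0.005)
  expect_equal(q2, loo_q2_oracle(fx$X_train, fx$y_train), tolerance = 1e-9)

  # tiny instances, exact agreement with the refit loop
  set.seed(13)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
    y <- rnorm(n)
    expect_equal(q2_loo(X, y), loo_q2_oracle(X, y), tolerance = 1e-9)
  }

  expect_error(q2_loo(fx$X_train, rep(1, 24)), "zero variance")
})

test_that("Q2 does not exceed the training R2 on the study data", {
  fx <- fixture_data()
  m <- fit_ols(fx$X_train, fx$y_train)
  fs <- fit_statistics(m, fx$X_train, fx$y_train)
  expect_lt(q2_loo(fx$X_train, fx$y_train), fs$r2)
})

test_that("external R2 is the squared Pearson form, not the PRESS form", {
  fx <- fixture_data()
  m <- fit_ols(fx$X_train, fx$y_train)
  r2p <- r2_pred(m, fx$X_test, fx$y_test)
  expect_equal(r2p, 0.905, tolerance = 0.005)

  # the PRESS-based alternative is a different, larger number here
  press_form <- 1 - sum((fx$y_test - predict(m, fx$X_test))^2) /
    sum((fx$y_test - mean(fx$y_train))^2)
  expect_equal(press_form, 0.957, tolerance = 0.005)
  expect_gt(abs(r2p - press_form), 0.03)

  # squared correlation of the published experimental/predicted test rows
  pub <- fx$resp[fx$resp$compound_id %in% fx$split$test_ids, ]
  expect_equal(cor(pub$ic50_experimental, pub$ic50_predicted)^2, 0.904,
               tolerance = 0.005)

  perfect <- m
  expect_equal(r2_pred(m, fx$X_train, predict(m, fx$X_train)), 1,
               tolerance = 1e-12)
  expect_error(r2_pred(m, fx$X_test, rep(1, 7)), "undefined")
})

test_that("the reliability gate applies both strict thresholds", {
  ok <- reliability_gate(0.829, 0.905)
  expect_equal(ok$gate, "reliable")
  expect_length(ok$gate_reasons, 0)

  g1 <- reliability_gate(0.5, 0.9)
  expect_equal(g1$gate, "unreliable")
  expect_match(g1$gate_reasons, "Q2", all = FALSE)

  g2 <- reliability_gate(0.9, 0.3)
  expect_equal(g2$gate, "unreliable")
  expect_match(g2$gate_reasons, "R2_pred", all = FALSE)

  g3 <- reliability_gate(0.9, NA)
  expect_equal(g3$gate, "unreliable")
})

test_that("the per-compound prediction table matches the published one", {
  fx <- fixture_data()
  m <- fit_ols(fx$X_train, fx$y_train)
  tab <- residual_table(m, fx$desc, fx$resp, published = fx$resp)
  expect_equal(nrow(tab), 31)
  expect_equal(tab$residual[tab$compound_id == 1], 0.193,
               tolerance = 0.01 / 0.193)
  expect_equal(tab$residual[tab$compound_id == 3], -0.910,
               tolerance = 0.01 / 0.910)
  expect_lt(abs(sum(tab$residual[tab$split_role == "train"])), 1e-9)
  expect_lte(max(abs(tab$delta_vs_published)), 0.01)
  expect_equal(sum(tab$split_role == "test"), 7)
})

test_that("all statistics are invariant under affine descriptor rescaling", {
  fx <- fixture_data()
  m <- fit_ols(fx$X_train, fx$y_train)
  fs <- fit_statistics(m, fx$X_train, fx$y_train)
  q2 <- q2_loo(fx$X_train, fx$y_train)
  r2p <- r2_pred(m, fx$X_test, fx$y_test)

  A <- fx$X_train
  B <- fx$X_test
  scales <- c(2, -0.5, 10, 0.01)
  shifts <- c(-3, 7, 0.2, 100)
  A2 <- sweep(sweep(A, 2, scales, "*"), 2, shifts, "+")
  B2 <- sweep(sweep(B, 2, scales, "*"), 2, shifts, "+")
  m2 <- fit_ols(A2, fx$y_train)
  fs2 <- fit_statistics(m2, A2, fx$y_train)
  expect_equal(fs2$r2, fs$r2, tolerance = 1e-10)
  expect_equal(fs2$rmse, fs$rmse, tolerance = 1e-10)
  expect_equal(fs2$f_stat, fs$f_stat, tolerance = 1e-8)
  expect_equal(q2_loo(A2, fx$y_train), q2, tolerance = 1e-10)
  expect_equal(r2_pred(m2, B2, fx$y_test), r2p, tolerance = 1e-10)
})
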