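test_that("generators are pure functions of spec and seed", {
  spec <- synthetic_spec(seed = 99)
  expect_identical(gen_descriptor_matrix(spec), gen_descriptor_matrix(spec))
  X <- gen_descriptor_matrix(spec)
  expect_identical(
    gen_response(X, spec$true_coefficients, spec$true_intercept, 0.5, seed = 99),
    gen_response(X, spec$true_coefficients, spec$true_intercept, 0.5, seed = 99))
  expect_identical(gen_viability_plate(2, seed = 4),
                   gen_viability_plate(2, seed = 4))
})

test_that("invalid specs are rejected before any generation", {
  bad <- matrix(c(1, 0.99, 0.99, 0.99, 1, 0.99, 0.99, 0.99, 0.5), 3, 3)
  expect_error(synthetic_spec(target_correlation = bad), "unit diagonal")
  bad2 <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_error(
    synthetic_spec(target_correlation = bad2,
                   descriptor_means = c(0, 0), descriptor_sds = c(1, 1),
                   true_coefficients = c(1, 1)),
    "positive definite")
  expect_error(synthetic_spec(noise_sd = -1), "noise_sd")
  expect_error(synthetic_spec(n_compounds = 2), "n_compounds")
})

test_that("sampled correlation structure follows the target", {
  id4 <- diag(4)
  dimnames(id4) <- rep(list(paste0("v", 1:4)), 2)
  spec <- synthetic_spec(n_compounds = 2000, target_correlation = id4,
                         descriptor_means = rep(0, 4),
                         descriptor_sds = rep(1, 4),
                         true_coefficients = rep(0, 4), seed = 2)
  X <- as.matrix(gen_descriptor_matrix(spec)[, -1])
  R <- cor(X)
  diag(R) <- 0
  expect_lt(max(abs(R)), 0.1)

  tgt <- diag(4)
  tgt[1, 2] <- tgt[2, 1] <- 0.9
  dimnames(tgt) <- rep(list(paste0("v", 1:4)), 2)
  spec2 <- synthetic_spec(n_compounds = 2000, target_correlation = tgt,
                          descriptor_means = rep(0, 4),
                          descriptor_sds = rep(1, 4),
                          true_coefficients = rep(0, 4), seed = 3)
  X2 <- as.matrix(gen_descriptor_matrix(spec2)[, -1])
  expect_lt(abs(cor(X2)[1, 2] - 0.9), 0.05)
})

test_that("noise-free responses are recovered exactly by OLS", {
  spec <- synthetic_spec(seed = 6)
  X <- gen_descriptor_matrix(spec)
  y <- gen_response(X, spec$true_coefficients, spec$true_intercept,
                    noise_sd = 0, seed = 6)
  m <- fit_ols(as.matrix(X[, -1]), y)
  expect_equal(unname(m$coefficients), unname(spec$true_coefficients),
               tolerance = 1e-9)
  expect_equal(m$intercept, spec$true_intercept, tolerance = 1e-9)
  expect_error(gen_response(X[, -1], c(1, 2), 0), "coefficient length")
})

test_that("coefficients are recovered at study-scale n and noise", {
  specs <- lapply(1:200, function(s) synthetic_spec(seed = s))
  ests <- vapply(specs, function(spec) {
    X <- gen_descriptor_matrix(spec)
    y <- gen_response(X, spec$true_coefficients, spec$true_intercept,
                      spec$noise_sd, seed = spec$seed)
    m <- fit_ols(as.matrix(X[, -1]), y)
    c(m$coefficients,
      fit_statistics(m, as.matrix(X[, -1]), y)$r2)
  }, numeric(5))
  beta <- synthetic_spec()$true_coefficients
  mean_beta <- rowMeans(ests[1:4, ])
  expect_true(all(abs(mean_beta - beta) / abs(beta) < 0.10))
  expect_lt(abs(mean(ests[5, ]) - 0.892), 0.1)
})

test_that("overwhelming noise drives the fitted R2 toward zero", {
  r2s <- vapply(1:200, function(s) {
    spec <- synthetic_spec(seed = s, noise_sd = 100)
    X <- gen_descriptor_matrix(spec)
    y <- gen_response(X, spec$true_coefficients, spec$true_intercept,
                      spec$noise_sd, seed = s)
    Xm <- as.matrix(X[, -1])
    fit_statistics(fit_ols(Xm, y), Xm, y)$r2
  }, 0)
  expect_lt(median(r2s), 0.3)
})

test_that("decoy pools label ground truth and reduce to the signal matrix", {
  spec <- synthetic_spec(seed = 12)
  pool0 <- gen_decoy_pool(spec, 0)
  expect_equal(as.data.frame(pool0)[names(gen_descriptor_matrix(spec))],
               gen_descriptor_matrix(spec))
  pool <- gen_decoy_pool(spec, 16)
  expect_equal(ncol(pool), 1 + 4 + 16)
  expect_setequal(attr(pool, "signal_columns"),
                  c("vsurf_DW23", "e_sol", "dipole", "vsurf_G"))
})

test_that("stepwise selection recovers planted signal among decoys", {
  hits <- vapply(1:100, function(s) {
    spec <- synthetic_spec(n_compounds = 24, seed = s)
    pool <- gen_decoy_pool(spec, 16)
    y <- gen_response(pool[attr(pool, "signal_columns")],
                      spec$true_coefficients, spec$true_intercept,
                      spec$noise_sd, seed = s)
    sel <- stepwise_mlr_select(pool[setdiff(names(pool), "compound_id")], y)
    sum(attr(pool, "signal_columns") %in% sel$selected)
  }, 0L)
  # vsurf_G's contribution (|10.627| x SD 0.048 ~ 0.51 uM) sits at the noise
  # floor, so full 4/4 recovery is not expected every run
  expect_gte(mean(hits >= 3), 0.6)
})

test_that("a duplicated signal column is caught by the collinearity filter", {
  spec <- synthetic_spec(n_compounds = 24, seed = 31)
  pool <- gen_decoy_pool(spec, 2)
  pool$decoy_01 <- pool$vsurf_DW23
  y <- stats::setNames(
    gen_response(pool[attr(pool, "signal_columns")], spec$true_coefficients,
                 spec$true_intercept, spec$noise_sd, seed = 31),
    pool$compound_id)
  Xm <- as.matrix(pool[setdiff(names(pool), "compound_id")])
  rownames(Xm) <- pool$compound_id
  cm <- pearson_matrix(y, Xm)
  res <- collinearity_filter(cm)
  expect_length(intersect(c("vsurf_DW23", "decoy_01"), res$selected), 1)
})

test_that("synthetic plates recover the true IC50", {
  plate0 <- gen_viability_plate(ic50 = 2, cv_noise = 0, seed = 1)
  v0 <- with(plate0, normalize_viability(
    absorbance, mean(absorbance[concentration == 0])))
  fit0 <- fit_dose_response(plate0$concentration, v0)
  expect_equal(fit0$ic50, 2, tolerance = 1e-6)

  rel_err <- vapply(1:200, function(s) {
    plate <- gen_viability_plate(ic50 = 2, cv_noise = 0.05, replicates = 3,
                                 seed = s)
    v <- with(plate, normalize_viability(
      absorbance, mean(absorbance[concentration == 0])))
    abs(fit_dose_response(plate$concentration, v)$ic50 - 2) / 2
  }, 0)
  expect_lt(median(rel_err), 0.10)
})

test_that("the noise-free pipeline is self-consistent end to end", {
  spec <- synthetic_spec(n_compounds = 31, noise_sd = 0, seed = 23)
  X <- gen_descriptor_matrix(spec)
  y <- gen_response(X, spec$true_coefficients, spec$true_intercept, 0,
                    seed = 23)
  Xm <- as.matrix(X[, -1])
  rownames(Xm) <- X$compound_id
  names(y) <- X$compound_id
  sel <- suppressWarnings(stepwise_mlr_select(as.data.frame(Xm[1:24, ]),
                                              y[1:24]))
  expect_setequal(sel$selected, colnames(Xm))
  m <- fit_ols(Xm[1:24, ], y[1:24])
  v <- validate_model(m, list(X = Xm[1:24, ], y = y[1:24]),
                      list(X = Xm[25:31, ], y = y[25:31]))
  expect_equal(v$r2, 1, tolerance = 1e-9)
  expect_equal(v$q2_loo, 1, tolerance = 1e-9)
  expect_equal(v$gate, "reliable")
})
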