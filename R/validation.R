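#' Training-fit summary statistics
#'
#' Computes the standard goodness-of-fit block for a linear QSAR model:
#' R2 = 1 - SSE/SST, adjusted R2 = 1 - (1 - R2)(n - 1)/(n - k - 1),
#' RMSE = sqrt(SSE/(n - k - 1)) (residual degrees of freedom in the
#' denominator), the overall F statistic (R2/k) / ((1 - R2)/(n - k - 1)) and
#' its p-value on (k, n - k - 1) degrees of freedom.
#'
#' @param model a fitted `qsar_model`.
#' @param X the training descriptor matrix the model was fit on.
#' @param y the training response vector.
#' @return list with `r2`, `r2_adj`, `rmse`, `f_stat`, `p_value`, `n`, `k`,
#'   `sse`, `sst`.
#' @export
fit_statistics <- function(model, X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- length(model$descriptor_names)
  if (n <= k + 1) {
    stop("fit_statistics: need n > k + 1", call. = FALSE)
  }
  yhat <- stats::predict(model, X)
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
  f_stat <- (r2 / k) / ((1 - r2) / (n - k - 1))
  list(
    r2 = r2,
    r2_adj = r2_adj,
    rmse = sqrt(sse / (n - k - 1)),
    f_stat = f_stat,
    p_value = stats::pf(f_stat, k, n - k - 1, lower.tail = FALSE),
    n = n, k = k, sse = sse, sst = sst
  )
}

#' Leave-one-out cross-validated Q2
#'
#' For each training row, the model is refit on the remaining n - 1 rows and
#' used to predict the held-out response. Q2 = 1 - PRESS/SST, where PRESS is
#' the sum of squared held-out prediction errors and SST sums squared
#' deviations of all n responses from the full training mean (not per-fold
#' means).
#'
#' @param X training descriptor matrix.
#' @param y training response vector.
#' @param fitter fitting function `(X, y) -> qsar_model`; default [fit_ols()].
#' @return Q2, a number at most 1 (negative when the model predicts worse
#'   than the training mean).
#' @export
q2_loo <- function(X, y, fitter = fit_ols) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("q2_loo: need at least 3 rows", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    stop("q2_loo: response has zero variance; Q2 undefined", call. = FALSE)
  }
  press <- 0
  for (i in seq_len(n)) {
    m <- fitter(X[-i, , drop = FALSE], y[-i])
    press <- press + (y[i] - stats::predict(m, X[i, , drop = FALSE]))^2
  }
  as.numeric(1 - press / sst)
}

#' External predictive R2 on a test set
#'
#' The squared Pearson correlation between observed and model-predicted
#' responses on compounds not used in fitting. This is the plain squared
#' correlation, not the PRESS-based 1 - PRESS/SST form.
#'
#' @param model a fitted `qsar_model`.
#' @param X_test test-set descriptor matrix (>= 3 rows).
#' @param y_test test-set responses.
#' @return squared Pearson correlation in `[0, 1]`.
#' @export
r2_pred <- function(model, X_test, y_test) {
  X_test <- as.matrix(X_test)
  if (nrow(X_test) < 3) {
    stop("r2_pred: need >= 3 test rows for a defined correlation",
         call. = FALSE)
  }
  yhat <- stats::predict(model, X_test)
  if (stats::sd(yhat) == 0 || stats::sd(y_test) == 0) {
    stop("r2_pred: constant predictions or responses; correlation undefined",
         call. = FALSE)
  }
  stats::cor(y_test, yhat)^2
}

#' Model reliability gate
#'
#' A QSAR model is accepted as reliable when both internal and external
#' criteria hold strictly: LOO Q2 > 0.5 and test-set predictive R2 > 0.6.
#'
#' @param q2 leave-one-out Q2 (or `NA` if unavailable).
#' @param r2p external predictive R2 (or `NA` if unavailable).
#' @return list with `gate` (`"reliable"` / `"unreliable"`) and
#'   `gate_reasons` (character vector of failed criteria, empty if reliable).
#' @export
reliability_gate <- function(q2, r2p) {
  reasons <- character(0)
  if (is.na(q2) || q2 <= 0.5) {
    reasons <- c(reasons, sprintf("Q2 (%s) not > 0.5",
                                  if (is.na(q2)) "unavailable" else
                                    formatC(q2, digits = 3, format = "f")))
  }
  if (is.na(r2p) || r2p <= 0.6) {
    reasons <- c(reasons, sprintf("R2_pred (%s) not > 0.6",
                                  if (is.na(r2p)) "unavailable" else
                                    formatC(r2p, digits = 3, format = "f")))
  }
  list(gate = if (length(reasons)) "unreliable" else "reliable",
       gate_reasons = reasons)
}

#' Per-compound predicted IC50 and residuals
#'
#' Applies the fitted model to every compound (training and test alike) and
#' tabulates prediction and residual, optionally diffing the predictions
#' against a published prediction column.
#'
#' @param model a fitted `qsar_model`.
#' @param descriptors full descriptor table (`compound_id` + descriptor
#'   columns).
#' @param responses table with `compound_id` and `ic50_experimental`.
#' @param spec split specification used in fitting, to label each row's role.
#' @param published optional table with `compound_id` and `ic50_predicted`
#'   to compare against.
#' @return data frame: `compound_id`, `ic50_experimental`, `ic50_predicted`,
#'   `residual`, `split_role`, and `delta_vs_published` when `published`
#'   is given.
#' @export
residual_table <- function(model, descriptors, responses,
                           spec = default_split(), published = NULL) {
  ids <- sort(responses$compound_id)
  X <- .descriptor_matrix(descriptors, ids)
  y <- .response_vector(responses, ids)
  yhat <- stats::predict(model, X)
  out <- data.frame(
    compound_id = ids,
    ic50_experimental = unname(y),
    ic50_predicted = yhat,
    residual = unname(y) - yhat,
    split_role = ifelse(ids %in% spec$test_ids, "test", "train")
  )
  if (!is.null(published)) {
    m <- match(ids, published$compound_id)
    out$delta_vs_published <- out$ic50_predicted - published$ic50_predicted[m]
  }
  out
}

#' Full validation report for a fitted model
#'
#' Bundles [fit_statistics()], [q2_loo()], [r2_pred()] and the
#' [reliability_gate()] into a single report. When the test set is empty or
#' too small for a defined correlation, `r2_pred` is reported `NA` and the
#' gate fails with that reason.
#'
#' @param model fitted `qsar_model` (trained on the training partition).
#' @param train list with `X`, `y` for the training set.
#' @param test list with `X`, `y` for the test set (may have 0 rows).
#' @param fitter fitting function used for the LOO refits.
#' @return object of class `validation_report`.
#' @export
validate_model <- function(model, train, test, fitter = fit_ols) {
  fs <- fit_statistics(model, train$X, train$y)
  q2 <- q2_loo(train$X, train$y, fitter = fitter)
  r2p <- if (!is.null(test$X) && nrow(as.matrix(test$X)) >= 3) {
    r2_pred(model, test$X, test$y)
  } else NA_real_
  gate <- reliability_gate(q2, r2p)
  structure(c(fs, list(q2_loo = q2, r2_pred = r2p), gate),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "R2 = %.3f, R2_adj = %.3f, Q2 = %.3f, F = %.3f, p = %.3g, RMSE = %.3f, R2_pred = %s\n",
    x$r2, x$r2_adj, x$q2_loo, x$f_stat, x$p_value, x$rmse,
    if (is.na(x$r2_pred)) "NA" else sprintf("%.3f", x$r2_pred)))
  cat("gate:", x$gate,
      if (length(x$gate_reasons)) paste0("(", paste(x$gate_reasons, collapse = "; "), ")"),
      "\n")
  invisible(x)
}
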