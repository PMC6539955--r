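#' Fit the linear QSAR model by ordinary least squares
#'
#' Least-squares fit of IC50 on the descriptor columns, with intercept.
#' Residuals are orthogonal to every descriptor column and sum to zero.
#'
#' @param X numeric matrix or data frame of descriptors (rows = compounds,
#'   row names = compound ids when available).
#' @param y numeric response vector (IC50, uM).
#' @return an object of class `qsar_model`: list with `descriptor_names`,
#'   `coefficients` (raw descriptor scale), `intercept`, `method = "ols"`,
#'   `training_ids`, `fitted`, `residuals` and the underlying `lm` fit.
#' @export
#' @examples
#' desc <- load_fixture("descriptors")
#' resp <- load_fixture("qsar_results")
#' tr <- default_split()$train_ids
#' m <- fit_ols(flavoqsar:::.descriptor_matrix(desc, tr),
#'              flavoqsar:::.response_vector(resp, tr))
#' format_equation(m)
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) <= ncol(X) + 1) {
    stop("fit_ols: need n > k + 1 observations", call. = FALSE)
  }
  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    stop("fit_ols: design matrix is rank deficient", call. = FALSE)
  }
  fit <- stats::lm(y ~ X)
  beta <- stats::coef(fit)
  structure(list(
    descriptor_names = colnames(X),
    coefficients = stats::setNames(beta[-1], colnames(X)),
    intercept = unname(beta[1]),
    method = "ols",
    n_components = NULL,
    training_ids = rownames(X),
    n = nrow(X),
    fitted = stats::setNames(unname(stats::fitted(fit)), rownames(X)),
    residuals = stats::setNames(unname(stats::resid(fit)), rownames(X)),
    lm_fit = fit
  ), class = "qsar_model")
}

#' Fit the linear QSAR model by NIPALS partial least squares
#'
#' PLS1 regression via the NIPALS algorithm on autoscaled descriptors
#' (column mean 0, SD 1); the latent-variable solution is back-transformed so
#' that coefficients and intercept are reported on the raw descriptor scale,
#' directly comparable to [fit_ols()]. With `n_components` equal to the
#' design rank, PLS reproduces the OLS solution.
#'
#' @param X numeric matrix or data frame of descriptors.
#' @param y numeric response vector.
#' @param n_components number of latent variables, between 1 and `ncol(X)`;
#'   default uses all (full rank, OLS-equivalent).
#' @return a `qsar_model` with `method = "pls"` and `n_components` set.
#' @export
fit_pls <- function(X, y, n_components = ncol(X)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  k <- ncol(X)
  if (n_components < 1 || n_components > k) {
    stop("fit_pls: n_components must be in 1..ncol(X)", call. = FALSE)
  }
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("fit_pls: zero-variance column '",
         colnames(X)[sds == 0][1], "' cannot be autoscaled", call. = FALSE)
  }
  Xs <- scale(X, center = mu, scale = sds)
  ybar <- mean(y)
  yc <- y - ybar

  E <- Xs
  f <- yc
  W <- P <- matrix(0, k, n_components)
  b <- numeric(n_components)
  Tm <- matrix(0, nrow(X), n_components)
  for (a in seq_len(n_components)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { # residual X carries no covariance with y; stop early
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1), drop = FALSE]
      b <- b[seq_len(a - 1)]
      break
    }
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    p <- crossprod(E, t) / tt
    b[a] <- sum(t * f) / tt
    W[, a] <- w
    P[, a] <- p
    Tm[, a] <- t
    E <- E - tcrossprod(t, p)
    f <- f - b[a] * t
  }
  # regression vector on the autoscaled space: B = W (P'W)^-1 b
  Bs <- W %*% solve(crossprod(P, W), b)
  beta <- as.numeric(Bs) / sds
  intercept <- ybar - sum(beta * mu)
  fitted <- as.numeric(X %*% beta + intercept)
  structure(list(
    descriptor_names = colnames(X),
    coefficients = stats::setNames(beta, colnames(X)),
    intercept = intercept,
    method = "pls",
    n_components = length(b),
    training_ids = rownames(X),
    n = nrow(X),
    fitted = stats::setNames(fitted, rownames(X)),
    residuals = stats::setNames(y - fitted, rownames(X)),
    scores = Tm
  ), class = "qsar_model")
}

#' Predict IC50 from a fitted QSAR model
#'
#' @param object a `qsar_model`.
#' @param newdata matrix or data frame whose columns include the model's
#'   descriptors (matched by name when names are present).
#' @param ... unused.
#' @return numeric vector of predicted IC50 (uM).
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata))
  if (!is.null(colnames(X))) {
    missing <- setdiff(object$descriptor_names, colnames(X))
    if (length(missing)) {
      stop("predict: descriptor column(s) missing: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    X <- X[, object$descriptor_names, drop = FALSE]
  } else if (ncol(X) != length(object$descriptor_names)) {
    stop("predict: expected ", length(object$descriptor_names),
         " descriptor columns, got ", ncol(X), call. = FALSE)
  }
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    stop("predict: missing descriptor value in row ",
         which(rowSums(is.na(X)) > 0)[1], call. = FALSE)
  }
  as.numeric(X %*% object$coefficients + object$intercept)
}

#' Render the model equation as text
#'
#' Formats the fitted model as `IC50 = c1*name1 + c2*name2 + ... + b0`, with
#' signs folded into the operators and coefficients rounded to `decimals`.
#' Zero coefficients are kept, not elided.
#'
#' @param model a `qsar_model`.
#' @param decimals decimal places, default 3.
#' @return a single character string.
#' @export
format_equation <- function(model, decimals = 3) {
  stopifnot(inherits(model, "qsar_model"))
  fmt <- function(x) formatC(abs(x), format = "f", digits = decimals)
  co <- model$coefficients
  terms <- paste0(fmt(co), names(co))
  ops <- ifelse(co < 0, "-", "+")
  eq <- paste0("IC50 = ",
               if (ops[1] == "-") "-" else "", terms[1])
  for (i in seq_along(terms)[-1]) {
    eq <- paste(eq, ops[i], terms[i])
  }
  paste(eq, if (model$intercept < 0) "-" else "+", fmt(model$intercept))
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("QSAR model (%s%s, n = %d):\n", toupper(x$method),
              if (!is.null(x$n_components))
                paste0(", ", x$n_components, " component(s)") else "",
              x$n))
  cat(" ", format_equation(x), "\n")
  invisible(x)
}

#' @export
coef.qsar_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
residuals.qsar_model <- function(object, ...) object$residuals
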