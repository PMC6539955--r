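#' Normalize raw well signal to viability fractions
#'
#' Viability is the ratio of a well's absorbance to the mean absorbance of
#' vehicle (drug-free) wells, so vehicle wells map to 1.0 on average.
#'
#' @param raw_signal numeric vector of per-well absorbances.
#' @param vehicle_mean positive mean absorbance of the vehicle wells.
#' @return viability fractions, same length as `raw_signal`.
#' @export
normalize_viability <- function(raw_signal, vehicle_mean) {
  if (!is.numeric(vehicle_mean) || length(vehicle_mean) != 1 ||
      !is.finite(vehicle_mean) || vehicle_mean <= 0) {
    stop("normalize_viability: vehicle_mean must be a positive number",
         call. = FALSE)
  }
  raw_signal / vehicle_mean
}

# 4-parameter logistic, decreasing in concentration for hill > 0:
#   v(c) = bottom + (top - bottom) / (1 + (c / ic50)^hill)
.fourpl <- function(conc, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit of viability against concentration, the standard
#' model for MTT-type cytotoxicity data. Zero-concentration wells are used
#' for normalization upstream and excluded here (the model is defined on the
#' log-concentration axis). The optimiser is Levenberg-Marquardt
#' ([minpack.lm::nlsLM]) with log-spaced initialisation of the midpoint and a
#' multi-start over hill slopes 0.5, 1 and 2; the best-SSE start wins.
#'
#' @param concentration nonnegative concentrations (uM); at least 5 distinct
#'   positive values are required.
#' @param viability viability fractions from [normalize_viability()].
#' @return an object of class `dose_response_fit`: list with `top`, `bottom`,
#'   `ic50` (the curve midpoint, uM), `hill`, `sse`, `n`, and a logical
#'   `no_inhibition` flag set when viability trends upward with concentration.
#' @export
#' @examples
#' conc <- rep(c(0.25, 0.5, 1, 2, 4, 8, 16), each = 3)
#' v <- 1 / (1 + (conc / 2))  # ideal curve, midpoint 2 uM
#' fit <- fit_dose_response(conc, v)
#' fit$ic50
fit_dose_response <- function(concentration, viability) {
  keep <- concentration > 0
  conc <- concentration[keep]
  v <- viability[keep]
  if (length(unique(conc)) < 5) {
    stop("fit_dose_response: need >= 5 distinct positive concentrations",
         call. = FALSE)
  }
  if (stats::sd(v) == 0) {
    stop("fit_dose_response: no response (viability is constant)",
         call. = FALSE)
  }
  slope <- stats::coef(stats::lm(v ~ log(conc)))[2]
  no_inhibition <- is.finite(slope) && slope > 0
  if (no_inhibition) {
    warning("fit_dose_response: viability increases with concentration; ",
            "no inhibition detected", call. = FALSE)
  }

  dat <- data.frame(conc = conc, v = v)
  top0 <- max(v)
  bottom0 <- min(v)
  # log-spaced midpoint start: concentration whose observed mean viability is
  # nearest the half-height
  half <- (top0 + bottom0) / 2
  agg <- tapply(v, conc, mean)
  ic50_0 <- as.numeric(names(agg))[which.min(abs(agg - half))]
  best <- NULL
  for (h0 in c(0.5, 1, 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ bottom + (top - bottom) / (1 + (conc / ic50)^hill),
        data = dat,
        start = list(top = top0, bottom = bottom0, ic50 = ic50_0, hill = h0),
        lower = c(top = -Inf, bottom = -Inf, ic50 = 1e-9, hill = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse) {
        p <- as.list(stats::coef(fit))
        best <- list(top = p$top, bottom = p$bottom, ic50 = p$ic50,
                     hill = p$hill, sse = sse)
      }
    }
  }
  if (is.null(best)) {
    stop("fit_dose_response: no start converged (n = ", length(conc),
         ", viability range ", signif(bottom0, 3), "-", signif(top0, 3), ")",
         call. = FALSE)
  }
  sse_flat <- sum((v - mean(v))^2)
  if (best$sse > sse_flat + 1e-8) {
    stop("fit_dose_response: 4PL fit worse than flat-line model",
         call. = FALSE)
  }
  structure(c(best, list(sse_flat = sse_flat, n = length(conc),
                         conc_range = range(conc),
                         no_inhibition = no_inhibition)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("4PL fit (n = %d): IC50 = %.4g uM, hill = %.3g, top = %.3g, bottom = %.3g, SSE = %.3g\n",
              x$n, x$ic50, x$hill, x$top, x$bottom, x$sse))
  invisible(x)
}

#' Absolute-50% IC50 from a fitted dose-response curve
#'
#' Returns the concentration at which the fitted curve crosses viability 0.5
#' (50% of the vehicle level), by closed-form inversion of the 4PL. For the
#' symmetric case top = 1, bottom = 0 this equals the curve midpoint.
#'
#' @param fit a `dose_response_fit` object.
#' @return positive concentration (uM).
#' @export
ic50_from_fit <- function(fit) {
  stopifnot(inherits(fit, "dose_response_fit"))
  lo <- min(fit$top, fit$bottom)
  hi <- max(fit$top, fit$bottom)
  if (!(lo < 0.5 && 0.5 < hi)) {
    stop(sprintf(
      "ic50_from_fit: fitted curve spans (%.3g, %.3g) and never crosses 0.5",
      lo, hi), call. = FALSE)
  }
  fit$ic50 * ((fit$top - 0.5) / (0.5 - fit$bottom))^(1 / fit$hill)
}
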