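# Seed substreams: each generator advances the RNG from its own fixed offset
# of the spec seed, so stages are individually reproducible.
.substream <- c(descriptors = 101L, response = 202L, decoys = 303L,
                plate = 404L)

# Inter-descriptor correlation structure of the study descriptor set
# (vsurf_DW23, e_sol, dipole, vsurf_G over the training compounds).
.study_correlation <- function() {
  R <- matrix(c(
     1.000,  0.006, -0.268, -0.212,
     0.006,  1.000, -0.464,  0.230,
    -0.268, -0.464,  1.000,  0.164,
    -0.212,  0.230,  0.164,  1.000), 4, 4)
  dimnames(R) <- rep(list(c("vsurf_DW23", "e_sol", "dipole", "vsurf_G")), 2)
  R
}

#' Specification for synthetic study-like data
#'
#' Defines the generative model used by the synthetic-data stage: descriptor
#' rows are drawn from a multivariate normal whose marginal means/SDs and
#' correlation structure default to the study descriptor table (31 flavonoids,
#' four descriptors), and IC50 responses follow the linear model
#' `y = X beta + b0 + N(0, noise_sd)` with the study model's coefficients and
#' a noise SD at the magnitude of the study fit's residual error (0.49 uM).
#'
#' @param n_compounds number of rows to generate (default 24, the training-set
#'   size).
#' @param target_correlation symmetric positive-definite correlation matrix
#'   with unit diagonal.
#' @param descriptor_means,descriptor_sds per-column marginals.
#' @param true_coefficients,true_intercept parameters of the linear response.
#' @param noise_sd response noise SD (uM), nonnegative.
#' @param seed integer master seed; generators derive fixed substreams of it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 24,
                           target_correlation = .study_correlation(),
                           descriptor_means = c(vsurf_DW23 = 2.359,
                                                e_sol = -2.662,
                                                dipole = 0.864,
                                                vsurf_G = 1.296),
                           descriptor_sds = c(vsurf_DW23 = 4.023,
                                              e_sol = 2.664,
                                              dipole = 0.294,
                                              vsurf_G = 0.048),
                           true_coefficients = c(vsurf_DW23 = 0.183,
                                                 e_sol = -0.359,
                                                 dipole = -3.181,
                                                 vsurf_G = 10.627),
                           true_intercept = -9.859,
                           noise_sd = 0.49,
                           seed = 1L) {
  R <- as.matrix(target_correlation)
  if (!isSymmetric(unname(R)) || any(abs(diag(R) - 1) > 1e-12)) {
    stop("synthetic_spec: target_correlation must be symmetric with unit diagonal",
         call. = FALSE)
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("synthetic_spec: target_correlation is not positive definite",
         call. = FALSE)
  }
  k <- ncol(R)
  stopifnot(length(descriptor_means) == k, length(descriptor_sds) == k,
            length(true_coefficients) == k)
  if (noise_sd < 0) stop("synthetic_spec: noise_sd must be >= 0", call. = FALSE)
  if (n_compounds < 3) stop("synthetic_spec: n_compounds must be >= 3", call. = FALSE)
  structure(list(
    n_compounds = as.integer(n_compounds),
    target_correlation = R,
    descriptor_means = descriptor_means,
    descriptor_sds = descriptor_sds,
    true_coefficients = true_coefficients,
    true_intercept = true_intercept,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Generate a correlated synthetic descriptor matrix
#'
#' Draws `n_compounds` rows from a multivariate normal with the spec's
#' marginals, imposing the target correlation through the upper-triangular
#' Cholesky factor of the correlation matrix. Deterministic given the spec
#' seed.
#'
#' @param spec a [synthetic_spec()].
#' @return data frame with `compound_id` and one column per descriptor.
#' @export
gen_descriptor_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + .substream[["descriptors"]])
  k <- ncol(spec$target_correlation)
  L <- chol(spec$target_correlation)
  Z <- matrix(stats::rnorm(spec$n_compounds * k), spec$n_compounds, k) %*% L
  X <- sweep(sweep(Z, 2, spec$descriptor_sds, "*"), 2,
             spec$descriptor_means, "+")
  colnames(X) <- names(spec$descriptor_means) %||% colnames(spec$target_correlation)
  cbind(data.frame(compound_id = seq_len(spec$n_compounds)), as.data.frame(X))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a linear IC50 response
#'
#' `y = X beta + b0 + epsilon`, epsilon iid Gaussian with SD `noise_sd`.
#' With `noise_sd = 0` an OLS refit recovers the coefficients exactly.
#'
#' @param X descriptor table (with or without a `compound_id` column) or
#'   matrix.
#' @param true_coefficients coefficient vector matching the descriptor
#'   columns.
#' @param true_intercept intercept.
#' @param noise_sd Gaussian noise SD (uM).
#' @param seed integer seed for the noise draw.
#' @return numeric response vector.
#' @export
gen_response <- function(X, true_coefficients, true_intercept,
                         noise_sd = 0, seed = 1L) {
  if (is.data.frame(X)) X <- X[, setdiff(names(X), "compound_id"), drop = FALSE]
  X <- as.matrix(X)
  if (ncol(X) != length(true_coefficients)) {
    stop("gen_response: coefficient length does not match descriptor columns",
         call. = FALSE)
  }
  set.seed(seed + .substream[["response"]])
  as.numeric(X %*% true_coefficients + true_intercept +
               stats::rnorm(nrow(X), 0, noise_sd))
}

#' Generate a descriptor pool with decoy columns
#'
#' Appends `n_decoys` independent standard-normal noise columns (named
#' `decoy_*`) to the spec's signal descriptors, for selection-power
#' experiments. Ground truth is recorded in the `signal_columns` attribute.
#'
#' @param spec a [synthetic_spec()].
#' @param n_decoys number of noise columns, >= 0.
#' @return data frame of signal + decoy columns with attribute
#'   `signal_columns`.
#' @export
gen_decoy_pool <- function(spec, n_decoys) {
  stopifnot(n_decoys >= 0)
  X <- gen_descriptor_matrix(spec)
  signal <- setdiff(names(X), "compound_id")
  if (n_decoys > 0) {
    set.seed(spec$seed + .substream[["decoys"]])
    D <- matrix(stats::rnorm(spec$n_compounds * n_decoys),
                spec$n_compounds, n_decoys,
                dimnames = list(NULL, sprintf("decoy_%02d", seq_len(n_decoys))))
    X <- cbind(X, as.data.frame(D))
  }
  attr(X, "signal_columns") <- signal
  X
}

#' Generate a synthetic viability plate
#'
#' Simulates an MTT-style plate: mean viability follows a four-parameter
#' logistic in concentration, observed absorbance is the mean response times
#' `(1 + N(0, cv_noise))` (multiplicative noise with the given coefficient of
#' variation). Zero-concentration vehicle wells are included for
#' normalization.
#'
#' @param ic50 curve midpoint (uM).
#' @param hill Hill slope.
#' @param top,bottom asymptotic viabilities.
#' @param concentrations positive concentration grid (uM); default a 7-point
#'   doubling series 0.25-16 uM within the 0-20 uM assay window.
#' @param cv_noise coefficient of variation of the multiplicative noise.
#' @param replicates wells per concentration (and vehicle wells), >= 1.
#' @param seed integer seed.
#' @return data frame with `well`, `treatment_id`, `concentration`,
#'   `absorbance`.
#' @export
gen_viability_plate <- function(ic50, hill = 1, top = 1, bottom = 0,
                                concentrations = c(0.25, 0.5, 1, 2, 4, 8, 16),
                                cv_noise = 0.05, replicates = 3, seed = 1L) {
  stopifnot(all(concentrations > 0), all(concentrations <= 20),
            replicates >= 1, cv_noise >= 0)
  conc <- c(rep(0, replicates), rep(concentrations, each = replicates))
  mu <- ifelse(conc == 0, top, .fourpl(conc, top, bottom, ic50, hill))
  set.seed(seed + .substream[["plate"]])
  absorbance <- mu * (1 + stats::rnorm(length(mu), 0, cv_noise))
  data.frame(
    well = sprintf("W%03d", seq_along(conc)),
    treatment_id = "synthetic",
    concentration = conc,
    absorbance = absorbance
  )
}
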