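#' Serialize / restore a fitted QSAR model
#'
#' @param model a `qsar_model`.
#' @param path destination JSON file.
#' @return `path` (for `model_to_json`), a `qsar_model` (for
#'   `model_from_json`).
#' @export
model_to_json <- function(model, path) {
  jsonlite::write_json(list(
    descriptor_names = model$descriptor_names,
    coefficients = as.list(model$coefficients),
    intercept = model$intercept,
    method = model$method,
    n_components = model$n_components,
    training_ids = model$training_ids
  ), path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  j <- jsonlite::fromJSON(path)
  structure(list(
    descriptor_names = j$descriptor_names,
    coefficients = stats::setNames(unlist(j$coefficients)[j$descriptor_names],
                                   j$descriptor_names),
    intercept = j$intercept,
    method = j$method,
    n_components = j$n_components,
    training_ids = j$training_ids,
    n = length(j$training_ids)
  ), class = "qsar_model")
}

.correlation_report <- function(cm) {
  disp <- matrix(paste0(formatC(cm$r, digits = 3, format = "f"),
                        ifelse(cm$stars == "", "", paste0(" ", cm$stars))),
                 nrow(cm$r), dimnames = dimnames(cm$r))
  disp[upper.tri(disp)] <- ""
  data.frame(label = rownames(disp), as.data.frame(disp, check.names = FALSE),
             row.names = NULL, check.names = FALSE)
}

#' Reproduce the full study analysis from the packaged tables
#'
#' Runs every stage end to end on the packaged fixtures: reversal-fold
#' recomputation and inhibitor classification, training-set correlation
#' analysis with significance stars, the collinearity check, the
#' four-descriptor model fit (OLS by default; full-component PLS gives the
#' same equation), internal (LOO Q2) and external (test-set R2) validation,
#' and the per-compound prediction table diffed against the published one.
#' All tabular artifacts are written under `out_dir`.
#'
#' @param out_dir output directory (created if absent); `NULL` writes nothing.
#' @param spec train/test split, default the study split.
#' @param method `"ols"` or `"pls"`.
#' @param n_components PLS components (ignored for OLS), default full rank.
#' @param flag_tol reversal-fold flag tolerance, see [reversal_table()].
#' @param concordance_tol maximum allowed |predicted - published predicted|
#'   (uM) for the bundle to report table concordance, default 0.01.
#' @return (invisibly) a list bundle: `reversal`, `correlation`,
#'   `collinearity`, `model`, `validation`, `predictions`, `equation`, `summary`
#'   (character vector), `ok` (TRUE iff the reliability gate passes and the
#'   prediction table is concordant).
#' @export
#' @examples
#' bundle <- run_reproduce(out_dir = NULL)
#' bundle$equation
#' bundle$validation$q2_loo
run_reproduce <- function(out_dir = NULL, spec = default_split(),
                          method = c("ols", "pls"), n_components = NULL,
                          flag_tol = 0.01, concordance_tol = 0.01) {
  method <- match.arg(method)
  cytotox <- load_fixture("cytotoxicity")
  printed <- load_fixture("reversal_printed")
  descriptors <- load_fixture("descriptors")
  responses <- load_fixture("qsar_results")

  reversal <- reversal_table(cytotox, printed = printed, flag_tol = flag_tol)

  y_all <- .response_vector(responses)
  cm <- pearson_matrix(y_all, descriptors, ids = spec$train_ids)
  collin <- collinearity_filter(cm)

  X_train <- .descriptor_matrix(descriptors, spec$train_ids)
  y_train <- .response_vector(responses, spec$train_ids)
  model <- if (method == "ols") {
    fit_ols(X_train, y_train)
  } else {
    fit_pls(X_train, y_train,
            n_components = n_components %||% ncol(X_train))
  }

  test <- if (length(spec$test_ids)) {
    list(X = .descriptor_matrix(descriptors, spec$test_ids),
         y = .response_vector(responses, spec$test_ids))
  } else list(X = NULL, y = NULL)
  fitter <- if (method == "ols") fit_ols else {
    function(X, y) fit_pls(X, y, n_components = n_components %||% ncol(X))
  }
  validation <- validate_model(model, list(X = X_train, y = y_train), test,
                               fitter = fitter)
  tab_pred <- residual_table(model, descriptors, responses, spec = spec,
                           published = responses)
  concordant <- max(abs(tab_pred$delta_vs_published)) <= concordance_tol
  equation <- format_equation(model)

  summary_lines <- c(
    "Flavonoid P-gp reversal and 2D-QSAR reproduction",
    sprintf("Training n = %d, test n = %d", length(spec$train_ids),
            length(spec$test_ids)),
    equation,
    sprintf("R2 = %.3f, R2_adj = %.3f, RMSE = %.3f uM, F = %.3f, p = %.3g",
            validation$r2, validation$r2_adj, validation$rmse,
            validation$f_stat, validation$p_value),
    sprintf("Q2 (LOO) = %.3f, R2_pred = %s", validation$q2_loo,
            if (is.na(validation$r2_pred)) "unavailable"
            else sprintf("%.3f", validation$r2_pred)),
    sprintf("Reliability gate: %s%s", validation$gate,
            if (length(validation$gate_reasons))
              paste0(" (", paste(validation$gate_reasons, collapse = "; "), ")")
            else ""),
    sprintf("Prediction table concordant within %.2f uM: %s",
            concordance_tol, concordant),
    sprintf("Reversal rows flagged inconsistent with published folds: %s",
            paste(reversal$treatment_id[reversal$inconsistent],
                  collapse = ", "))
  )

  bundle <- list(reversal = reversal, correlation = cm,
                 collinearity = collin, model = model,
                 validation = validation, predictions = tab_pred,
                 equation = equation, summary = summary_lines,
                 ok = validation$gate == "reliable" && concordant)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(reversal, file.path(out_dir, "reversal_report.csv"))
    write_table(.correlation_report(cm),
                file.path(out_dir, "correlation_report.csv"))
    model_to_json(model, file.path(out_dir, "model.json"))
    jsonlite::write_json(
      list(r2 = validation$r2, r2_adj = validation$r2_adj,
           rmse = validation$rmse, f_stat = validation$f_stat,
           p_value = validation$p_value, q2_loo = validation$q2_loo,
           r2_pred = validation$r2_pred, gate = validation$gate,
           gate_reasons = validation$gate_reasons),
      file.path(out_dir, "validation_report.json"),
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    write_table(tab_pred, file.path(out_dir, "prediction_table.csv"))
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  }
  invisible(bundle)
}

#' Run the pipeline on synthetic data and report parameter recovery
#'
#' Generates a synthetic descriptor matrix and linear IC50 response under
#' `spec`, splits off a test set, fits and validates the model exactly as
#' [run_reproduce()] does, and tabulates estimated against true coefficients.
#'
#' @param spec a [synthetic_spec()].
#' @param n_test number of synthetic compounds held out, default 7.
#' @param out_dir optional output directory for the report bundle.
#' @return (invisibly) list with `model`, `validation`, `recovery` (data
#'   frame of true vs estimated coefficients), `data`.
#' @export
run_simulate <- function(spec = synthetic_spec(n_compounds = 31),
                         n_test = 7, out_dir = NULL) {
  X <- gen_descriptor_matrix(spec)
  y <- gen_response(X, spec$true_coefficients, spec$true_intercept,
                    spec$noise_sd, seed = spec$seed)
  sp <- split_spec(seq_len(n_test), all_ids = X$compound_id)
  Xm <- as.matrix(X[, setdiff(names(X), "compound_id")])
  rownames(Xm) <- X$compound_id
  X_train <- Xm[as.character(sp$train_ids), , drop = FALSE]
  X_test <- Xm[as.character(sp$test_ids), , drop = FALSE]
  y_train <- y[sp$train_ids]
  y_test <- y[sp$test_ids]
  model <- fit_ols(X_train, y_train)
  validation <- validate_model(model, list(X = X_train, y = y_train),
                               list(X = X_test, y = y_test))
  recovery <- data.frame(
    parameter = c(names(spec$true_coefficients), "(Intercept)"),
    true = c(unname(spec$true_coefficients), spec$true_intercept),
    estimate = c(unname(model$coefficients), model$intercept)
  )
  recovery$error <- recovery$estimate - recovery$true
  bundle <- list(model = model, validation = validation, recovery = recovery,
                 data = cbind(X, ic50 = y))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(bundle$data, file.path(out_dir, "synthetic_data.csv"))
    write_table(recovery, file.path(out_dir, "recovery.csv"))
    model_to_json(model, file.path(out_dir, "model.json"))
    writeLines(c(format_equation(model),
                 utils::capture.output(print(validation))),
               file.path(out_dir, "summary.txt"))
  }
  invisible(bundle)
}

#' Predict IC50 for a descriptor table with a saved model
#'
#' @param model a `qsar_model` or path to a `model.json`.
#' @param descriptors descriptor table (with `compound_id`) or path to a
#'   descriptor CSV.
#' @return data frame with `compound_id` and `predicted_ic50`; zero rows in,
#'   zero rows out.
#' @export
run_predict <- function(model, descriptors) {
  if (is.character(model)) model <- model_from_json(model)
  if (is.character(descriptors)) {
    descriptors <- read_table(descriptors, schema = "descriptors")
  }
  if (nrow(descriptors) == 0) {
    return(data.frame(compound_id = integer(0), predicted_ic50 = numeric(0)))
  }
  data.frame(
    compound_id = descriptors$compound_id,
    predicted_ic50 = stats::predict(model, descriptors[model$descriptor_names])
  )
}
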