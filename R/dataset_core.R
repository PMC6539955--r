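#' @keywords internal
"_PACKAGE"

# Column schemas for every table the package reads or writes. `numeric`
# columns must parse cleanly with "." as the decimal mark; `key` columns must
# be unique within the table (or unique per group, see .check_schema).
.schemas <- list(
  compounds = list(
    columns  = c("compound_id", "name", "cas", "scaffold", "substituents"),
    numeric  = "compound_id",
    key      = "compound_id"
  ),
  descriptors = list(
    columns  = c("compound_id", "vsurf_DW23", "e_sol", "dipole", "vsurf_G"),
    numeric  = c("compound_id", "vsurf_DW23", "e_sol", "dipole", "vsurf_G"),
    key      = "compound_id"
  ),
  cytotoxicity = list(
    columns  = c("treatment_id", "cell_line", "ic50_mean", "ic50_sd"),
    numeric  = c("ic50_mean", "ic50_sd"),
    key      = c("treatment_id", "cell_line")
  ),
  qsar_results = list(
    columns  = c("compound_id", "ic50_experimental", "ic50_predicted", "residual"),
    numeric  = c("compound_id", "ic50_experimental", "ic50_predicted", "residual"),
    key      = "compound_id"
  ),
  reversal_printed = list(
    columns  = c("treatment_id", "rf_mdr1", "rf_kb", "rf_cross"),
    numeric  = c("rf_mdr1", "rf_kb", "rf_cross"),
    key      = "treatment_id"
  ),
  plate = list(
    columns  = c("well", "treatment_id", "concentration", "absorbance"),
    numeric  = c("concentration", "absorbance"),
    key      = NULL
  )
)

.scaffold_levels <- c("flavone", "flavanone", "flavanonol-like",
                      "isoflavone", "flavonolignan")
.substituent_codes <- c("OH", "OMe", "H", "Cglc", "Carb", "ORG")
.substituent_positions <- c("3", "5", "6", "7", "8", "2'", "3'", "4'", "5'")

.check_schema <- function(df, schema_name, source = "<table>") {
  sch <- .schemas[[schema_name]]
  if (is.null(sch)) {
    stop("unknown schema: ", schema_name, call. = FALSE)
  }
  missing <- setdiff(sch$columns, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", source,
                 paste(sQuote(missing), collapse = ", ")), call. = FALSE)
  }
  for (col in sch$numeric) {
    v <- df[[col]]
    if (is.character(v)) {
      # reject "," decimal marks explicitly rather than coercing them to NA
      if (any(grepl(",", v, fixed = TRUE))) {
        stop(sprintf("%s: column '%s' contains ',' decimal marks (row %d)",
                     source, col, which(grepl(",", v, fixed = TRUE))[1]),
             call. = FALSE)
      }
      v <- suppressWarnings(as.numeric(v))
    }
    if (!is.numeric(v) || anyNA(v)) {
      bad <- if (is.numeric(v)) which(is.na(v))[1] else 1L
      stop(sprintf("%s: non-numeric value in column '%s' (row %d)",
                   source, col, bad), call. = FALSE)
    }
    df[[col]] <- v
  }
  if (!is.null(sch$key)) {
    key <- do.call(paste, c(df[sch$key], sep = "\r"))
    if (anyDuplicated(key)) {
      stop(sprintf("%s: duplicate key (%s) at row %d", source,
                   paste(sch$key, collapse = ", "), anyDuplicated(key)),
           call. = FALSE)
    }
  }
  df
}

.check_invariants <- function(df, schema_name, source = "<table>") {
  fail <- function(what) {
    stop(sprintf("%s: fixture integrity violated: %s", source, what),
         call. = FALSE)
  }
  switch(schema_name,
    descriptors = {
      if (any(df$vsurf_DW23 < 0)) fail("vsurf_DW23 must be nonnegative")
      if (any(df$dipole < 0)) fail("dipole must be nonnegative")
      if (any(df$vsurf_G < 1)) fail("vsurf_G must be >= 1")
      if (!all(is.finite(as.matrix(df[-1])))) fail("non-finite descriptor value")
    },
    cytotoxicity = {
      if (any(df$ic50_mean <= 0)) fail("ic50_mean must be positive")
      if (any(df$ic50_sd < 0)) fail("ic50_sd must be nonnegative")
      if (!all(df$cell_line %in% c("KB", "KB_MDR1"))) {
        fail("cell_line must be KB or KB_MDR1")
      }
    },
    compounds = {
      if (!all(df$compound_id %in% 1:31)) fail("compound_id must be in 1..31")
      if (!all(df$scaffold %in% .scaffold_levels)) fail("unknown scaffold")
      subs <- parse_substituents(df$substituents)
      for (i in seq_along(subs)) {
        s <- subs[[i]]
        if (!all(names(s) %in% .substituent_positions)) {
          fail(sprintf("compound %d: unknown substituent position", df$compound_id[i]))
        }
        if (!all(s %in% .substituent_codes)) {
          fail(sprintf("compound %d: unknown substituent code", df$compound_id[i]))
        }
      }
    },
    qsar_results = {
      dev <- abs(df$ic50_experimental - df$ic50_predicted - df$residual)
      if (any(dev > 0.001)) {
        fail(sprintf("residual != experimental - predicted for compound %d",
                     df$compound_id[which.max(dev)]))
      }
    }
  )
  invisible(df)
}

#' Parse substituent pattern strings
#'
#' Substituent patterns are stored as `"pos=code"` pairs separated by `";"`,
#' e.g. `"5=OMe;7=OMe"` for 5,7-dimethoxy substitution. Positions use the
#' flavonoid ring numbering (3, 5, 6, 7, 8 on the A/C rings; primed positions
#' on the B ring).
#'
#' @param x character vector of pattern strings (may be empty strings).
#' @return a list of named character vectors, one per input element.
#' @export
parse_substituents <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(stats::setNames(character(0), character(0)))
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    stats::setNames(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1))
  })
}

#' Read a schema-validated CSV table
#'
#' Reads a UTF-8, comma-separated, "."-decimal CSV with a mandatory header and
#' validates it against one of the package schemas. Row order is preserved.
#'
#' @param path file path to the CSV.
#' @param schema one of `"compounds"`, `"descriptors"`, `"cytotoxicity"`,
#'   `"qsar_results"`, `"reversal_printed"`, `"plate"`.
#' @return a `data.frame` with validated columns.
#' @export
read_table <- function(path, schema) {
  schema <- match.arg(schema, names(.schemas))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  sch <- .schemas[[schema]]
  df <- .check_schema(df, schema, source = path)
  for (col in setdiff(sch$columns, sch$numeric)) df[[col]] <- as.character(df[[col]])
  df
}

#' Write a table as CSV
#'
#' Inverse of [read_table()]: UTF-8, comma separator, "." decimal, header row.
#'
#' @param df data frame to write.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Load a packaged study table
#'
#' The full study dataset is shipped with the package: the 31 flavonoids with
#' scaffold class and substituent pattern, the daunorubicin cytotoxicity IC50
#' table for KB and KB/MDR1 cells (with the published reversal-fold columns
#' kept separately in `"reversal_printed"`), the four-descriptor matrix, and
#' the published per-compound predicted IC50s and residuals.
#'
#' Every fixture is integrity-checked on load. The cytotoxicity table is not
#' silently corrected: rows whose published reversal folds cannot be
#' reproduced from the published IC50 means (the elacridar positive control is
#' the known case) are detected downstream by [reversal_table()], never edited
#' here.
#'
#' @param table_name one of `"compounds"`, `"cytotoxicity"`, `"descriptors"`,
#'   `"qsar_results"`, `"reversal_printed"`.
#' @return a validated `data.frame`.
#' @export
#' @examples
#' desc <- load_fixture("descriptors")
#' nrow(desc)  # 31 compounds
load_fixture <- function(table_name) {
  table_name <- match.arg(table_name,
                          c("compounds", "cytotoxicity", "descriptors",
                            "qsar_results", "reversal_printed"))
  path <- system.file("extdata", paste0(table_name, ".csv"),
                      package = "flavoqsar", mustWork = TRUE)
  df <- read_table(path, schema = table_name)
  .check_invariants(df, table_name, source = path)
  df
}

#' Default train/test split of the 31 compounds
#'
#' Seven compounds (2, 4, 9, 20, 22, 27, 30) form the external test set; the
#' remaining 24 are the training set used for model fitting and leave-one-out
#' cross-validation.
#'
#' @return a list with integer vectors `test_ids` and `train_ids`.
#' @export
default_split <- function() {
  path <- system.file("extdata", "split.json", package = "flavoqsar",
                      mustWork = TRUE)
  test_ids <- sort(as.integer(jsonlite::fromJSON(path)$test_ids))
  split_spec(test_ids)
}

#' Construct and validate a split specification
#'
#' @param test_ids integer ids held out as the external test set.
#' @param all_ids the full id universe (default the 31 study compounds).
#' @return a list with `test_ids` and `train_ids`, disjoint, union `all_ids`.
#' @export
split_spec <- function(test_ids, all_ids = 1:31) {
  test_ids <- sort(unique(as.integer(test_ids)))
  if (!all(test_ids %in% all_ids)) {
    stop("split: test id(s) ", paste(setdiff(test_ids, all_ids), collapse = ", "),
         " outside the compound set", call. = FALSE)
  }
  list(test_ids = test_ids, train_ids = sort(setdiff(all_ids, test_ids)))
}

#' Partition descriptor and response tables into train and test sets
#'
#' @param descriptors descriptor table with a `compound_id` column.
#' @param responses response table with a `compound_id` column.
#' @param spec a split specification from [split_spec()] or [default_split()].
#' @return list with `train` and `test`, each a list of `descriptors` and
#'   `responses` data frames.
#' @export
split_train_test <- function(descriptors, responses, spec = default_split()) {
  ids <- sort(unique(c(spec$train_ids, spec$test_ids)))
  for (nm in c("descriptors", "responses")) {
    tab <- get(nm)
    absent <- setdiff(ids, tab$compound_id)
    if (length(absent)) {
      stop(sprintf("split: id(s) %s in spec absent from %s table",
                   paste(absent, collapse = ", "), nm), call. = FALSE)
    }
  }
  take <- function(tab, ids) tab[tab$compound_id %in% ids, , drop = FALSE]
  list(
    train = list(descriptors = take(descriptors, spec$train_ids),
                 responses   = take(responses,   spec$train_ids)),
    test  = list(descriptors = take(descriptors, spec$test_ids),
                 responses   = take(responses,   spec$test_ids))
  )
}

# Descriptor matrix (rows ordered by compound_id) and named response vector
# for a set of ids; the workhorse accessor behind the model-fitting steps.
.descriptor_matrix <- function(descriptors, ids = descriptors$compound_id) {
  d <- descriptors[match(sort(ids), descriptors$compound_id), , drop = FALSE]
  X <- as.matrix(d[, c("vsurf_DW23", "e_sol", "dipole", "vsurf_G")])
  rownames(X) <- d$compound_id
  X
}

.response_vector <- function(qsar_results, ids = qsar_results$compound_id) {
  d <- qsar_results[match(sort(ids), qsar_results$compound_id), , drop = FALSE]
  stats::setNames(d$ic50_experimental, d$compound_id)
}
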