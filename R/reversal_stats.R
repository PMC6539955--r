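#' Reversal fold of an inhibitor within one cell line
#'
#' The reversal fold compares daunorubicin's IC50 without an inhibitor to its
#' IC50 in the presence of the inhibitor, in the same cell line. A fold above
#' 1 means the co-treatment sensitised the cells to the drug.
#'
#' @param ic50_without IC50 of the drug alone (uM), positive.
#' @param ic50_with IC50 of the drug plus inhibitor (uM), positive.
#' @return positive numeric, `ic50_without / ic50_with`.
#' @export
#' @examples
#' reversal_fold(3.102, 0.901)  # 3.443
reversal_fold <- function(ic50_without, ic50_with) {
  if (any(ic50_without <= 0) || any(ic50_with <= 0)) {
    stop("reversal_fold: IC50 values must be positive", call. = FALSE)
  }
  ic50_without / ic50_with
}

#' Cross-resistance fold between the resistant and parental cell line
#'
#' Ratio of the drug's IC50 in the P-gp-overexpressing KB/MDR1 line to its
#' IC50 in the parental KB line, under the same treatment. Quantifies how much
#' resistance the efflux pump confers under that treatment.
#'
#' @param ic50_mdr1 IC50 in KB/MDR1 cells (uM), positive.
#' @param ic50_kb IC50 in KB cells (uM), positive.
#' @return positive numeric, `ic50_mdr1 / ic50_kb`.
#' @export
cross_resistance_fold <- function(ic50_mdr1, ic50_kb) {
  if (any(ic50_mdr1 <= 0) || any(ic50_kb <= 0)) {
    stop("cross_resistance_fold: IC50 values must be positive", call. = FALSE)
  }
  ic50_mdr1 / ic50_kb
}

#' Classify a compound from its KB/MDR1 reversal fold
#'
#' A compound whose reversal fold in the resistant line exceeds 1.000 is a
#' potential P-gp inhibitor; below 1.000 it behaves as a potential activator;
#' exactly 1.000 is neutral. The comparison is a strict inequality.
#'
#' @param rf_mdr1 positive reversal fold(s) in KB/MDR1 cells.
#' @return character vector: `"potential_inhibitor"`, `"potential_activator"`
#'   or `"neutral"`.
#' @export
classify_inhibitor <- function(rf_mdr1) {
  if (any(rf_mdr1 <= 0)) {
    stop("classify_inhibitor: reversal fold must be positive", call. = FALSE)
  }
  ifelse(rf_mdr1 > 1, "potential_inhibitor",
         ifelse(rf_mdr1 < 1, "potential_activator", "neutral"))
}

#' Reversal-fold table for a full cytotoxicity experiment
#'
#' Recomputes, for every treatment, the three fold statistics from the IC50
#' means: the within-line reversal folds `rf_mdr1` (KB/MDR1) and `rf_kb` (KB)
#' against the negative control, and the cross-resistance fold `rf_cross`
#' (KB/MDR1 vs KB under the same treatment). Folds are always recomputed from
#' the IC50 means, never copied from a published fold column; if published
#' folds are supplied, each recomputed value is diffed against them and rows
#' deviating by more than `flag_tol` in any fold are flagged `inconsistent`.
#'
#' @param cytotox long-format cytotoxicity table (`treatment_id`, `cell_line`,
#'   `ic50_mean`, `ic50_sd`) containing a `negative_control` row for both
#'   cell lines.
#' @param printed optional table of published folds (`treatment_id`,
#'   `rf_mdr1`, `rf_kb`, `rf_cross`) to diff against.
#' @param flag_tol absolute deviation (in fold units) above which a row is
#'   flagged inconsistent with its published folds; default 0.01, chosen so
#'   third-decimal rounding of the underlying replicate-level data does not
#'   raise flags.
#' @return data frame with one row per treatment: the three recomputed folds,
#'   the inhibitor/activator classification and, when `printed` is given,
#'   per-fold deltas and a logical `inconsistent` column.
#' @export
#' @examples
#' rt <- reversal_table(load_fixture("cytotoxicity"),
#'                      printed = load_fixture("reversal_printed"))
#' rt[rt$treatment_id == "9", c("rf_mdr1", "classification")]
reversal_table <- function(cytotox, printed = NULL, flag_tol = 0.01) {
  wide <- function(line) {
    d <- cytotox[cytotox$cell_line == line, c("treatment_id", "ic50_mean")]
    stats::setNames(d$ic50_mean, d$treatment_id)
  }
  mdr1 <- wide("KB_MDR1")
  kb <- wide("KB")
  if (!("negative_control" %in% names(mdr1)) ||
      !("negative_control" %in% names(kb))) {
    stop("reversal_table: negative_control row missing for a cell line",
         call. = FALSE)
  }
  ids <- unique(cytotox$treatment_id)
  both <- intersect(names(mdr1), names(kb))
  if (!all(ids %in% both)) {
    stop("reversal_table: treatment(s) ",
         paste(setdiff(ids, both), collapse = ", "),
         " missing a cell line", call. = FALSE)
  }
  out <- data.frame(
    treatment_id = ids,
    rf_mdr1  = reversal_fold(mdr1[["negative_control"]], mdr1[ids]),
    rf_kb    = reversal_fold(kb[["negative_control"]], kb[ids]),
    rf_cross = cross_resistance_fold(mdr1[ids], kb[ids]),
    row.names = NULL
  )
  out$classification <- classify_inhibitor(out$rf_mdr1)
  if (!is.null(printed)) {
    m <- match(out$treatment_id, printed$treatment_id)
    out$delta_rf_mdr1  <- out$rf_mdr1 - printed$rf_mdr1[m]
    out$delta_rf_kb    <- out$rf_kb - printed$rf_kb[m]
    out$delta_rf_cross <- out$rf_cross - printed$rf_cross[m]
    out$inconsistent <- pmax(abs(out$delta_rf_mdr1), abs(out$delta_rf_kb),
                             abs(out$delta_rf_cross)) > flag_tol
  }
  out
}
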