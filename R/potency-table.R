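# Potency/efficacy panel I/O and validation.
#
# A potency table has one row per (receptor, ligand) with the summary
# statistics of a fitted concentration-response curve: pEC50 (-log10 molar
# EC50) and Imax (fraction of the maximal ACh response), each with a
# standard error and replicate count.

POTENCY_COLS <- c("receptor", "ligand", "pec50_mean", "pec50_se",
                  "imax_mean", "imax_se", "n", "core_panel")

#' Validate a potency/efficacy table
#'
#' Checks the structural invariants of a potency panel: required columns,
#' canonical receptor keys, unique (receptor, ligand) pairs, pEC50 within
#' the physically plausible \[2, 12\] window, non-negative Imax, and
#' Imax = 1 for every reference-ligand row (the normalization identity).
#'
#' @param table A data frame with the potency-table columns.
#' @param reference Reference ligand name (default `"ACh"`).
#' @return The validated table, invisibly coerced to a tibble with
#'   canonical receptor keys.
#' @export
validate_potency_table <- function(table, reference = reference_ligand()) {
  missing_cols <- setdiff(setdiff(POTENCY_COLS, "core_panel"), names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("Potency table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  tbl <- tibble::as_tibble(table)
  if (nrow(tbl) == 0L) abort("Potency table has no rows.")
  if (!"core_panel" %in% names(tbl)) tbl$core_panel <- TRUE
  for (col in c("pec50_mean", "pec50_se", "imax_mean", "imax_se", "n")) {
    if (!is.numeric(tbl[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(tbl[[col]])))))
      abort(paste0("Non-numeric value in column '", col, "' at row(s) ",
                   paste(utils::head(bad, 5), collapse = ", "), "."))
    }
  }
  tbl$receptor <- vapply(tbl$receptor, subunit_key, character(1),
                         USE.NAMES = FALSE)
  tbl$ligand <- as.character(tbl$ligand)
  dup <- duplicated(tbl[, c("receptor", "ligand")])
  if (any(dup)) {
    abort(paste0("Duplicate (receptor, ligand) pair(s) at row(s) ",
                 paste(which(dup), collapse = ", "), "."))
  }
  bad_p <- which(!is.finite(tbl$pec50_mean) |
                   tbl$pec50_mean < 2 | tbl$pec50_mean > 12)
  if (length(bad_p) > 0) {
    abort(paste0("pec50_mean outside [2, 12] (or non-finite) at row(s) ",
                 paste(bad_p, collapse = ", "), "."))
  }
  if (any(tbl$imax_mean < 0)) {
    abort(paste0("Negative imax_mean at row(s) ",
                 paste(which(tbl$imax_mean < 0), collapse = ", "), "."))
  }
  ref_rows <- tbl$ligand == reference
  if (any(ref_rows) && any(abs(tbl$imax_mean[ref_rows] - 1) > 1e-8)) {
    abort(paste0(
      "Reference ligand (", reference, ") rows must have imax_mean = 1 ",
      "(responses are normalized to the maximal ", reference, " response)."
    ))
  }
  invisible(tbl)
}

#' Read a potency/efficacy table from CSV
#'
#' Expects the documented schema
#' `receptor,ligand,pec50_mean,pec50_se,imax_mean,imax_se,n,core_panel`
#' with receptors in "/"-joined subunit form (ASCII or Greek spelling).
#'
#' @param path Path to a CSV file.
#' @inheritParams validate_potency_table
#' @return A validated potency tibble.
#' @export
read_potency_table <- function(path, reference = reference_ligand()) {
  tbl <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste0("Cannot read potency CSV '", path, "': ",
                                     conditionMessage(e)))
  )
  if (nrow(tbl) == 0L || ncol(tbl) == 0L) {
    abort(paste0("Potency CSV '", path, "' is empty."))
  }
  validate_potency_table(tbl, reference = reference)
}

#' Write a potency/efficacy table to CSV
#'
#' Inverse of [read_potency_table()]: `read_potency_table(write_potency_table(x, f))`
#' returns a table identical to `x` up to column classes.
#'
#' @param table A potency table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_potency_table <- function(table, path) {
  tbl <- validate_potency_table(table)
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' The Drosophila melanogaster nAChR agonist panel
#'
#' The published potency/efficacy panel for 18 receptor subunit
#' combinations expressed in Xenopus oocytes and challenged with ACh and
#' three neonicotinoids (imidacloprid, thiacloprid, clothianidin): mean and
#' standard error of pEC50 and Imax, n = 5 oocytes per curve. The 12
#' "core panel" receptors are the combinations of Da1, Da2, Da3, Db2
#' around the essential Db1 subunit and feed the factor-model, CHAID and
#' lattice analyses (48 = 12 receptors x 4 ligands samples); the remaining
#' 6 rows are Da4/Db3 substitution receptors. Reference-ligand (ACh) rows
#' carry Imax = 1 by normalization.
#'
#' @param core_only If `TRUE`, return only the 12-receptor core panel.
#' @return A potency tibble with 72 (or 48) rows.
#' @export
#' @examples
#' panel <- dmel_nachr_panel()
#' dplyr::filter(panel, receptor == "Da3/Db1", ligand == "imidacloprid")
dmel_nachr_panel <- function(core_only = FALSE) {
  path <- system.file("extdata", "dmel_nachr_panel.csv",
                      package = "nachrpharm", mustWork = TRUE)
  tbl <- read_potency_table(path)
  if (core_only) tbl <- dplyr::filter(tbl, .data$core_panel)
  tbl
}

# Concentration-response records ---------------------------------------------

RESPONSE_COLS <- c("oocyte_id", "receptor", "ligand", "concentration_molar",
                   "response", "response_kind")

#' Validate concentration-response records
#'
#' Long-format per-oocyte records: one row per (oocyte, receptor, ligand,
#' concentration) peak-current measurement, either raw (`response_kind =
#' "raw_uA"`) or normalized to the maximal ACh response
#' (`response_kind = "normalized"`).
#'
#' @param records A data frame with the record columns.
#' @return The validated tibble, invisibly.
#' @export
validate_response_records <- function(records) {
  missing_cols <- setdiff(RESPONSE_COLS, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Response records are missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  tbl <- tibble::as_tibble(records)
  if (any(!tbl$response_kind %in% c("normalized", "raw_uA"))) {
    abort("response_kind must be 'normalized' or 'raw_uA'.")
  }
  if (any(!is.finite(tbl$concentration_molar) | tbl$concentration_molar <= 0)) {
    abort("All concentrations must be finite and > 0 (molar).")
  }
  norm <- tbl$response_kind == "normalized"
  if (any(norm & tbl$response < 0)) {
    abort("Normalized responses must be >= 0.")
  }
  tbl$receptor <- vapply(tbl$receptor, subunit_key, character(1),
                         USE.NAMES = FALSE)
  invisible(tbl)
}

#' Read/write concentration-response CSV
#'
#' Schema: `oocyte_id,receptor,ligand,concentration_molar,response,response_kind`.
#'
#' @param path CSV path.
#' @return A validated records tibble.
#' @export
read_response_records <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tbl) == 0L) abort(paste0("Response CSV '", path, "' is empty."))
  validate_response_records(tbl)
}

#' @rdname read_response_records
#' @param records A records tibble.
#' @export
write_response_records <- function(records, path) {
  tbl <- validate_response_records(records)
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}
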