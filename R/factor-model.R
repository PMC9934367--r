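quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# Additive subunit/compound factor model.
#
# The 48 core-panel summary means (12 receptors x 4 ligands) are regressed
# on binary subunit-presence indicators (Da1, Da2, Da3, Db2 - Db1 is common
# to every functional receptor and hence inestimable) plus ligand dummies
# with ACh as the reference level. The model is fitted on summary means,
# not per-oocyte replicates: n = 48, residual df = 40.

#' Build the subunit/compound design for the factor model
#'
#' One row per (receptor, ligand) of the core panel: binary presence
#' columns for each subunit covariate, the ligand as a factor with the
#' reference level first, and the chosen outcome.
#'
#' @param panel A potency table (only `core_panel` rows are used).
#' @param outcome `"pec50"` or `"imax"`.
#' @param subunits Subunit covariates (default `Da1, Da2, Da3, Db2`). A
#'   subunit constant across the panel (such as Db1) is rejected.
#' @param reference Reference ligand (default `"ACh"`).
#' @return A tibble with columns `receptor`, `ligand` (factor), one 0/1
#'   column per subunit, and `outcome`.
#' @export
#' @examples
#' d <- build_design(dmel_nachr_panel(), "pec50")
#' nrow(d)  # 48
build_design <- function(panel, outcome = c("pec50", "imax"),
                         subunits = c("Da1", "Da2", "Da3", "Db2"),
                         reference = reference_ligand()) {
  outcome <- match.arg(outcome)
  tbl <- validate_potency_table(panel, reference = reference)
  tbl <- dplyr::filter(tbl, .data$core_panel)
  ligands <- unique(tbl$ligand)
  if (!reference %in% ligands) {
    abort(paste0("Reference ligand '", reference, "' absent from the panel."))
  }
  gaps <- tidyr::expand_grid(receptor = unique(tbl$receptor),
                             ligand = ligands) %>%
    dplyr::anti_join(tbl, by = c("receptor", "ligand"))
  if (nrow(gaps) > 0) {
    abort(paste0(
      "Missing (receptor, ligand) cell(s): ",
      paste(paste0(gaps$receptor, " x ", gaps$ligand), collapse = "; "), "."
    ))
  }
  pres <- subunit_presence(unique(tbl$receptor), subunits = subunits)
  constant <- names(pres)[-1][vapply(pres[-1], function(col)
    length(unique(col)) == 1L, logical(1))]
  if (length(constant) > 0) {
    abort(paste0(
      "Subunit covariate(s) constant across the panel: ",
      paste(constant, collapse = ", "),
      ". Constant subunits (e.g. the essential Db1) are inestimable."
    ))
  }
  out_col <- if (outcome == "pec50") "pec50_mean" else "imax_mean"
  tbl %>%
    dplyr::left_join(pres, by = "receptor") %>%
    dplyr::mutate(ligand = as_ligand_factor(.data$ligand,
                                            levels = c(reference,
                                                       setdiff(LIGAND_LEVELS, reference))),
                  outcome = .data[[out_col]]) %>%
    dplyr::select(dplyr::all_of(c("receptor", "ligand", names(pres)[-1], "outcome"))) %>%
    dplyr::arrange(.data$receptor, .data$ligand)
}

#' Fit the additive subunit/compound factor model
#'
#' Ordinary least squares of the panel means on subunit-presence
#' indicators and ligand dummies (reference: ACh). Exact least-squares
#' solution via the QR decomposition; 95% confidence intervals use the t
#' quantile with the residual degrees of freedom.
#'
#' @inheritParams build_design
#' @return An object of class `factor_fit` wrapping the `lm` fit, with the
#'   design, outcome name and reference ligand attached. Methods:
#'   [tidy.factor_fit()], [glance.factor_fit()], [coefficient_table()],
#'   `print`, `autoplot`.
#' @export
#' @examples
#' fit <- fit_factor_model(dmel_nachr_panel(), "pec50")
#' tidy(fit)
#' glance(fit)
fit_factor_model <- function(panel, outcome = c("pec50", "imax"),
                             subunits = c("Da1", "Da2", "Da3", "Db2"),
                             reference = reference_ligand()) {
  outcome <- match.arg(outcome)
  design <- build_design(panel, outcome, subunits = subunits,
                         reference = reference)
  sub_cols <- setdiff(names(design), c("receptor", "ligand", "outcome"))
  fml <- stats::as.formula(paste("outcome ~",
                                 paste(c(sub_cols, "ligand"), collapse = " + ")))
  lm_fit <- stats::lm(fml, data = design)
  aliased <- names(which(is.na(stats::coef(lm_fit))))
  if (length(aliased) > 0) {
    abort(paste0("Design is rank deficient; collinear column(s): ",
                 paste(aliased, collapse = ", "), "."))
  }
  structure(list(lm = lm_fit, design = design, outcome = outcome,
                 subunits = sub_cols, reference = reference),
            class = "factor_fit")
}

#' Tidy the factor-model fit
#'
#' @param x A `factor_fit`.
#' @param conf.level Confidence level for the intervals (default 0.95).
#' @param ... Unused.
#' @return One row per term: `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`, and `significant` (does the CI
#'   exclude zero, equivalent to the two-sided t-test at 1 - `conf.level`).
#' @method tidy factor_fit
#' @export
tidy.factor_fit <- function(x, conf.level = 0.95, ...) {
  # zero-residual fits (e.g. exact synthetic panels) are expected here, so
  # summary.lm's "essentially perfect fit" warning is noise
  sm <- quiet_perfect_fit(stats::summary.lm(x$lm))$coefficients
  ci <- quiet_perfect_fit(stats::confint(x$lm, level = conf.level))
  term <- rownames(sm)
  term <- sub("^ligand", "", term)
  tibble::tibble(
    term = term,
    estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]), p.value = unname(sm[, 4]),
    conf.low = unname(ci[, 1]), conf.high = unname(ci[, 2]),
    significant = unname(ci[, 1] > 0 | ci[, 2] < 0)
  )
}

#' @rdname tidy.factor_fit
#' @return `glance()`: one row with `n`, `df_residual`, `r.squared`,
#'   `adj.r.squared`, `rss`, `sigma`, and the information criterion under
#'   two conventions: `aic_rss` = n log(RSS/n) + 2k (k estimated
#'   coefficients) and `aic_gaussian` = the full Gaussian log-likelihood
#'   form including additive constants and the variance parameter
#'   (`stats::AIC`).
#' @method glance factor_fit
#' @export
glance.factor_fit <- function(x, ...) {
  sm <- quiet_perfect_fit(stats::summary.lm(x$lm))
  n <- nrow(x$design)
  k <- length(stats::coef(x$lm))
  rss <- sum(stats::residuals(x$lm)^2)
  tibble::tibble(
    outcome = x$outcome, n = n,
    df_residual = stats::df.residual(x$lm),
    r.squared = sm$r.squared, adj.r.squared = sm$adj.r.squared,
    rss = rss, sigma = sm$sigma,
    aic_rss = n * log(rss / n) + 2 * k,
    aic_gaussian = stats::AIC(x$lm)
  )
}

#' @export
print.factor_fit <- function(x, ...) {
  cat("Additive subunit/compound factor model (outcome: ", x$outcome,
      ", reference ligand: ", x$reference, ")\n", sep = "")
  print(coefficient_table(x), n = Inf)
  g <- glance(x)
  cat(sprintf("n = %d, residual df = %d, R2 = %.3f (adjusted %.3f)\n",
              g$n, g$df_residual, g$r.squared, g$adj.r.squared))
  invisible(x)
}

#' Coefficient table with significance stars
#'
#' A compact report of the fitted factor model: coefficient, 95% CI, and a
#' star when the interval excludes zero (two-sided t-test at P < 0.05).
#'
#' @param fit A `factor_fit`.
#' @param digits Rounding for display columns (default 3).
#' @return A tibble with `term`, `estimate`, `conf.low`, `conf.high`,
#'   `stars`.
#' @export
coefficient_table <- function(fit, digits = 3) {
  td <- tidy(fit)
  tibble::tibble(
    term = td$term,
    estimate = round(td$estimate, digits),
    conf.low = round(td$conf.low, digits),
    conf.high = round(td$conf.high, digits),
    stars = ifelse(td$significant, "*", "")
  )
}

#' Ligand-effect coefficients of a factor fit
#'
#' The dummy coefficients of the non-reference ligands (effects relative
#' to ACh). Label-invariant summaries (`max`, `min`) of these are the
#' robust way to compare against published values when compound labels
#' are in doubt.
#'
#' @param fit A `factor_fit`.
#' @return Named numeric vector of ligand-dummy coefficients.
#' @export
ligand_effects <- function(fit) {
  td <- tidy(fit)
  sel <- !(td$term %in% c("(Intercept)", fit$subunits))
  stats::setNames(td$estimate[sel], td$term[sel])
}

#' Subunit-effect coefficients of a factor fit
#'
#' @param fit A `factor_fit`.
#' @return Named numeric vector of subunit-presence coefficients.
#' @export
subunit_effects <- function(fit) {
  td <- tidy(fit)
  sel <- td$term %in% fit$subunits
  stats::setNames(td$estimate[sel], td$term[sel])
}
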