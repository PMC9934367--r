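# Hill concentration-response model and nonlinear least-squares fitting.
#
# Model:  Y = Imax / (1 + 10^((logEC50 - X) * nH)),  X = log10[ligand (M)],
# parameterized by pEC50 = -logEC50 so the fitted potency is directly the
# quantity tabulated in the panel. Fits are box-bounded Levenberg-Marquardt
# with a deterministic multistart over a pEC50 grid, since Hill fits on
# sparse curves are multimodal.

#' Hill model response
#'
#' Predicted normalized response at given molar concentrations.
#'
#' @param concentration Molar concentrations (> 0).
#' @param pec50 Potency, -log10(EC50 in molar).
#' @param imax Maximal normalized response.
#' @param nh Hill coefficient.
#' @return Numeric vector of responses; `hill_response(10^-pec50, ...)`
#'   equals `imax / 2` exactly.
#' @export
#' @examples
#' hill_response(1e-6, pec50 = 6, imax = 1, nh = 1)  # half-maximum
hill_response <- function(concentration, pec50, imax, nh) {
  x <- log10(concentration)
  imax / (1 + 10^((-pec50 - x) * nh))
}

#' Control settings for Hill fitting
#'
#' @param nh_bounds Bounds for the Hill coefficient (default `c(0.3, 5)`,
#'   keeping slopes physical on non-plateau curves).
#' @param imax_bounds Bounds for Imax (default `c(1e-6, 2)`).
#' @param pec50_margin Log-units the pEC50 start grid (and box) extends
#'   beyond the observed concentration range (default 1).
#' @param grid_step Spacing of the pEC50 multistart grid in log units
#'   (default 0.5).
#' @param ftol,ptol Levenberg-Marquardt convergence tolerances on relative
#'   RSS / parameter change (default 1e-12, giving reproducible 3-decimal
#'   pEC50 reporting).
#' @param maxiter Maximum LM iterations per start.
#' @param plateau_fraction A fit is flagged `extrapolated_plateau` when the
#'   mean response at the top concentration is below this fraction of the
#'   fitted Imax (default 0.9).
#' @return A list of class `hill_control`.
#' @export
hill_control <- function(nh_bounds = c(0.3, 5), imax_bounds = c(1e-6, 2),
                         pec50_margin = 1, grid_step = 0.5,
                         ftol = 1e-12, ptol = 1e-12, maxiter = 300,
                         plateau_fraction = 0.9) {
  stopifnot(nh_bounds[1] > 0, nh_bounds[1] < nh_bounds[2],
            imax_bounds[1] > 0, imax_bounds[1] < imax_bounds[2])
  structure(list(nh_bounds = nh_bounds, imax_bounds = imax_bounds,
                 pec50_margin = pec50_margin, grid_step = grid_step,
                 ftol = ftol, ptol = ptol, maxiter = maxiter,
                 plateau_fraction = plateau_fraction),
            class = "hill_control")
}

#' Fit the Hill model to one concentration-response curve
#'
#' Least-squares estimation of (pEC50, Imax, nH) from normalized responses,
#' pooling all points (replicate oocytes included) into a single fit.
#' Starts are taken from a fixed log-spaced pEC50 grid spanning the
#' observed concentration range plus a margin, with Imax seeded at the
#' maximum observed response and nH at 1; the best converged start (lowest
#' residual sum of squares) wins, so the result is deterministic for
#' identical inputs and control settings.
#'
#' @param concentration Molar concentrations (>= 4 distinct values).
#' @param response Normalized responses (same length, >= 0).
#' @param control A [hill_control()] list.
#' @return An object of class `hill_fit` with elements `pec50`, `imax`,
#'   `nh`, asymptotic standard errors `se_pec50`/`se_imax`/`se_nh`, `rss`,
#'   `converged`, `extrapolated_plateau`, `n_points`, and the data used.
#'   Non-convergence is reported via `converged = FALSE`, never silently.
#' @export
#' @examples
#' conc <- 10^seq(-8, -4.5, by = 0.5)
#' y <- hill_response(conc, 6, 1, 1)
#' fit <- fit_hill(conc, y)
#' tidy(fit)
fit_hill <- function(concentration, response, control = hill_control()) {
  stopifnot(length(concentration) == length(response))
  keep <- is.finite(concentration) & is.finite(response)
  concentration <- concentration[keep]
  response <- response[keep]
  if (any(concentration <= 0)) abort("Concentrations must be > 0 (molar).")
  if (any(response < 0)) abort("Normalized responses must be >= 0.")
  n_distinct_conc <- length(unique(concentration))
  if (n_distinct_conc < 4) {
    abort(paste0("Hill fitting needs >= 4 distinct concentrations; got ",
                 n_distinct_conc, "."))
  }
  x <- log10(concentration)
  y <- response

  p_lo <- -max(x) - control$pec50_margin
  p_hi <- -min(x) + control$pec50_margin
  starts_p <- seq(p_lo, p_hi, by = control$grid_step)
  imax0 <- max(max(y), control$imax_bounds[1] * 2)
  imax0 <- min(imax0, control$imax_bounds[2])

  lower <- c(pec50 = p_lo, imax = control$imax_bounds[1],
             nh = control$nh_bounds[1])
  upper <- c(pec50 = p_hi, imax = control$imax_bounds[2],
             nh = control$nh_bounds[2])
  ctrl <- minpack.lm::nls.lm.control(ftol = control$ftol, ptol = control$ptol,
                                     maxiter = control$maxiter)
  resid_fun <- function(par) {
    y - hill_response(concentration, par[["pec50"]], par[["imax"]], par[["nh"]])
  }

  best <- NULL
  for (p0 in starts_p) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = c(pec50 = p0, imax = imax0, nh = 1),
                         lower = lower, upper = upper,
                         fn = resid_fun, control = ctrl),
      error = function(e) NULL
    )
    if (is.null(res)) next
    rss <- res$deviance
    conv <- res$info %in% 1:4
    if (is.null(best) || rss < best$rss - 1e-15 ||
        (abs(rss - best$rss) <= 1e-15 && conv && !best$converged)) {
      best <- list(fit = res, rss = rss, converged = conv)
    }
  }
  if (is.null(best)) {
    abort("All Hill-fit starts failed; check the input data.")
  }

  par <- best$fit$par
  se <- rep(NA_real_, 3)
  vc <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
  if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) >= 0)) {
    se <- sqrt(diag(vc))
  }
  top_mean <- mean(y[x == max(x)])
  out <- structure(list(
    pec50 = unname(par[["pec50"]]), imax = unname(par[["imax"]]),
    nh = unname(par[["nh"]]),
    se_pec50 = se[1], se_imax = se[2], se_nh = se[3],
    rss = best$rss, converged = best$converged,
    extrapolated_plateau = top_mean < control$plateau_fraction * par[["imax"]],
    n_points = length(y),
    data = tibble::tibble(concentration = concentration, response = y),
    control = control
  ), class = "hill_fit")
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill concentration-response fit (", x$n_points, " points)\n", sep = "")
  cat(sprintf("  pEC50 = %.3f (SE %.3f)   EC50 = %.3g M\n",
              x$pec50, x$se_pec50, 10^(-x$pec50)))
  cat(sprintf("  Imax  = %.3f (SE %.3f)\n", x$imax, x$se_imax))
  cat(sprintf("  nH    = %.3f (SE %.3f)\n", x$nh, x$se_nh))
  cat(sprintf("  RSS %.3g | converged: %s%s\n", x$rss, x$converged,
              if (x$extrapolated_plateau) " | plateau extrapolated" else ""))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, concentration = NULL, ...) {
  if (is.null(concentration)) concentration <- object$data$concentration
  hill_response(concentration, object$pec50, object$imax, object$nh)
}

#' Tidy a Hill fit
#'
#' @param x A `hill_fit` object.
#' @param ... Unused.
#' @return One row per parameter with estimate and asymptotic standard
#'   error.
#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(
    term = c("pec50", "imax", "nh"),
    estimate = c(x$pec50, x$imax, x$nh),
    std.error = c(x$se_pec50, x$se_imax, x$se_nh)
  )
}

#' @rdname tidy.hill_fit
#' @return `glance()`: a one-row tibble with fit-level summaries.
#' @method glance hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(
    pec50 = x$pec50, imax = x$imax, nh = x$nh, rss = x$rss,
    converged = x$converged, extrapolated_plateau = x$extrapolated_plateau,
    n_points = x$n_points
  )
}

#' Fit Hill curves for every (receptor, ligand) in a set of records
#'
#' Groups normalized concentration-response records by receptor and ligand,
#' pools replicate oocytes, and fits each curve with [fit_hill()].
#'
#' @param records Normalized concentration-response records (see
#'   [validate_response_records()]).
#' @param control A [hill_control()] list.
#' @return A tibble with one row per curve: `receptor`, `ligand`, the three
#'   parameter estimates with standard errors, `rss`, `converged`,
#'   `extrapolated_plateau`, `n_points`, and a list-column `fit` of
#'   `hill_fit` objects.
#' @export
fit_hill_curves <- function(records, control = hill_control()) {
  tbl <- validate_response_records(records)
  if (any(tbl$response_kind != "normalized")) {
    abort("fit_hill_curves() expects normalized responses; see normalize_responses().")
  }
  tbl %>%
    dplyr::group_by(.data$receptor, .data$ligand) %>%
    dplyr::group_modify(function(df, key) {
      fit <- fit_hill(df$concentration_molar, df$response, control = control)
      tibble::tibble(
        pec50 = fit$pec50, imax = fit$imax, nh = fit$nh,
        se_pec50 = fit$se_pec50, se_imax = fit$se_imax, se_nh = fit$se_nh,
        rss = fit$rss, converged = fit$converged,
        extrapolated_plateau = fit$extrapolated_plateau,
        n_points = fit$n_points, fit = list(fit)
      )
    }) %>%
    dplyr::ungroup()
}

#' Convert Hill-curve fits to a potency/efficacy table
#'
#' Reshapes the output of [fit_hill_curves()] into the summary-panel schema
#' consumed by the factor-model, CHAID and lattice stages. Standard errors
#' are the asymptotic fit SEs.
#'
#' @param fits Output of [fit_hill_curves()].
#' @param n Replicate count to record per curve (default 5 oocytes).
#' @return A validated potency tibble.
#' @export
fits_to_potency_table <- function(fits, n = 5L) {
  tbl <- tibble::tibble(
    receptor = fits$receptor, ligand = fits$ligand,
    pec50_mean = fits$pec50, pec50_se = fits$se_pec50,
    imax_mean = ifelse(fits$ligand == reference_ligand(), 1, fits$imax),
    imax_se = ifelse(fits$ligand == reference_ligand(), 0, fits$se_imax),
    n = n, core_panel = TRUE
  )
  validate_potency_table(tbl)
}

# Normalization ---------------------------------------------------------------

#' Normalize raw currents to the per-oocyte maximal ACh response
#'
#' Each oocyte's raw peak currents are divided by that oocyte's plateau
#' response to the reference agonist ACh, so responses become fractions of
#' the maximal ACh response (ACh plateau maps to ~1).
#'
#' @param records Concentration-response records with
#'   `response_kind = "raw_uA"`.
#' @param reference A data frame with columns `oocyte_id` and
#'   `reference_current` (the plateau ACh current of that oocyte, > 0).
#' @return The records with `response` divided by the matching reference
#'   and `response_kind = "normalized"`.
#' @export
normalize_responses <- function(records, reference) {
  tbl <- validate_response_records(records)
  if (!all(c("oocyte_id", "reference_current") %in% names(reference))) {
    abort("reference must have columns oocyte_id and reference_current.")
  }
  ref <- tibble::as_tibble(reference)
  missing_ids <- setdiff(unique(tbl$oocyte_id), ref$oocyte_id)
  bad_ref <- ref$oocyte_id[!is.finite(ref$reference_current) |
                             ref$reference_current <= 0]
  bad <- union(missing_ids, intersect(bad_ref, tbl$oocyte_id))
  if (length(bad) > 0) {
    abort(paste0(
      "Missing or non-positive ACh reference current for oocyte(s): ",
      paste(sort(as.character(bad)), collapse = ", "), "."
    ))
  }
  out <- dplyr::left_join(tbl, ref[, c("oocyte_id", "reference_current")],
                          by = "oocyte_id")
  out$response <- out$response / out$reference_current
  out$response_kind <- "normalized"
  out$reference_current <- NULL
  validate_response_records(out)
  out
}

# Potency arithmetic -----------------------------------------------------------

#' pEC50/EC50 conversions and potency fold-changes
#'
#' `pec50_to_ec50()` returns the molar EC50 `10^(-pEC50)`;
#' `ec50_nM()` renders it in nanomolar; `ec50_to_pec50()` inverts;
#' `fold_change()` returns the EC50 ratio `10^(pec50_high - pec50_low)`,
#' i.e. how many times lower the EC50 of the more potent pairing is.
#'
#' @param pec50,pec50_high,pec50_low Potencies in -log10 molar units.
#' @param ec50 Molar EC50.
#' @param digits Significant digits for the nanomolar rendering.
#' @return Numeric vector.
#' @export
#' @examples
#' ec50_nM(6.99)           # 102 nM
#' fold_change(8.32, 7.16) # 14.45-fold EC50 difference
pec50_to_ec50 <- function(pec50) {
  stopifnot(all(is.finite(pec50)))
  10^(-pec50)
}

#' @rdname pec50_to_ec50
#' @export
ec50_nM <- function(pec50, digits = 3) {
  signif(pec50_to_ec50(pec50) * 1e9, digits)
}

#' @rdname pec50_to_ec50
#' @export
ec50_to_pec50 <- function(ec50) {
  stopifnot(all(is.finite(ec50) & ec50 > 0))
  -log10(ec50)
}

#' @rdname pec50_to_ec50
#' @export
fold_change <- function(pec50_high, pec50_low) {
  stopifnot(all(is.finite(pec50_high)), all(is.finite(pec50_low)))
  10^(pec50_high - pec50_low)
}
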