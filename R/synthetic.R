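# Ground-truth-known synthetic electrophysiology data.
#
# The generator is the generative inverse of the factor model: true pEC50
# surfaces are subunit-additive (intercept + per-subunit effects + per-
# compound offset), efficacies are compound-specific, and per-oocyte
# concentration-response curves are Hill-shaped with Gaussian response
# noise truncated at zero. Every stage of the pipeline can therefore be
# checked against configured truth without any external data.

#' The 12 core-panel receptor combinations
#'
#' Every subunit set containing the essential Db1 plus any combination of
#' Da1, Da2, Da3, Db2 that includes at least one of the robustly
#' expressing alpha subunits Da1 or Da3 (combinations with Da2 as the only
#' alpha subunit do not express).
#'
#' @return Character vector of 12 canonical receptor keys.
#' @export
core_panel_receptors <- function() {
  combos <- expand.grid(Da1 = 0:1, Da2 = 0:1, Da3 = 0:1, Db2 = 0:1)
  combos <- combos[combos$Da1 == 1 | combos$Da3 == 1, ]
  apply(combos, 1, function(r) {
    members <- c(names(r)[r == 1], "Db1")
    subunit_key(members)
  }) |> unname() |> sort()
}

#' Ground-truth configuration for the synthetic panel
#'
#' Defaults mirror the fitted additive model of the published panel:
#' subunit effects Da1 -0.306, Da2 -0.754, Da3 +0.524, Db2 +0.092 around
#' an ACh intercept of 6.96; compound pEC50 offsets and true Imax values
#' at the panel's per-compound means. The reference ligand has offset 0
#' and Imax 1 by definition.
#'
#' @param subunit_effects Named additive pEC50 contributions per subunit.
#' @param intercept Baseline pEC50 of the reference ligand on a receptor
#'   with none of the modeled subunits.
#' @param compound_offsets Named additive pEC50 offsets vs the reference
#'   ligand (reference must be 0).
#' @param compound_imax Named true Imax per ligand (reference must be 1).
#' @param nh_range Interval the per-curve true Hill coefficient is drawn
#'   from (default `c(1, 2)`).
#' @param receptors Panel of receptor keys (default the 12-receptor core
#'   panel); all must be functional (contain Db1).
#' @param seed Integer seed controlling the (deterministic) Hill-
#'   coefficient draw.
#' @return A list of class `truth_config`.
#' @export
truth_config <- function(
    subunit_effects = c(Da1 = -0.306, Da2 = -0.754, Da3 = 0.524, Db2 = 0.092),
    intercept = 6.96,
    compound_offsets = c(ACh = 0, imidacloprid = 1.785, thiacloprid = 2.229,
                         clothianidin = 1.414),
    compound_imax = c(ACh = 1, imidacloprid = 0.119, thiacloprid = 0.049,
                      clothianidin = 0.667),
    nh_range = c(1, 2),
    receptors = core_panel_receptors(),
    seed = 1L) {
  ref <- reference_ligand()
  stopifnot(!is.null(names(subunit_effects)),
            !is.null(names(compound_offsets)),
            !is.null(names(compound_imax)),
            length(nh_range) == 2, nh_range[1] <= nh_range[2],
            nh_range[1] > 0)
  if (!ref %in% names(compound_offsets) || compound_offsets[[ref]] != 0) {
    abort("The reference ligand must have compound offset 0.")
  }
  if (!ref %in% names(compound_imax) || compound_imax[[ref]] != 1) {
    abort("The reference ligand must have true Imax 1.")
  }
  receptors <- vapply(receptors, subunit_key, character(1), USE.NAMES = FALSE)
  not_fun <- receptors[!is_functional_receptor(receptors)]
  if (length(not_fun) > 0) {
    abort(paste0("Non-functional receptor(s) (no Db1): ",
                 paste(not_fun, collapse = ", "), "."))
  }
  structure(list(subunit_effects = subunit_effects, intercept = intercept,
                 compound_offsets = compound_offsets,
                 compound_imax = compound_imax, nh_range = nh_range,
                 receptors = receptors, seed = as.integer(seed)),
            class = "truth_config")
}

#' Noise configuration for simulated curves
#'
#' @param response_sigma Gaussian SD of the normalized response noise
#'   (default 0.03, the scale implied by the panel's reported standard
#'   errors).
#' @param n_oocytes Replicate oocytes per curve (default 5, the study's
#'   replication level).
#' @param concentrations Molar concentration grid applied to every curve,
#'   or `NULL` (default) for per-curve dose-ranging: 8 half-log-spaced
#'   concentrations bracketing each curve's true EC50, emulating how
#'   concentration ranges are chosen per ligand and receptor in practice.
#' @param seed Integer seed for the noise draws.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(response_sigma = 0.03, n_oocytes = 5,
                         concentrations = NULL, seed = 1L) {
  stopifnot(response_sigma >= 0, n_oocytes >= 1)
  if (!is.null(concentrations)) {
    stopifnot(all(is.finite(concentrations) & concentrations > 0))
  }
  structure(list(response_sigma = response_sigma,
                 n_oocytes = as.integer(n_oocytes),
                 concentrations = concentrations, seed = as.integer(seed)),
            class = "noise_config")
}

#' Generate the ground-truth potency table
#'
#' Applies the additive model: `pEC50(receptor, ligand) = intercept +
#' sum(subunit effects of the receptor's members) + compound offset`, with
#' compound-specific Imax and a per-curve Hill coefficient drawn uniformly
#' (seeded, hence deterministic) from `nh_range`. Standard errors are 0.
#'
#' @param config A [truth_config()].
#' @return A potency tibble with an extra `nh_true` column.
#' @export
#' @examples
#' truth <- generate_truth(truth_config())
#' dplyr::filter(truth, receptor == "Da3/Db1", ligand == "ACh")  # 6.96 + 0.524
generate_truth <- function(config = truth_config()) {
  stopifnot(inherits(config, "truth_config"))
  effects <- config$subunit_effects
  ligands <- names(config$compound_offsets)
  grid <- tidyr::expand_grid(receptor = config$receptors, ligand = ligands)
  pec50 <- vapply(seq_len(nrow(grid)), function(i) {
    members <- parse_subunits(grid$receptor[i])
    unknown <- setdiff(members, c(names(effects), "Db1"))
    if (length(unknown) > 0) {
      abort(paste0("No configured effect for subunit(s): ",
                   paste(unknown, collapse = ", "), "."))
    }
    config$intercept + sum(effects[intersect(members, names(effects))]) +
      config$compound_offsets[[grid$ligand[i]]]
  }, numeric(1))
  nh <- withr::with_seed(config$seed, {
    stats::runif(nrow(grid), config$nh_range[1], config$nh_range[2])
  })
  tbl <- tibble::tibble(
    receptor = grid$receptor, ligand = grid$ligand,
    pec50_mean = pec50, pec50_se = 0,
    imax_mean = unname(config$compound_imax[grid$ligand]), imax_se = 0,
    n = 1L, core_panel = TRUE, nh_true = nh
  )
  validate_potency_table(tbl)
  tbl
}

per_curve_grid <- function(pec50, n_points = 8, step = 0.5) {
  offsets <- (seq_len(n_points) - (n_points + 1) / 2) * step
  10^(-pec50 + offsets)
}

#' Simulate per-oocyte concentration-response records
#'
#' For every (receptor, ligand) curve of a truth table, draws `n_oocytes`
#' replicate response series on the concentration grid: `response =
#' Hill(truth) + N(0, sigma)`, truncated at 0 (currents cannot be
#' negative). All randomness flows from `noise$seed`; identical configs
#' give identical output.
#'
#' @param truth A truth table from [generate_truth()] (needs `nh_true`).
#' @param noise A [noise_config()].
#' @return A normalized concentration-response records tibble.
#' @export
simulate_curves <- function(truth, noise = noise_config()) {
  stopifnot(inherits(noise, "noise_config"))
  tbl <- validate_potency_table(truth)
  if (!"nh_true" %in% names(tbl)) {
    abort("Truth table must carry an nh_true column (see generate_truth()).")
  }
  withr::with_seed(noise$seed, {
    rows <- lapply(seq_len(nrow(tbl)), function(i) {
      conc <- if (is.null(noise$concentrations)) {
        per_curve_grid(tbl$pec50_mean[i])
      } else noise$concentrations
      grid <- tidyr::expand_grid(oocyte = seq_len(noise$n_oocytes),
                                 concentration_molar = conc)
      mu <- hill_response(grid$concentration_molar, tbl$pec50_mean[i],
                          tbl$imax_mean[i], tbl$nh_true[i])
      eps <- stats::rnorm(nrow(grid), 0, noise$response_sigma)
      tibble::tibble(
        oocyte_id = sprintf("%s|%s|oo%02d", tbl$receptor[i], tbl$ligand[i],
                            grid$oocyte),
        receptor = tbl$receptor[i], ligand = tbl$ligand[i],
        concentration_molar = grid$concentration_molar,
        response = pmax(0, mu + eps),
        response_kind = "normalized"
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Parameter-recovery experiment
#'
#' Runs the full pipeline `simulate_curves -> fit_hill_curves ->
#' fit_factor_model` on `n_reps` independently seeded replicates of the
#' same truth, and summarizes how well the configured subunit effects are
#' recovered: bias, RMSE and 95%-CI coverage per subunit, plus the mean
#' bias of the per-curve Hill pEC50 estimates.
#'
#' @param truth_cfg A [truth_config()].
#' @param noise_cfg A [noise_config()]; replicate r uses seed
#'   `noise_cfg$seed + r - 1`.
#' @param n_reps Number of replicates (>= 1).
#' @return A list of class `recovery_report`: `summary` (one row per
#'   subunit: `term`, `true`, `bias`, `rmse`, `coverage`),
#'   `pec50_bias` (mean and max absolute bias of fitted pEC50s), and
#'   `estimates` (per-replicate coefficient estimates).
#' @export
recovery_experiment <- function(truth_cfg = truth_config(),
                                noise_cfg = noise_config(), n_reps = 1) {
  stopifnot(n_reps >= 1)
  truth <- generate_truth(truth_cfg)
  true_effects <- truth_cfg$subunit_effects
  est_rows <- vector("list", n_reps)
  hill_bias <- numeric(0)
  for (r in seq_len(n_reps)) {
    nc <- noise_cfg
    nc$seed <- noise_cfg$seed + r - 1L
    records <- simulate_curves(truth, nc)
    fits <- fit_hill_curves(records)
    hill_bias <- c(hill_bias, fits$pec50 -
                     truth$pec50_mean[match(paste(fits$receptor, fits$ligand),
                                            paste(truth$receptor, truth$ligand))])
    panel <- fits_to_potency_table(fits, n = nc$n_oocytes)
    fit <- fit_factor_model(panel, "pec50",
                            subunits = names(true_effects))
    td <- tidy(fit)
    sel <- td$term %in% names(true_effects)
    est_rows[[r]] <- tibble::tibble(
      rep = r, term = td$term[sel], estimate = td$estimate[sel],
      conf.low = td$conf.low[sel], conf.high = td$conf.high[sel]
    )
  }
  est <- dplyr::bind_rows(est_rows)
  est$true <- unname(true_effects[est$term])
  summary <- est %>%
    dplyr::group_by(.data$term) %>%
    dplyr::summarise(
      true = .data$true[1],
      bias = mean(.data$estimate - .data$true),
      rmse = sqrt(mean((.data$estimate - .data$true)^2)),
      coverage = mean(.data$conf.low <= .data$true &
                        .data$true <= .data$conf.high),
      .groups = "drop"
    )
  structure(list(summary = summary,
                 pec50_bias = tibble::tibble(
                   mean_bias = mean(hill_bias),
                   max_abs_bias = max(abs(hill_bias))),
                 estimates = est),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter-recovery report (", max(x$estimates$rep), " replicate(s))\n",
      sep = "")
  print(x$summary, n = Inf)
  cat(sprintf("Hill pEC50: mean bias %.4f, max |bias| %.4f\n",
              x$pec50_bias$mean_bias, x$pec50_bias$max_abs_bias))
  invisible(x)
}
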