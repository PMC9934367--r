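# Powerset (Hasse) lattice analysis of subunit contributions.
#
# Receptor subunit sets are partially ordered by inclusion; Hasse edges
# connect sets differing by exactly one subunit and are labeled "+<subunit>"
# by the added member. Each edge, evaluated for a ligand, carries
# delta = pEC50(larger set) - pEC50(smaller set); grouping the deltas by the
# added subunit and forming a t-based 95% CI summarizes that subunit's
# potency contribution.

#' Hasse-diagram edges of a receptor collection
#'
#' All ordered pairs of receptors in the collection whose subunit sets
#' differ by exactly one added subunit.
#'
#' @param receptors Character vector of receptor keys (>= 2 distinct).
#' @return A tibble with `smaller`, `larger`, `added_subunit`.
#' @export
#' @examples
#' hasse_edges(c("Da1/Db1", "Da1/Da2/Db1", "Da1/Db1/Db2"))
hasse_edges <- function(receptors) {
  keys <- unique(vapply(receptors, subunit_key, character(1),
                        USE.NAMES = FALSE))
  if (length(keys) < 2) abort("Need at least 2 distinct receptors.")
  sets <- lapply(keys, parse_subunits)
  sizes <- lengths(sets)
  edges <- list()
  for (i in seq_along(keys)) {
    for (j in seq_along(keys)) {
      if (sizes[j] != sizes[i] + 1L) next
      if (all(sets[[i]] %in% sets[[j]])) {
        edges[[length(edges) + 1L]] <- tibble::tibble(
          smaller = keys[i], larger = keys[j],
          added_subunit = setdiff(sets[[j]], sets[[i]])
        )
      }
    }
  }
  if (length(edges) == 0) {
    return(tibble::tibble(smaller = character(), larger = character(),
                          added_subunit = character()))
  }
  dplyr::arrange(dplyr::bind_rows(edges), .data$added_subunit,
                 .data$smaller, .data$larger)
}

#' Per-edge, per-ligand pEC50 increments
#'
#' Evaluates every Hasse edge of the panel's receptors for each requested
#' ligand: `delta = pEC50(larger) - pEC50(smaller)`.
#'
#' @param panel A potency table (core-panel rows used by default).
#' @param ligands Ligand names to evaluate, or `NULL` for every ligand in
#'   the panel.
#' @param skeleton Optional pre-built edge table from [hasse_edges()];
#'   defaults to the edges of the panel's receptors.
#' @param core_only Restrict to `core_panel` receptors (default `TRUE`).
#' @return A tibble with `smaller`, `larger`, `added_subunit`, `ligand`,
#'   `delta`.
#' @export
#' @examples
#' deltas <- lattice_deltas(dmel_nachr_panel())
#' dplyr::filter(deltas, added_subunit == "Da2", ligand == "ACh")
lattice_deltas <- function(panel, ligands = NULL, skeleton = NULL,
                           core_only = TRUE) {
  tbl <- validate_potency_table(panel)
  if (core_only) tbl <- dplyr::filter(tbl, .data$core_panel)
  if (is.null(ligands)) ligands <- unique(tbl$ligand)
  if (is.null(skeleton)) skeleton <- hasse_edges(unique(tbl$receptor))
  lookup <- stats::setNames(tbl$pec50_mean,
                            paste(tbl$receptor, tbl$ligand, sep = "|"))
  out <- tidyr::expand_grid(skeleton, ligand = ligands)
  key_small <- paste(out$smaller, out$ligand, sep = "|")
  key_large <- paste(out$larger, out$ligand, sep = "|")
  missing_keys <- setdiff(c(key_small, key_large), names(lookup))
  if (length(missing_keys) > 0) {
    abort(paste0("Panel is missing pEC50 for: ",
                 paste(sub("\\|", " x ", missing_keys), collapse = "; "), "."))
  }
  out$delta <- unname(lookup[key_large] - lookup[key_small])
  out
}

#' Summarize pEC50 increments by added subunit
#'
#' Pools each subunit's edge deltas (across ligands unless `per_ligand`)
#' and reports the mean with a t-based 95% confidence interval; the
#' contribution is flagged significant when the interval excludes zero.
#' Subunits with fewer than 2 deltas get an undefined CI and a warning
#' flag. A subunit that never appears as an added member (Db1 on the core
#' panel, where it is always present) is simply absent from the output.
#'
#' @param deltas Edge deltas from [lattice_deltas()].
#' @param per_ligand Summarize per (subunit, ligand) instead of pooling
#'   across ligands (default `FALSE`).
#' @param conf.level Confidence level (default 0.95).
#' @return A tibble with `subunit` (and `ligand` if per-ligand),
#'   `n_edges`, `mean_delta`, `ci_low`, `ci_high`, `significant`,
#'   `ci_defined`.
#' @export
subunit_delta_summary <- function(deltas, per_ligand = FALSE,
                                  conf.level = 0.95) {
  grp <- if (per_ligand) c("added_subunit", "ligand") else "added_subunit"
  out <- deltas %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
    dplyr::summarise(
      n_edges = dplyr::n(),
      mean_delta = mean(.data$delta),
      sd_delta = stats::sd(.data$delta),
      .groups = "drop"
    )
  half <- ifelse(out$n_edges >= 2,
                 stats::qt(1 - (1 - conf.level) / 2, out$n_edges - 1) *
                   out$sd_delta / sqrt(out$n_edges),
                 NA_real_)
  out$ci_low <- out$mean_delta - half
  out$ci_high <- out$mean_delta + half
  out$ci_defined <- out$n_edges >= 2
  out$significant <- !is.na(half) & (out$ci_low > 0 | out$ci_high < 0)
  if (any(!out$ci_defined)) {
    warn(paste0(
      "Subunit(s) with < 2 edge deltas (CI undefined): ",
      paste(out$added_subunit[!out$ci_defined], collapse = ", "), "."
    ))
  }
  out <- dplyr::rename(out, subunit = "added_subunit")
  out$sd_delta <- NULL
  out
}

#' DOT description of the subunit lattice
#'
#' Renders the Hasse diagram (optionally with per-edge mean deltas) as a
#' Graphviz DOT string for external rendering.
#'
#' @param deltas Edge deltas from [lattice_deltas()].
#' @return A single DOT-format string.
#' @export
lattice_dot <- function(deltas) {
  agg <- deltas %>%
    dplyr::group_by(.data$smaller, .data$larger, .data$added_subunit) %>%
    dplyr::summarise(delta = mean(.data$delta), .groups = "drop")
  nodes <- unique(c(agg$smaller, agg$larger))
  node_lines <- sprintf('  "%s" [label="%s"];', nodes, format_subunits(nodes))
  edge_lines <- sprintf('  "%s" -> "%s" [label="+%s (%+.2f)"];',
                        agg$smaller, agg$larger,
                        format_subunits(agg$added_subunit), agg$delta)
  paste(c("digraph subunit_lattice {", "  rankdir=BT;",
          node_lines, edge_lines, "}"), collapse = "\n")
}
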