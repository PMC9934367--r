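# ggplot2 views of the result types.

#' Plot a fitted Hill curve
#'
#' Observed points and the fitted concentration-response curve on a log
#' concentration axis, with the EC50 marked.
#'
#' @param object A `hill_fit`.
#' @param n_curve Points used to draw the smooth curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hill_fit
#' @export
autoplot.hill_fit <- function(object, n_curve = 200, ...) {
  rng <- range(log10(object$data$concentration))
  curve <- tibble::tibble(
    concentration = 10^seq(rng[1] - 0.25, rng[2] + 0.25,
                           length.out = n_curve)
  )
  curve$response <- predict(object, curve$concentration)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = 10^(-object$pec50), linetype = 2,
                        colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (M)", y = "normalized response",
                  title = sprintf("pEC50 %.2f, Imax %.2f, nH %.2f",
                                  object$pec50, object$imax, object$nh)) +
    ggplot2::theme_minimal()
}

#' Coefficient plot of a factor-model fit
#'
#' Point estimates with 95% confidence intervals for every term of the
#' additive subunit/compound model; intervals excluding zero are
#' highlighted.
#'
#' @param object A `factor_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot factor_fit
#' @export
autoplot.factor_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", ]
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term,
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey40"),
                                 guide = "none") +
    ggplot2::labs(x = paste0("coefficient (", object$outcome, ")"),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a CHAID tree
#'
#' Simple node-and-edge layout: leaves are spaced evenly, internal nodes
#' sit above the mean position of their children, and each node is
#' labeled with its condition, mean outcome and size.
#'
#' @param object A `chaid_tree`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chaid_tree
#' @export
autoplot.chaid_tree <- function(object, ...) {
  td <- tidy(object)
  x <- rep(NA_real_, nrow(td))
  leaf_ids <- td$node_id[td$is_leaf]
  x[match(leaf_ids, td$node_id)] <- seq_along(leaf_ids)
  for (d in sort(unique(td$depth), decreasing = TRUE)) {
    for (i in which(td$depth == d & !td$is_leaf)) {
      kids <- td$node_id[!is.na(td$parent_id) & td$parent_id == td$node_id[i]]
      x[i] <- mean(x[match(kids, td$node_id)])
    }
  }
  td$x <- x
  td$y <- -td$depth
  td$label <- sprintf("%s\nmean %.3f (n = %d)", td$condition, td$mean, td$n)
  seg <- td[!is.na(td$parent_id), ]
  seg$xend <- td$x[match(seg$parent_id, td$node_id)]
  seg$yend <- td$y[match(seg$parent_id, td$node_id)]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(xend = .data$xend, yend = .data$yend),
                          colour = "grey60") +
    ggplot2::geom_label(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::theme_void()
}

#' Heatmap of a potency/efficacy panel
#'
#' Receptor-by-ligand tile plot of pEC50 (affinity) or Imax (efficacy),
#' the standard overview of a subunit-combination panel.
#'
#' @param panel A potency table.
#' @param value `"pec50"` or `"imax"`.
#' @param core_only Restrict to the core panel (default `FALSE`).
#' @return A ggplot object.
#' @export
plot_potency_heatmap <- function(panel, value = c("pec50", "imax"),
                                 core_only = FALSE) {
  value <- match.arg(value)
  tbl <- validate_potency_table(panel)
  if (core_only) tbl <- dplyr::filter(tbl, .data$core_panel)
  col <- if (value == "pec50") "pec50_mean" else "imax_mean"
  tbl$receptor_disp <- factor(format_subunits(tbl$receptor),
                              levels = rev(unique(format_subunits(tbl$receptor))))
  tbl$ligand <- as_ligand_factor(tbl$ligand)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$ligand,
                                    y = .data$receptor_disp,
                                    fill = .data[[col]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (value == "pec50") "pEC50" else "Imax") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of subunit delta summaries
#'
#' Mean per-subunit pEC50 increment with its 95% confidence interval, as
#' produced by [subunit_delta_summary()].
#'
#' @param summary Output of [subunit_delta_summary()].
#' @return A ggplot object.
#' @export
plot_delta_summary <- function(summary) {
  summary$subunit_disp <- format_subunits(summary$subunit)
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$mean_delta, y = .data$subunit_disp,
                               colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey40"),
                                 guide = "none") +
    ggplot2::labs(x = expression(Delta * "pEC50 per added subunit"),
                  y = NULL) +
    ggplot2::theme_minimal()
}
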