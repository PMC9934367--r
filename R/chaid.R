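# CHAID-style regression tree for a continuous outcome over categorical
# predictors (Kass's procedure): within each predictor, categories with
# indistinguishable outcome distributions are merged by pairwise F-tests;
# the split predictor is the one whose merged grouping gives the smallest
# Bonferroni-adjusted one-way ANOVA p-value; growth stops at a depth limit,
# a minimum node size, or when no adjusted p clears the significance
# threshold. Everything is deterministic: no randomness, ties broken by
# predictor order.

#' CHAID tree settings
#'
#' @param max_depth Maximum number of node levels, root included (default
#'   4, so at most 3 splits along any root-to-leaf path).
#' @param alpha_split Significance threshold an adjusted split p-value must
#'   clear (default 0.05). Setting it to 1 disables the significance stop,
#'   so nodes split on the best available predictor until the depth or
#'   node-size limit — the behaviour of common CHAID implementations that
#'   gate only on depth and node size, and the configuration under which
#'   the published panel tree (whose deeper splits are not significant at
#'   0.05) is reproduced.
#' @param alpha_merge Categories whose pairwise F-test p-value exceeds this
#'   are merged (default 0.05).
#' @param min_node Minimum samples per node; a split leaving any child
#'   smaller is inadmissible (default 2).
#' @param bonferroni Multiply each predictor's ANOVA p-value by the number
#'   of ways its original categories can collapse to the merged grouping
#'   (default `TRUE`; the multiplier is 1 for binary predictors).
#' @return A list of class `chaid_control`.
#' @export
chaid_control <- function(max_depth = 4, alpha_split = 0.05,
                          alpha_merge = 0.05, min_node = 2,
                          bonferroni = TRUE) {
  stopifnot(max_depth >= 1, alpha_split > 0, alpha_split <= 1,
            alpha_merge > 0, alpha_merge < 1, min_node >= 1)
  structure(list(max_depth = max_depth, alpha_split = alpha_split,
                 alpha_merge = alpha_merge, min_node = min_node,
                 bonferroni = bonferroni),
            class = "chaid_control")
}

# Two-group F-test (square of the pooled-variance t statistic).
pairwise_f_p <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  df <- n1 + n2 - 2
  if (df <= 0) return(1)
  s2p <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / df
  d <- mean(x1) - mean(x2)
  if (s2p <= 0) return(if (abs(d) <= .Machine$double.eps^0.5) 1 else 0)
  f <- d^2 / (s2p * (1 / n1 + 1 / n2))
  stats::pf(f, 1, df, lower.tail = FALSE)
}

# One-way ANOVA p-value for a merged grouping.
anova_f_p <- function(values, group) {
  k <- length(unique(group))
  n <- length(values)
  if (k < 2 || n - k <= 0) return(1)
  gm <- mean(values)
  means <- tapply(values, group, mean)
  ns <- tapply(values, group, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[match(group, names(means))])^2)
  if (ssw <= .Machine$double.eps * max(1, ssb)) {
    return(if (ssb <= .Machine$double.eps) 1 else 0)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  stats::pf(f, k - 1, n - k, lower.tail = FALSE)
}

# Number of ways c original categories can collapse into r non-empty
# groups (Stirling number of the second kind; Kass's Bonferroni
# multiplier for free categorical predictors). S(2, 2) = 1, so binary
# predictors are never penalized.
n_collapsings <- function(c_orig, r_groups) {
  i <- 0:(r_groups - 1)
  round(sum((-1)^i * (r_groups - i)^c_orig /
              (factorial(i) * factorial(r_groups - i))))
}

#' Merge predictor categories by pairwise F-tests
#'
#' Iteratively merges the pair of category groups with the largest
#' pairwise F-test p-value until every pairwise p-value is at or below
#' `alpha_merge` or a single group remains. Predictors with only two
#' original categories are returned unchanged.
#'
#' @param values Numeric outcome values.
#' @param categories Category label for each value.
#' @param alpha_merge Merge threshold (default 0.05).
#' @return A list of character vectors, each the original categories
#'   forming one merged group.
#' @export
#' @examples
#' chaid_merge_categories(c(1, 1.1, 5, 5.2, 5.1, 4.9),
#'                        c("a", "a", "b", "b", "c", "c"))
chaid_merge_categories <- function(values, categories, alpha_merge = 0.05) {
  categories <- as.character(categories)
  stopifnot(length(values) == length(categories))
  if (any(tapply(values, categories, length) == 0)) {
    abort("Empty category in merge step.")
  }
  lev <- unique(categories)
  if (length(lev) < 2) {
    abort("Category merging needs at least 2 categories.")
  }
  groups <- as.list(lev)
  if (length(lev) == 2) return(groups)
  repeat {
    if (length(groups) == 1) break
    vals <- lapply(groups, function(g) values[categories %in% g])
    pairs <- utils::combn(length(groups), 2)
    ps <- apply(pairs, 2, function(ij) pairwise_f_p(vals[[ij[1]]], vals[[ij[2]]]))
    worst <- which.max(ps)
    if (ps[worst] <= alpha_merge) break
    ij <- pairs[, worst]
    merged <- c(groups[[ij[1]]], groups[[ij[2]]])
    groups <- c(groups[-ij], list(merged))
  }
  groups
}

#' Best CHAID split for one node
#'
#' For each candidate predictor: merge its categories, run the one-way
#' F-test across the merged groups, and Bonferroni-adjust by the number of
#' ways the original categories can collapse to that grouping. Returns the
#' predictor with the smallest adjusted p-value if it clears
#' `alpha_split`, otherwise `NULL`. Ties are broken by predictor order.
#'
#' @param data A data frame.
#' @param outcome Name of the numeric outcome column.
#' @param predictors Character vector of candidate predictor columns.
#' @param control A [chaid_control()].
#' @return `NULL`, or a list with `predictor`, `p_adj`, `p_raw`, `groups`
#'   (the merged category groups).
#' @export
chaid_best_split <- function(data, outcome, predictors,
                             control = chaid_control()) {
  missing_pred <- setdiff(predictors, names(data))
  if (length(missing_pred) > 0) {
    abort(paste0("Predictor(s) absent from data: ",
                 paste(missing_pred, collapse = ", "), "."))
  }
  y <- data[[outcome]]
  best <- NULL
  for (pred in predictors) {
    cats <- as.character(data[[pred]])
    lev <- unique(cats)
    if (length(lev) < 2) next
    groups <- chaid_merge_categories(y, cats, control$alpha_merge)
    if (length(groups) < 2) next
    assign <- vapply(cats, function(cc)
      which(vapply(groups, function(g) cc %in% g, logical(1))), integer(1))
    sizes <- tabulate(assign, nbins = length(groups))
    if (any(sizes < control$min_node)) next
    p_raw <- anova_f_p(y, assign)
    mult <- if (control$bonferroni) n_collapsings(length(lev), length(groups)) else 1
    p_adj <- min(1, p_raw * mult)
    if (is.null(best) || p_adj < best$p_adj) {
      best <- list(predictor = pred, p_adj = p_adj, p_raw = p_raw,
                   groups = groups)
    }
  }
  if (is.null(best) || best$p_adj > control$alpha_split) return(NULL)
  best
}

grow_node <- function(data, outcome, predictors, control, depth, predicate) {
  y <- data[[outcome]]
  node <- list(predicate = predicate, n = length(y), mean = mean(y),
               depth = depth, split_var = NA_character_, p_adj = NA_real_,
               groups = NULL, children = list())
  if (depth < control$max_depth && length(y) >= 2 * control$min_node) {
    split <- chaid_best_split(data, outcome, predictors, control)
    if (!is.null(split)) {
      node$split_var <- split$predictor
      node$p_adj <- split$p_adj
      node$groups <- split$groups
      cats <- as.character(data[[split$predictor]])
      node$children <- lapply(split$groups, function(g) {
        sub <- data[cats %in% g, , drop = FALSE]
        child_pred <- c(predicate,
                        stats::setNames(list(g), split$predictor))
        grow_node(sub, outcome, predictors, control, depth + 1, child_pred)
      })
    }
  }
  node
}

#' Fit a CHAID regression tree
#'
#' Recursive application of [chaid_best_split()] from the root down, with
#' the depth, node-size and significance stopping rules of
#' [chaid_control()]. Fully deterministic.
#'
#' @inheritParams chaid_best_split
#' @return An object of class `chaid_tree` with the nested root node and
#'   metadata. Methods: `print`, [tidy.chaid_tree()], [chaid_leaves()],
#'   `autoplot`.
#' @export
#' @examples
#' d <- chaid_data(dmel_nachr_panel())
#' tree <- fit_chaid(d, "outcome", c("Da1", "Da2", "Da3", "Db2"))
#' tree
fit_chaid <- function(data, outcome, predictors,
                      control = chaid_control()) {
  if (!outcome %in% names(data)) {
    abort(paste0("Outcome column '", outcome, "' absent from data."))
  }
  missing_pred <- setdiff(predictors, names(data))
  if (length(missing_pred) > 0) {
    abort(paste0("Predictor(s) absent from data: ",
                 paste(missing_pred, collapse = ", "), "."))
  }
  data <- as.data.frame(data)
  root <- grow_node(data, outcome, predictors, control, depth = 1L,
                    predicate = list())
  structure(list(root = root, outcome = outcome, predictors = predictors,
                 control = control),
            class = "chaid_tree")
}

#' Node-level data of a CHAID tree
#'
#' @param x A `chaid_tree`.
#' @param ... Unused.
#' @return A tibble with one row per node: `node_id`, `parent_id`,
#'   `depth`, `condition` (the predicate step that formed the node),
#'   `predicate` (list-column of the full path predicate), `n`, `mean`,
#'   `split_var`, `p_adj`, `is_leaf`.
#' @method tidy chaid_tree
#' @export
tidy.chaid_tree <- function(x, ...) {
  rows <- list()
  walk <- function(node, parent_id) {
    id <- length(rows) + 1L
    cond <- if (length(node$predicate) == 0) "<root>" else {
      last <- length(node$predicate)
      paste0(names(node$predicate)[last], " in {",
             paste(node$predicate[[last]], collapse = ","), "}")
    }
    rows[[id]] <<- tibble::tibble(
      node_id = id, parent_id = parent_id, depth = node$depth,
      condition = cond, predicate = list(node$predicate),
      n = node$n, mean = node$mean, split_var = node$split_var,
      p_adj = node$p_adj, is_leaf = length(node$children) == 0
    )
    for (ch in node$children) walk(ch, id)
  }
  walk(x$root, NA_integer_)
  dplyr::bind_rows(rows)
}

#' Leaves of a CHAID tree
#'
#' @param tree A `chaid_tree`.
#' @return The leaf rows of [tidy.chaid_tree()], with a readable
#'   `path` label.
#' @export
chaid_leaves <- function(tree) {
  td <- tidy(tree)
  td$path <- vapply(td$predicate, function(p) {
    if (length(p) == 0) "<root>" else
      paste(vapply(seq_along(p), function(i)
        paste0(names(p)[i], "={", paste(p[[i]], collapse = ","), "}"),
        character(1)), collapse = " & ")
  }, character(1))
  dplyr::filter(td, .data$is_leaf)
}

#' @export
print.chaid_tree <- function(x, ...) {
  cat("CHAID regression tree (outcome: ", x$outcome, ")\n", sep = "")
  walk <- function(node, indent) {
    pad <- strrep("  ", indent)
    lab <- if (length(node$predicate) == 0) "<root>" else {
      last <- length(node$predicate)
      paste0(names(node$predicate)[last], " in {",
             paste(node$predicate[[last]], collapse = ","), "}")
    }
    extra <- if (!is.na(node$split_var))
      sprintf("  split: %s (p_adj = %.3g)", node$split_var, node$p_adj) else ""
    cat(sprintf("%s%s  [mean %.3f, n %d]%s\n", pad, lab, node$mean, node$n,
                extra))
    for (ch in node$children) walk(ch, indent + 1)
  }
  walk(x$root, 0)
  invisible(x)
}

#' Count and mean of rows matching a predicate
#'
#' Direct node-statistic query without growing a tree: the predicate is a
#' named list mapping predictor columns to allowed values, all conditions
#' conjoined.
#'
#' @param data A data frame.
#' @param predicate Named list, e.g. `list(Da1 = "without", Da3 = "with")`.
#' @param outcome Name of the numeric outcome column.
#' @return A tibble with `n` and `mean`.
#' @export
#' @examples
#' d <- chaid_data(dmel_nachr_panel())
#' node_stats(d, list(Da1 = "without", Da2 = "without", Da3 = "with"))
node_stats <- function(data, predicate, outcome = "outcome") {
  missing_cols <- setdiff(c(names(predicate), outcome), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Unknown column(s) in predicate/outcome: ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  keep <- rep(TRUE, nrow(data))
  for (col in names(predicate)) {
    keep <- keep & as.character(data[[col]]) %in% as.character(predicate[[col]])
  }
  if (!any(keep)) abort("Predicate matches no rows.")
  tibble::tibble(n = sum(keep), mean = mean(data[[outcome]][keep]))
}

#' Panel data shaped for CHAID
#'
#' Expands the core panel into a 48-row data frame with subunit presence
#' coded as `"with"`/`"without"` factors, the compound as a factor, and
#' the chosen outcome in column `outcome`.
#'
#' @inheritParams build_design
#' @param include_compound Add the `compound` column as a candidate
#'   predictor value set (default `TRUE`; whether it is *used* is decided
#'   by the `predictors` argument of [fit_chaid()]).
#' @return A tibble ready for [fit_chaid()] / [node_stats()].
#' @export
chaid_data <- function(panel, outcome = c("pec50", "imax"),
                       subunits = c("Da1", "Da2", "Da3", "Db2"),
                       include_compound = TRUE) {
  outcome <- match.arg(outcome)
  design <- build_design(panel, outcome, subunits = subunits)
  out <- design
  for (s in subunits) {
    out[[s]] <- factor(ifelse(design[[s]] == 1, "with", "without"),
                       levels = c("without", "with"))
  }
  if (include_compound) out$compound <- design$ligand
  out$ligand <- NULL
  out
}
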