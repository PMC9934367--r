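# Independent oracles used to cross-check the package's estimators.

# Ordinary least squares by the normal equations (no lm()).
ols_normal_equations <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# Model matrix for the panel factor model, built by hand from the design
# tibble (intercept + subunit indicators + ligand dummies).
oracle_model_matrix <- function(design) {
  sub_cols <- setdiff(names(design), c("receptor", "ligand", "outcome"))
  lig <- levels(design$ligand)
  X <- cbind(1, as.matrix(design[sub_cols]))
  for (l in lig[-1]) X <- cbind(X, as.integer(design$ligand == l))
  colnames(X) <- c("(Intercept)", sub_cols, lig[-1])
  X
}

# Hill fit by coarse grid search plus Nelder-Mead refinement; independent
# of the package's Levenberg-Marquardt path.
hill_grid_oracle <- function(conc, resp) {
  x <- log10(conc)
  rss_fun <- function(p) {
    mu <- p[2] / (1 + 10^((-p[1] - x) * p[3]))
    sum((resp - mu)^2)
  }
  grid <- expand.grid(
    pec50 = seq(-max(x) - 1, -min(x) + 1, by = 0.1),
    imax = seq(0.05, 1.6, by = 0.05),
    nh = seq(0.4, 3, by = 0.2)
  )
  rss <- apply(grid, 1, rss_fun)
  start <- as.numeric(grid[which.min(rss), ])
  opt <- stats::optim(start, rss_fun, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt <- stats::optim(opt$par, rss_fun, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  stats::setNames(opt$par, c("pec50", "imax", "nh"))
}

# Exhaustive single-predictor split search for binary predictors: the
# CHAID choice must coincide (no merging is possible, Bonferroni
# multiplier 1).
oracle_best_binary_split <- function(data, outcome, predictors, alpha) {
  ps <- vapply(predictors, function(p) {
    g <- as.character(data[[p]])
    if (length(unique(g)) < 2) return(NA_real_)
    fit <- stats::oneway.test(data[[outcome]] ~ g, var.equal = TRUE)
    unname(fit$p.value)
  }, numeric(1))
  if (all(is.na(ps)) || min(ps, na.rm = TRUE) > alpha) return(NULL)
  list(predictor = predictors[which.min(ps)], p = min(ps, na.rm = TRUE))
}

# Random 48-row panel-shaped dataset over 4 binary predictors.
random_binary_panel <- function(seed, n = 48, k = 4) {
  set.seed(seed)
  d <- as.data.frame(matrix(sample(c("without", "with"), n * k, TRUE),
                            ncol = k))
  names(d) <- paste0("P", seq_len(k))
  d$outcome <- stats::rnorm(n) +
    stats::rnorm(1, 0, 0.8) * (d$P1 == "with") +
    stats::rnorm(1, 0, 0.8) * (d$P2 == "with")
  d
}
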