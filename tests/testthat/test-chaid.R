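panel <- dmel_nachr_panel()
cd <- chaid_data(panel)
subunit_preds <- c("Da1", "Da2", "Da3", "Db2")

test_that("category merging: binary unchanged, identical groups collapse", {
  g <- chaid_merge_categories(rnorm(10), rep(c("x", "y"), each = 5))
  expect_length(g, 2)
  set.seed(3)
  v <- rnorm(30)
  g2 <- chaid_merge_categories(v, rep(c("a", "b", "c"), 10))
  expect_length(g2, 1)  # identical distributions merge completely
})

test_that("the 4-level compound factor separates ACh from neonicotinoids", {
  g <- chaid_merge_categories(cd$outcome, as.character(cd$compound))
  ach_group <- g[vapply(g, function(x) "ACh" %in% x, logical(1))][[1]]
  expect_equal(ach_group, "ACh")
})

test_that("the root of the subunit-only tree splits on Da2", {
  s <- chaid_best_split(cd, "outcome", subunit_preds)
  expect_equal(s$predictor, "Da2")
  expect_lt(s$p_adj, 0.05)
})

test_that("a perfectly separating binary predictor wins with p ~ 0", {
  d <- data.frame(P1 = rep(c("with", "without"), each = 10),
                  P2 = rep(c("with", "without"), 10))
  d$outcome <- ifelse(d$P1 == "with", 1, 2) + rnorm(20, 0, 1e-8)
  s <- chaid_best_split(d, "outcome", c("P2", "P1"))
  expect_equal(s$predictor, "P1")
  expect_lt(s$p_adj, 1e-12)
})

test_that("the depth-4 subunit tree reproduces the published leaf", {
  tree <- fit_chaid(cd, "outcome", subunit_preds,
                    control = chaid_control(alpha_split = 1))
  expect_equal(tree$root$split_var, "Da2")
  leaves <- chaid_leaves(tree)
  target <- leaves[vapply(leaves$predicate, function(p) {
    identical(p[["Da1"]], "without") && identical(p[["Da2"]], "without") &&
      identical(p[["Da3"]], "with")
  }, logical(1)), ]
  expect_equal(nrow(target), 1)
  expect_equal(target$n, 8)
  expect_equal(target$mean, 7.50625, tolerance = 1e-10)
  expect_true(all(tidy(tree)$depth <= 4))
})

test_that("direct node queries return printed panel statistics", {
  leaf <- node_stats(cd, list(Da1 = "without", Da2 = "without", Da3 = "with"))
  expect_equal(leaf$n, 8)
  expect_equal(leaf$mean, 7.50625, tolerance = 1e-10)
  expect_equal(node_stats(cd, list(Da2 = "with"))$n, 24)
  # a predicate matching a single row returns that row's value (Da1/Db1, ACh)
  one <- node_stats(cd, list(Da1 = "with", Da2 = "without", Da3 = "without",
                             Db2 = "without", compound = "ACh"))
  expect_equal(one$n, 1)
  expect_equal(one$mean, 5.24)
  expect_error(node_stats(cd, list(Da1 = "nope")), "matches no rows")
  expect_error(node_stats(cd, list(Dx9 = "with")), "Dx9")
})

test_that("max_depth 1 returns the root only, at the grand mean", {
  tree <- fit_chaid(cd, "outcome", subunit_preds,
                    control = chaid_control(max_depth = 1))
  expect_length(tree$root$children, 0)
  expect_equal(tree$root$mean, 6.775417, tolerance = 1e-6)
  expect_equal(tree$root$n, 48)
})

test_that("a constant outcome yields no split", {
  d <- cd
  d$outcome <- 5
  tree <- fit_chaid(d, "outcome", subunit_preds)
  expect_length(tree$root$children, 0)
})

test_that("node counts and means are conserved down the tree", {
  tree <- fit_chaid(cd, "outcome", subunit_preds,
                    control = chaid_control(alpha_split = 1))
  td <- tidy(tree)
  for (i in which(!td$is_leaf)) {
    kids <- td[!is.na(td$parent_id) & td$parent_id == td$node_id[i], ]
    expect_equal(sum(kids$n), td$n[i])
    expect_equal(sum(kids$n * kids$mean) / td$n[i], td$mean[i],
                 tolerance = 1e-12)
  }
  leaves <- td[td$is_leaf, ]
  expect_equal(sum(leaves$n * leaves$mean), sum(cd$outcome),
               tolerance = 1e-10)
})

test_that("the split choice matches an exhaustive binary-split oracle", {
  for (seed in 1:40) {
    d <- random_binary_panel(seed)
    s <- chaid_best_split(d, "outcome", paste0("P", 1:4),
                          control = chaid_control())
    o <- oracle_best_binary_split(d, "outcome", paste0("P", 1:4), 0.05)
    if (is.null(o)) {
      expect_null(s)
    } else {
      expect_equal(s$predictor, o$predictor)
      expect_equal(s$p_adj, o$p, tolerance = 1e-9)
    }
  }
})

test_that("tightening alpha_split never grows the tree", {
  sizes <- vapply(c(1, 0.2, 0.05, 0.01, 0.001), function(a) {
    tree <- fit_chaid(cd, "outcome", subunit_preds,
                      control = chaid_control(alpha_split = a))
    nrow(tidy(tree))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("missing predictors are reported by name", {
  expect_error(fit_chaid(cd, "outcome", c("Da1", "Dq7")), "Dq7")
  expect_error(fit_chaid(cd, "nope", "Da1"), "nope")
})
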