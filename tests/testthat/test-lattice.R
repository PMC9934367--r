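panel <- dmel_nachr_panel()

test_that("the full 4-subunit presence cube has 32 Hasse edges", {
  combos <- expand.grid(Da1 = 0:1, Da2 = 0:1, Da3 = 0:1, Db2 = 0:1)
  sets <- apply(combos, 1, function(r)
    subunit_key(c(names(r)[r == 1], "Db1")))
  edges <- hasse_edges(sets)
  expect_equal(nrow(edges), 32)  # n * 2^(n-1) for an n-cube
})

test_that("a single covering pair yields one labeled edge", {
  edges <- hasse_edges(c("Da1/Db1", "Da1/Da2/Db1"))
  expect_equal(nrow(edges), 1)
  expect_equal(edges$added_subunit, "Da2")
  expect_equal(edges$smaller, "Da1/Db1")
})

test_that("every core-panel edge adds exactly one subunit", {
  edges <- hasse_edges(unique(panel$receptor[panel$core_panel]))
  for (i in seq_len(nrow(edges))) {
    small <- parse_subunits(edges$smaller[i])
    large <- parse_subunits(edges$larger[i])
    expect_length(setdiff(large, small), 1)
    expect_equal(setdiff(large, small), edges$added_subunit[i])
    expect_length(large, length(small) + 1)
  }
})

test_that("edge deltas reproduce arithmetic on the printed panel", {
  deltas <- lattice_deltas(panel)
  pick <- function(s, l, lig) {
    dplyr::filter(deltas, smaller == s, larger == l, ligand == lig)$delta
  }
  expect_equal(pick("Da3/Db1", "Da2/Da3/Db1", "ACh"), -0.69)
  expect_equal(pick("Da1/Db1", "Da1/Db1/Db2", "imidacloprid"), -0.17)
})

test_that("a missing panel cell is reported by receptor and ligand", {
  holey <- panel[-which(panel$receptor == "Da3/Db1" &
                          panel$ligand == "ACh"), ]
  expect_error(lattice_deltas(holey), "Da3/Db1 x ACh")
})

test_that("deltas telescope along inclusion chains and are antisymmetric", {
  deltas <- lattice_deltas(panel)
  lookup <- function(s, l, lig) {
    dplyr::filter(deltas, smaller == s, larger == l, ligand == lig)$delta
  }
  pec <- function(r, lig) {
    dplyr::filter(panel, receptor == r, ligand == lig)$pec50_mean
  }
  chains <- list(
    c("Da1/Db1", "Da1/Da2/Db1", "Da1/Da2/Da3/Db1", "Da1/Da2/Da3/Db1/Db2"),
    c("Da3/Db1", "Da3/Db1/Db2", "Da1/Da3/Db1/Db2", "Da1/Da2/Da3/Db1/Db2")
  )
  for (lig in unique(panel$ligand)) {
    for (ch in chains) {
      s <- sum(vapply(seq_len(length(ch) - 1), function(i)
        lookup(ch[i], ch[i + 1], lig), numeric(1)))
      expect_equal(s, pec(ch[length(ch)], lig) - pec(ch[1], lig),
                   tolerance = 1e-12)
    }
  }
  # antisymmetry: evaluating a reversed edge negates the delta
  skel <- hasse_edges(unique(panel$receptor[panel$core_panel]))
  rev_one <- lattice_deltas(panel, ligands = "ACh",
                            skeleton = skel[1, ])$delta
  fwd <- dplyr::filter(deltas, smaller == skel$smaller[1],
                       larger == skel$larger[1], ligand == "ACh")$delta
  expect_equal(rev_one, fwd)
  swapped <- skel[1, ]
  names(swapped)[1:2] <- c("larger", "smaller")
  rev_delta <- lattice_deltas(panel, ligands = "ACh",
                              skeleton = swapped[, c("smaller", "larger",
                                                     "added_subunit")])$delta
  expect_equal(rev_delta, -fwd)
})

test_that("on a purely additive zero-noise panel every +s edge equals the true effect of s", {
  cfg <- truth_config()
  truth <- generate_truth(cfg)
  deltas <- lattice_deltas(truth)
  for (s in names(cfg$subunit_effects)) {
    d_s <- deltas$delta[deltas$added_subunit == s]
    expect_true(length(d_s) >= 2)
    expect_true(all(abs(d_s - cfg$subunit_effects[[s]]) < 1e-12))
  }
  summ <- subunit_delta_summary(deltas)
  expect_equal(summ$ci_low, summ$ci_high, tolerance = 1e-10)
  expect_equal(summ$mean_delta,
               unname(cfg$subunit_effects[summ$subunit]), tolerance = 1e-12)
})

test_that("on the published panel Da2 is a significant negative factor", {
  summ <- subunit_delta_summary(lattice_deltas(panel))
  da2 <- summ[summ$subunit == "Da2", ]
  expect_true(da2$significant)
  expect_lt(da2$mean_delta, 0)
  expect_equal(da2$n_edges, 24)  # 6 covering pairs x 4 ligands
  # Db1 never appears as an added subunit on the core panel
  expect_false("Db1" %in% summ$subunit)
})

test_that("subunits with a single edge get a warning and no CI", {
  deltas <- lattice_deltas(panel, ligands = "ACh",
                           skeleton = hasse_edges(c("Da1/Db1",
                                                    "Da1/Da2/Db1")))
  expect_warning(summ <- subunit_delta_summary(deltas), "Da2")
  expect_false(summ$ci_defined)
  expect_true(is.na(summ$ci_low))
})

test_that("DOT export lists every node and labeled edge", {
  deltas <- lattice_deltas(panel)
  dot <- lattice_dot(deltas)
  expect_match(dot, "digraph")
  expect_match(dot, "\\+Dα2")
  for (r in unique(panel$receptor[panel$core_panel])) {
    expect_match(dot, r, fixed = TRUE)
  }
})
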