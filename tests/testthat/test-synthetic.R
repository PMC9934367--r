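test_that("truth generation is additive arithmetic on subunit effects", {
  flat <- truth_config(subunit_effects = c(Da1 = 0, Da2 = 0, Da3 = 0, Db2 = 0),
                       intercept = 6,
                       compound_offsets = c(ACh = 0, imidacloprid = 0,
                                            thiacloprid = 0, clothianidin = 0),
                       compound_imax = c(ACh = 1, imidacloprid = 1,
                                         thiacloprid = 1, clothianidin = 1))
  tt <- generate_truth(flat)
  expect_true(all(tt$pec50_mean == 6))

  tt2 <- generate_truth(truth_config())
  row <- dplyr::filter(tt2, receptor == "Da3/Db1", ligand == "ACh")
  expect_equal(row$pec50_mean, 6.96 + 0.524)
  row2 <- dplyr::filter(tt2, receptor == "Da1/Da2/Db1", ligand == "thiacloprid")
  expect_equal(row2$pec50_mean, 6.96 - 0.306 - 0.754 + 2.229)
})

test_that("misconfigured truth is rejected", {
  expect_error(truth_config(receptors = c("Da1/Da2")), "Db1")
  expect_error(truth_config(compound_offsets = c(ACh = 0.5)), "offset 0")
  cfg <- truth_config(receptors = c("Da1/Da4/Db1"))
  expect_error(generate_truth(cfg), "Da4")
})

test_that("zero-noise panel refits to the configured coefficients exactly", {
  cfg <- truth_config()
  truth <- generate_truth(cfg)
  fit <- fit_factor_model(truth, "pec50")
  expect_equal(unname(subunit_effects(fit)[names(cfg$subunit_effects)]),
               unname(cfg$subunit_effects), tolerance = 1e-12)
  expect_equal(unname(ligand_effects(fit)[c("imidacloprid", "thiacloprid",
                                            "clothianidin")]),
               unname(cfg$compound_offsets[c("imidacloprid", "thiacloprid",
                                             "clothianidin")]),
               tolerance = 1e-12)
})

test_that("simulation is exact at sigma 0 and byte-identical under a seed", {
  truth <- generate_truth(truth_config(receptors = c("Da1/Db1", "Da3/Db1")))
  rec0 <- simulate_curves(truth, noise_config(response_sigma = 0, seed = 5))
  mu <- hill_response(rec0$concentration_molar,
                      truth$pec50_mean[match(paste(rec0$receptor, rec0$ligand),
                                             paste(truth$receptor, truth$ligand))],
                      truth$imax_mean[match(paste(rec0$receptor, rec0$ligand),
                                            paste(truth$receptor, truth$ligand))],
                      truth$nh_true[match(paste(rec0$receptor, rec0$ligand),
                                          paste(truth$receptor, truth$ligand))])
  expect_equal(rec0$response, mu, tolerance = 1e-15)

  a <- simulate_curves(truth, noise_config(seed = 123))
  b <- simulate_curves(truth, noise_config(seed = 123))
  expect_identical(a, b)
  c <- simulate_curves(truth, noise_config(seed = 124))
  expect_false(identical(a$response, c$response))
})

test_that("zero-noise end-to-end pipeline is exactly identifiable", {
  cfg <- truth_config()
  truth <- generate_truth(cfg)
  rec <- simulate_curves(truth, noise_config(response_sigma = 0, seed = 1))
  fits <- fit_hill_curves(rec)
  key <- paste(truth$receptor, truth$ligand)
  idx <- match(paste(fits$receptor, fits$ligand), key)
  expect_lt(max(abs(fits$pec50 - truth$pec50_mean[idx])), 1e-6)
  expect_lt(max(abs(fits$imax - truth$imax_mean[idx])), 1e-6)
  panel <- fits_to_potency_table(fits)
  fit <- fit_factor_model(panel, "pec50")
  expect_equal(unname(subunit_effects(fit)[names(cfg$subunit_effects)]),
               unname(cfg$subunit_effects), tolerance = 1e-6)
  # CHAID node means and lattice deltas also hit the configured truth
  cd <- chaid_data(panel)
  leaf <- node_stats(cd, list(Da1 = "without", Da2 = "without", Da3 = "with"))
  truth_cd <- chaid_data(truth)
  leaf_truth <- node_stats(truth_cd,
                           list(Da1 = "without", Da2 = "without", Da3 = "with"))
  expect_equal(leaf$mean, leaf_truth$mean, tolerance = 1e-6)
  deltas <- lattice_deltas(panel)
  expect_true(all(abs(deltas$delta[deltas$added_subunit == "Da3"] -
                        cfg$subunit_effects[["Da3"]]) < 1e-6))
})

test_that("recovery experiment: zero noise gives zero bias and RMSE", {
  rep0 <- recovery_experiment(truth_config(),
                              noise_config(response_sigma = 0), n_reps = 1)
  expect_lt(max(abs(rep0$summary$bias)), 1e-6)
  expect_lt(max(rep0$summary$rmse), 1e-6)
  expect_lt(rep0$pec50_bias$max_abs_bias, 1e-6)
})

test_that("doubling the noise does not shrink any subunit-effect RMSE", {
  # adequate-SNR truth: compound efficacies >= 0.5 so every curve is
  # identifiable; 6-receptor subpanel keeps the design estimable
  cfg <- truth_config(
    compound_imax = c(ACh = 1, imidacloprid = 0.8, thiacloprid = 0.6,
                      clothianidin = 0.9),
    receptors = c("Da1/Db1", "Da3/Db1", "Da1/Da3/Db1", "Da1/Da2/Db1",
                  "Da3/Db1/Db2", "Da1/Da2/Da3/Db1/Db2"))
  r_lo <- recovery_experiment(cfg, noise_config(response_sigma = 0.02,
                                                seed = 100), n_reps = 25)
  r_hi <- recovery_experiment(cfg, noise_config(response_sigma = 0.08,
                                                seed = 100), n_reps = 25)
  expect_true(all(r_hi$summary$rmse >= r_lo$summary$rmse))
})

test_that("subunit-effect CIs approximately cover the configured truth", {
  cfg <- truth_config(
    compound_imax = c(ACh = 1, imidacloprid = 0.8, thiacloprid = 0.6,
                      clothianidin = 0.9))
  rep <- recovery_experiment(cfg, noise_config(seed = 2000), n_reps = 60)
  expect_true(all(rep$summary$coverage >= 0.85))
  expect_true(all(abs(rep$summary$bias) < 0.05))
})
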