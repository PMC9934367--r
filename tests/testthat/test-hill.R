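test_that("noiseless curves are recovered exactly (exact model class)", {
  conc <- 10^seq(-8, -4.5, by = 0.5)
  cases <- list(c(6, 1, 1), c(7.5, 0.5, 1.8), c(5.2, 0.25, 0.9))
  for (tr in cases) {
    fit <- fit_hill(conc, hill_response(conc, tr[1], tr[2], tr[3]))
    expect_true(fit$converged)
    expect_lt(abs(fit$pec50 - tr[1]), 1e-6)
    expect_lt(abs(fit$imax - tr[2]), 1e-6)
    expect_lt(abs(fit$nh - tr[3]), 1e-6)
  }
})

test_that("fitted curve passes through half-maximum at the EC50", {
  conc <- 10^seq(-9, -5, by = 0.5)
  set.seed(11)
  y <- pmax(0, hill_response(conc, 7, 0.8, 1.4) + rnorm(length(conc), 0, 0.02))
  fit <- fit_hill(conc, y)
  expect_equal(predict(fit, 10^(-fit$pec50)), fit$imax / 2, tolerance = 1e-12)
  # monotone increasing in concentration when nH > 0
  grid <- 10^seq(-10, -4, length.out = 100)
  expect_true(all(diff(predict(fit, grid)) > 0))
})

test_that("rescaling responses rescales Imax and leaves pEC50, nH fixed", {
  conc <- 10^seq(-8, -4.5, by = 0.5)
  y <- hill_response(conc, 6.4, 0.9, 1.3)
  f1 <- fit_hill(conc, y)
  f2 <- fit_hill(conc, y * 1.7)
  expect_lt(abs(f2$imax - 1.7 * f1$imax), 1e-6)
  expect_lt(abs(f2$pec50 - f1$pec50), 1e-6)
  expect_lt(abs(f2$nh - f1$nh), 1e-6)
})

test_that("LM multistart agrees with a grid-search + refinement oracle", {
  conc <- 10^seq(-8.5, -5, by = 0.5)
  truths <- expand.grid(pec50 = c(5.8, 6.6, 7.4), imax = c(0.4, 1),
                        nh = c(0.8, 2))
  for (i in seq_len(nrow(truths))) {
    tr <- as.numeric(truths[i, ])
    y <- hill_response(conc, tr[1], tr[2], tr[3])
    fit <- fit_hill(conc, y)
    oracle <- hill_grid_oracle(conc, y)
    expect_lt(abs(fit$pec50 - oracle[["pec50"]]), 1e-4)
    expect_lt(abs(fit$imax - oracle[["imax"]]), 1e-4)
    expect_lt(abs(fit$nh - oracle[["nh"]]), 1e-4)
  }
})

test_that("noisy replicate curves recover the true pEC50 on average", {
  # 5 oocytes, sigma = 0.03, truth (6.5, 0.8, 1.5); mean fitted pEC50 over
  # 200 seeded replicates stays within 0.1 of truth
  conc <- 10^seq(-8.25, -4.75, by = 0.5)
  mu <- hill_response(rep(conc, 5), 6.5, 0.8, 1.5)
  ests <- vapply(1:200, function(s) {
    set.seed(s)
    y <- pmax(0, mu + rnorm(length(mu), 0, 0.03))
    fit_hill(rep(conc, 5), y)$pec50
  }, numeric(1))
  expect_lt(abs(mean(ests) - 6.5), 0.1)
})

test_that("degenerate inputs are rejected; non-plateau curves are flagged", {
  expect_error(fit_hill(c(1e-6, 1e-5, 1e-4), c(0.1, 0.5, 0.9)),
               "4 distinct")
  # top concentration far below the fitted plateau
  conc <- 10^seq(-9, -7, by = 0.5)
  y <- hill_response(conc, 6, 1, 1)
  fit <- fit_hill(conc, y)
  expect_true(fit$extrapolated_plateau)
})

test_that("normalization divides by the per-oocyte ACh reference", {
  rec <- tibble::tibble(
    oocyte_id = c("a", "a", "b"), receptor = "Da1/Db1", ligand = "ACh",
    concentration_molar = c(1e-6, 1e-5, 1e-6),
    response = c(0.5, 1.0, 2.0), response_kind = "raw_uA"
  )
  ref <- tibble::tibble(oocyte_id = c("a", "b"), reference_current = c(1, 2))
  out <- normalize_responses(rec, ref)
  expect_equal(out$response, c(0.5, 1.0, 1.0))
  expect_true(all(out$response_kind == "normalized"))
  # a missing reference names the offending oocyte
  expect_error(normalize_responses(rec, ref[1, ]), "b")
  ref_bad <- ref; ref_bad$reference_current[1] <- 0
  expect_error(normalize_responses(rec, ref_bad), "a")
})

test_that("potency arithmetic matches the published conversions", {
  expect_equal(ec50_nM(6.99), 102)
  expect_equal(ec50_nM(8.28), 5.25)
  expect_equal(ec50_nM(9.0), 1)
  expect_equal(pec50_to_ec50(6), 1e-6)
  expect_equal(ec50_to_pec50(1e-6), 6)
  expect_equal(fold_change(8.32, 7.16), 10^1.16)
  expect_equal(fold_change(8.32, 7.16), 14.45, tolerance = 1e-3)
  expect_equal(fold_change(6.14, 5.24), 7.94, tolerance = 1e-3)
  expect_equal(fold_change(5, 5), 1)
})

test_that("grouped curve fitting returns one converged fit per curve", {
  truth <- generate_truth(truth_config(receptors = c("Da1/Db1", "Da3/Db1")))
  rec <- simulate_curves(truth, noise_config(response_sigma = 0, seed = 7))
  fits <- fit_hill_curves(rec)
  expect_equal(nrow(fits), 8)
  expect_true(all(fits$converged))
  key <- paste(truth$receptor, truth$ligand)
  err <- fits$pec50 - truth$pec50_mean[match(paste(fits$receptor, fits$ligand), key)]
  expect_lt(max(abs(err)), 1e-6)
  panel <- fits_to_potency_table(fits)
  expect_silent(validate_potency_table(panel))
})
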