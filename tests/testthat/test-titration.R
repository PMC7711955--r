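test_that("predict_intensity respects its physical limits", {
  expect_equal(predict_intensity(0, kd = 2, i_apo = 100, i_holo = 30, protein_total = 0.25), 100)
  # saturation limit
  expect_equal(predict_intensity(1e7, kd = 2, i_apo = 100, i_holo = 30, protein_total = 0.25),
               30, tolerance = 1e-4)
  # stoichiometric (kd = 0) limit at half-equivalence
  expect_equal(predict_intensity(0.125, kd = 0, i_apo = 100, i_holo = 30, protein_total = 0.25),
               65)
  # bounded and monotone
  v <- predict_intensity(seq(0, 10, by = 0.1), kd = 1, i_apo = 100, i_holo = 30,
                         protein_total = 0.25)
  expect_true(all(v <= 100 & v >= 30))
  expect_true(all(diff(v) <= 0))
  expect_error(predict_intensity(-1, 1, 100, 30, 0.25), "non-negative")
})

test_that("predicted bound fraction equals the mass-balance bisection root", {
  for (case in list(c(1, 0.25, 1), c(0.1, 0.25, 0.5), c(5, 2, 3), c(0.01, 0.25, 0.1))) {
    kd <- case[1]; P <- case[2]; L <- case[3]
    x <- bound_by_bisection(P, L, kd)
    pred <- predict_intensity(L, kd, 0, 1, P)  # = bound fraction of protein
    expect_equal(pred, x / P, tolerance = 1e-9)
  }
})

test_that("tight-binding model reduces to the hyperbola when protein is dilute", {
  kd <- 1
  P <- 0.01 * kd
  L <- c(0.1, 0.3, 1, 3, 10)
  full <- predict_intensity(L, kd, 0, 1, P)
  hyperbola <- L / (kd + L)
  expect_true(all(abs(full - hyperbola) / hyperbola < 0.01))
})

test_that("fit_titration recovers noiseless generating parameters", {
  truth <- variant_truth("x", kd_fad = 1)
  curve <- simulate_titration(truth, noise = noise_spec(0))
  fit <- fit_titration(curve, 0.25)
  expect_equal(fit$kd, 1, tolerance = 1e-6)
  expect_equal(fit$i_apo, 100, tolerance = 1e-6)
  expect_equal(fit$i_holo, 30, tolerance = 1e-6)
})

test_that("fit_titration rejects flat curves and too-few points", {
  flat <- tibble::tibble(ligand_total_uM = 0:9, intensity_au = rep(50, 10))
  expect_error(fit_titration(flat, 0.25), "no binding signal")
  short <- tibble::tibble(ligand_total_uM = 0:3, intensity_au = c(10, 8, 6, 5))
  expect_error(fit_titration(short, 0.25), "at least 5")
})

test_that("fitted Kd is invariant to affine intensity rescaling", {
  curve <- simulate_titration(variant_truth("x", kd_fad = 0.4), noise = noise_spec(0.02, 11))
  f1 <- fit_titration(curve, 0.25)
  curve2 <- dplyr::mutate(curve, intensity_au = 3.7 * intensity_au + 250)
  f2 <- fit_titration(curve2, 0.25)
  expect_equal(f2$kd, f1$kd, tolerance = 1e-6)
  expect_equal(f2$i_apo, 3.7 * f1$i_apo + 250, tolerance = 1e-5)
  expect_equal(f2$i_holo, 3.7 * f1$i_holo + 250, tolerance = 1e-5)
})

test_that("optimizer finds the same optimum as the exhaustive grid oracle", {
  curve <- simulate_titration(variant_truth("x", kd_fad = 0.5), noise = noise_spec(0.02, 42))
  fit <- fit_titration(curve, 0.25)
  oracle <- titration_grid_oracle(curve, 0.25)
  expect_equal(fit$kd, oracle$kd, tolerance = 0.01)
  expect_lte(fit$residual_norm, oracle$rss * (1 + 1e-6))
})

test_that("binding free energies follow RT log identities with propagated errors", {
  expect_equal(binding_free_energy(1e6)$dg, 0)  # 1 M reference state
  expect_equal(binding_free_energy(1)$dg, RT25 * log(1e-6), tolerance = 1e-12)
  bfe <- binding_free_energy(2, kd_se_uM = 0.2)
  expect_equal(bfe$dg_se, RT25 * 0.1, tolerance = 1e-12)
  expect_error(binding_free_energy(0), "positive")
})

test_that("delta_delta_g matches closed forms and is antisymmetric", {
  expect_equal(delta_delta_g(12, 1)$ddg, RT25 * log(12))
  expect_equal(delta_delta_g(5, 5)$ddg, 0)
  set.seed(1)
  for (i in 1:20) {
    a <- stats::runif(1, 0.01, 50); b <- stats::runif(1, 0.01, 50)
    expect_equal(delta_delta_g(a, b)$ddg, -delta_delta_g(b, a)$ddg, tolerance = 1e-12)
  }
  expect_error(delta_delta_g(-1, 1), "positive")
})

test_that("flavin occupancy is the normalized 450 nm absorbance over the flavin coefficient", {
  expect_equal(fad_content(11300), 1)
  expect_equal(fad_content(5650), 0.5)
  expect_equal(fad_content(0), 0)
  # spectra not yet normalized are rescaled by the protein absorbance
  expect_equal(fad_content(5650 / 2, a280_normalized = 47900 / 2), 0.5)
  expect_error(fad_content(100, a280_normalized = 0), "positive")
})
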