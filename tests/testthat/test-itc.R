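test_that("blank and athermal titrations give pure dilution heats", {
  v <- c(0.5, rep(1.75, 20))
  blank <- predict_injection_heats(1, 0.05, -8, -0.1, 0, 120, 200, v)
  expect_equal(blank, -0.1 * v)
  nodh <- predict_injection_heats(1, 0.05, 0, -0.1, 10, 120, 200, v)
  expect_equal(nodh, -0.1 * v)
})

test_that("heat conservation: total binding heat equals the enthalpic cell content", {
  d <- itc_design()
  v <- d$injection_volumes_uL
  heats <- predict_injection_heats(1, 0.05, -8, d$q_dil, d$cell_protein_uM,
                                   d$syringe_ligand_uM, d$cell_volume_uL, v)
  total_binding <- sum(heats - d$q_dil * v)
  expected <- -8 * 1 * d$cell_protein_uM * d$cell_volume_uL * 1e-3
  expect_equal(total_binding, expected, tolerance = 5e-3)
  # per-injection heats match the brute-force bisection mass balance
  ligand <- d$syringe_ligand_uM * cumsum(v) / d$cell_volume_uL
  bound <- vapply(ligand, function(L) bound_by_bisection(d$cell_protein_uM, L, 0.05),
                  numeric(1))
  brute <- -8 * d$cell_volume_uL * diff(c(0, bound)) * 1e-3 + d$q_dil * v
  expect_equal(heats, brute, tolerance = 1e-9)
})

test_that("single-site fit round-trips noiseless synthetic runs", {
  truth <- variant_truth("x", kd_dic = 0.05, dh_bind = -8)
  run <- simulate_itc(truth, noise = noise_spec(0))
  fit <- fit_itc(run)
  expect_equal(fit$n_sites, 1, tolerance = 1e-4)
  expect_equal(fit$kd, 0.05, tolerance = 1e-4)
  expect_equal(fit$dh, -8, tolerance = 1e-4)
  expect_equal(fit$q_dil, itc_design()$q_dil, tolerance = 1e-4)
})

test_that("blank enthalpograms are rejected as signal-free", {
  d <- itc_design()
  d$cell_protein_uM <- 0
  run <- simulate_itc(variant_truth("x"), d, noise_spec(0))
  expect_error(fit_itc(run, cell_protein_uM = 10), "no binding signal")
})

test_that("every fit is thermodynamically consistent and flags extreme c-values", {
  run <- simulate_itc(variant_truth("x", kd_dic = 0.2, dh_bind = -9),
                      noise = noise_spec(0.02, 17))
  fit <- fit_itc(run)
  # dG = dH - T dS to numerical precision
  expect_lt(abs(fit$dg - (fit$dh - (273.15 + 25) * fit$ds / 1000)), 1e-6)
  expect_equal(fit$ka, 1 / (fit$kd * 1e-6))
  tight <- simulate_itc(variant_truth("x", kd_dic = 0.002, dh_bind = -8),
                        noise = noise_spec(0))
  expect_warning(fit_itc(tight), "technical limit")
})

test_that("noisy-fit optimum matches the grid + polish oracle", {
  run <- simulate_itc(variant_truth("x", kd_dic = 0.1, dh_bind = -8),
                      noise = noise_spec(0.02, 31))
  fit <- fit_itc(run)
  oracle <- itc_grid_oracle(run)
  expect_equal(fit$kd, oracle$kd, tolerance = 0.02)
  expect_equal(fit$dh, oracle$dh, tolerance = 0.01)
  expect_lte(fit$residual_norm, oracle$rss * (1 + 1e-6))
})

test_that("heat-capacity change is the OLS slope of enthalpy vs temperature", {
  temps <- c(10, 15, 17.5, 20, 25)
  expect_equal(fit_delta_cp(-8 - 0.2 * (temps - 25), temps)$dcp, -0.2, tolerance = 1e-12)
  expect_equal(fit_delta_cp(rep(-7, 4), c(10, 15, 20, 25))$dcp, 0)
  expect_error(fit_delta_cp(c(-8, -7), c(10, 25)), "at least 3")
  set.seed(4)
  y <- -8 - 0.2 * (temps - 25) + stats::rnorm(5, 0, 0.1)
  expect_equal(fit_delta_cp(y, temps)$dcp,
               unname(normal_equations_line(temps, y)["slope"]), tolerance = 1e-10)
})

test_that("enthalpies fitted across temperatures recover the generating dCp", {
  truth <- variant_truth("x", kd_dic = 0.05, dh_bind = -8, dcp_bind = -0.20)
  temps <- c(10, 15, 17.5, 20, 25)
  dh <- vapply(temps, function(temp) {
    d <- itc_design(); d$temperature_C <- temp
    fit_itc(simulate_itc(truth, d, noise_spec(0)))$dh
  }, numeric(1))
  expect_equal(fit_delta_cp(dh, temps)$dcp, -0.20, tolerance = 1e-4)
})

test_that("conformational-change estimators follow the per-residue coefficients", {
  rigid <- conformational_change(-5.8, -0.14)
  expect_equal(rigid$n_conf_avg, 0)
  ten_h <- conformational_change(-5.8 + 2.15, -0.14)
  expect_equal(ten_h$n_conf_from_h, 10)
  ten_cp <- conformational_change(-5.8, -0.14 - 0.138)
  expect_equal(ten_cp$n_conf_from_cp, 10)
  expect_equal(ten_cp$n_conf_from_cp_signed, -10)
  # linearity: doubling both conformational contributions doubles the estimators
  a <- conformational_change(-5.8 - 1, -0.14 - 0.05)
  b <- conformational_change(-5.8 - 2, -0.14 - 0.10)
  expect_equal(b$n_conf_from_h, 2 * a$n_conf_from_h)
  expect_equal(b$n_conf_from_cp, 2 * a$n_conf_from_cp)
  expect_equal(a$n_conf_avg, mean(c(a$n_conf_from_h, a$n_conf_from_cp)))
})

test_that("cavity destabilization bounds use the 24-36 cal per cubic angstrom range", {
  expect_equal(unname(cavity_destabilization(17, 71)$bounds), c(1.296, 1.944))
  expect_equal(unname(cavity_destabilization(31, 109)$bounds), c(1.872, 2.808))
  expect_equal(unname(cavity_destabilization(50, 50)$bounds), c(0, 0))
  expect_error(cavity_destabilization(-1, 10), "non-negative")
})
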