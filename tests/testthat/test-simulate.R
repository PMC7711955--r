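test_that("identical truth, design and seed give bit-identical datasets", {
  tr <- variant_truth("x", kd_fad = 0.4, kprot = 0.07, tm = 51, kd_dic = 0.05)
  expect_identical(simulate_titration(tr, noise = noise_spec(0.03, 7)),
                   simulate_titration(tr, noise = noise_spec(0.03, 7)))
  expect_identical(simulate_proteolysis(tr, noise = noise_spec(0.03, 7)),
                   simulate_proteolysis(tr, noise = noise_spec(0.03, 7)))
  expect_identical(simulate_thermal(tr, noise = noise_spec(0.01, 7)),
                   simulate_thermal(tr, noise = noise_spec(0.01, 7)))
  expect_identical(simulate_itc(tr, noise = noise_spec(0.02, 7)),
                   simulate_itc(tr, noise = noise_spec(0.02, 7)))
})

test_that("seeded simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- stats::rnorm(1)
  set.seed(123)
  invisible(simulate_titration(variant_truth("x"), noise = noise_spec(0.02, 99)))
  b <- stats::rnorm(1)
  expect_identical(a, b)
})

test_that("noise is additive and zero-mean: replicate averages converge to the forward model", {
  tr <- variant_truth("x", kd_fad = 0.5)
  clean <- simulate_titration(tr, noise = noise_spec(0))$intensity_au
  sims <- vapply(1:1000, function(s) {
    simulate_titration(tr, noise = noise_spec(0.02, s))$intensity_au
  }, numeric(length(clean)))
  avg <- rowMeans(sims)
  bound <- 3 * 0.02 * 70 / sqrt(1000)  # 3 sd of the mean, amplitude-scaled noise
  expect_lt(max(abs(avg - clean)), bound * 1.5)  # joint bound over 16 points
  expect_lt(mean(abs(avg - clean)), bound)
})

test_that("simulators validate their designs", {
  tr <- variant_truth("x")
  expect_error(simulate_titration(tr, list(protein_total_uM = 0.25, ligand_uM = numeric(0),
                                           i_apo = 100, i_holo = 30)), "empty")
  expect_error(simulate_titration(tr, list(protein_total_uM = 0.25, ligand_uM = c(-1, 0:8),
                                           i_apo = 100, i_holo = 30)), "non-negative")
  expect_error(simulate_proteolysis(tr, list(protease_uM = c(0.2, 0.6), time_min = c(0, 5))),
               "at least 3")
  expect_error(simulate_proteolysis(tr, list(protease_uM = c(0.2, 0.6, 1), time_min = c(1, 5))),
               "include 0")
  expect_error(variant_truth("x", tm = 75), "scan window")
  d <- itc_design(); d$cell_volume_uL <- 0
  expect_error(simulate_itc(tr, d), "positive")
})

test_that("no-ligand titration returns the apo intensity", {
  d <- titration_design(); d$ligand_uM <- 0
  s <- simulate_titration(variant_truth("x", kd_fad = 3), d, noise_spec(0))
  expect_equal(s$intensity_au, d$i_apo)
})

test_that("fixture panel encodes the reported fold-changes", {
  panel <- build_fixture_panel()
  expect_equal(nrow(panel), 7)
  expect_equal(panel$variant_id[1], "WT")
  wt <- panel[panel$variant_id == "WT", ]
  expect_equal(panel$kd_fad[panel$variant_id == "T16M"] / wt$kd_fad, 12)
  expect_equal(panel$kd_fad[panel$variant_id == "A29T"] / wt$kd_fad, 6)
  expect_equal(panel$tm[panel$variant_id == "V9I"] - wt$tm, -1.5)
  expect_true(panel$tm[panel$variant_id == "T16M"] - wt$tm <= -4 &&
              panel$tm[panel$variant_id == "T16M"] - wt$tm >= -5)
  # invariants: positive constants, yields, window
  expect_true(all(panel$kd_fad > 0 & panel$kd_dic > 0 & panel$kprot >= 0))
  expect_true(all(panel$tm > 20 & panel$tm < 70))
  expect_true(all(panel$expression_pct >= 0))
})

test_that("noiseless fixture scans reproduce the reported Tm shifts", {
  panel <- build_fixture_panel()
  tm_of <- function(id) {
    extract_tm(normalize_scan(simulate_thermal(panel[panel$variant_id == id, ],
                                               noise = noise_spec(0))))$tm
  }
  d_t16m <- tm_of("T16M") - tm_of("WT")
  expect_true(d_t16m <= -4 && d_t16m >= -5)
  expect_equal(tm_of("V9I") - tm_of("WT"), -1.5, tolerance = 0.05)
})

test_that("titration fits recover the generating Kd within coverage at 2% noise", {
  # study-condition noisy recovery, small slice; the full sweep is in the
  # acceptance suite
  cov <- vapply(1:50, function(s) {
    f <- fit_titration(simulate_titration(variant_truth("x", kd_fad = 0.1),
                                          noise = noise_spec(0.02, s)), 0.25)
    abs(f$kd - 0.1) <= 3 * f$kd_se
  }, logical(1))
  expect_gte(mean(cov), 0.9)
})
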