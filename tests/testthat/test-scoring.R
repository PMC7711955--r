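test_that("plus-symbol codes decode positionally", {
  expect_equal(decode_symbol(c("+", "++", "+++")), c(1L, 2L, 3L))
  expect_equal(decode_symbol(c("N.Det.", "", NA)), rep(NA_integer_, 3))
  expect_error(decode_symbol("++++"), "unrecognized")
})

test_that("trait rubric boundaries are inclusive on the neutral side", {
  expect_equal(code_trait("expression", c(95, 50, 49.9, 20, 19.9)), c(3L, 3L, 2L, 2L, 1L))
  expect_equal(code_trait("thermal", c(-0.5, -2, -2.1, -4.5, -5, -5.1, 4)),
               c(3L, 3L, 2L, 2L, 2L, 1L, 3L))
  expect_equal(code_trait("proteolysis", c(1, 3, 3.1, 30, 30.5, 0.2)),
               c(3L, 3L, 2L, 2L, 1L, 3L))
  expect_equal(code_trait("fad_binding", c(1, 3, 6, 10, 12, 0.5)),
               c(3L, 3L, 2L, 2L, 1L, 3L))
  expect_equal(code_trait("dic_binding", 1.3), 3L)
  expect_true(is.na(code_trait("fad_binding", NA)))
  expect_error(code_trait("activity", 1), "arg")
})

test_that("experimental score averages available codes only", {
  expect_equal(experimental_score(c(3, 2, 2, 1, 3)), 2.2)
  expect_equal(experimental_score(c(1, NA, NA, NA, NA)), 1)
  expect_equal(experimental_score(rep(3, 5)), 3)
  expect_error(experimental_score(c(NA, NA)), "no trait codes")
  expect_error(experimental_score(c(3, 4)), "1, 2 or 3")
})

test_that("predictor categories map to the rubric with undetermined exclusion", {
  expect_equal(map_predictor("ponp2", "Unknown"), 2L)
  expect_equal(map_predictor("polyphen2", "Benign"), 3L)
  expect_equal(map_predictor("polyphen2", "Possibly damaging"), 2L)
  expect_equal(map_predictor("sift", "Not tolerated"), 1L)
  expect_equal(map_predictor("provean", "Deleterious"), 1L)
  expect_true(is.na(map_predictor("mutation_taster", "NotDetermined")))
  expect_error(map_predictor("sift", "NotDetermined"), "invalid category")
  expect_error(map_predictor("polyphen2", "Damaging"), "invalid category")
})

test_that("bioinformatic score averages determined predictors only", {
  expect_equal(bioinformatic_score(c(1, 1, NA, 3, 2)), 1.75)
  expect_equal(bioinformatic_score(c(2, 1, NA, 1, 1)), 1.25)
  expect_equal(bioinformatic_score(rep(3, 5)), 3)
  expect_error(bioinformatic_score(rep(NA, 5)), "undetermined")
})

test_that("stability-predictor aggregation is a plain mean and sd", {
  expect_equal(aggregate_stability_predictions(c(-1, -2)),
               list(mean = -1.5, sd = stats::sd(c(-1, -2)), n = 2L))
  agg <- aggregate_stability_predictions(c(-0.7, -0.7, -0.7))
  expect_equal(agg$mean, -0.7)
  expect_equal(agg$sd, 0)
  expect_error(aggregate_stability_predictions(-1), "at least 2")
})

test_that("scores are bounded and ES is monotone in each trait code", {
  set.seed(2)
  for (i in 1:50) {
    codes <- sample(1:3, 5, replace = TRUE)
    es <- experimental_score(codes)
    expect_true(es >= 1 && es <= 3)
    j <- sample(5, 1)
    worse <- codes
    worse[j] <- max(1, codes[j] - 1)
    expect_lte(experimental_score(worse), es)
  }
})

test_that("published panels recompute: ES exact, BS exact except the known row", {
  sp <- score_published_panels()
  expect_equal(nrow(sp), 22)
  expect_true(all(sp$es_match))
  expect_equal(sum(sp$bs_match), 21)
  bad <- sp[!sp$bs_match, ]
  expect_equal(bad$variant, "P187S")
  expect_equal(bad$bs_recomputed, 2.4)
  expect_equal(bad$bs_printed, 2)
})

test_that("variant sets are assigned from the mutated position", {
  expect_equal(variant_set(c("G3S", "T16M", "P187S", "P187E", "K240H")),
               c("Nt", "Nt", "P187", "P187", "K240"))
})

test_that("score regression satisfies the normal equations and flags degeneracy", {
  pairs <- tibble::tibble(variant = c("a", "b", "c", "d"),
                          es = c(1, 2, 2.5, 3), bs = c(1.2, 1.8, 2.6, 2.9),
                          set = "Nt")
  res <- correlate_scores(pairs, group_by_set = FALSE)
  ne <- normal_equations_line(pairs$bs, pairs$es)
  expect_equal(res$slope, unname(ne["slope"]), tolerance = 1e-10)
  expect_equal(res$intercept, unname(ne["intercept"]), tolerance = 1e-10)
  expect_equal(res$r, stats::cor(pairs$bs, pairs$es), tolerance = 1e-12)
  perfect <- tibble::tibble(variant = c("a", "b", "c"), es = 1:3, bs = 1:3, set = "Nt")
  resp <- correlate_scores(perfect, group_by_set = FALSE)
  expect_equal(resp$slope, 1)
  expect_equal(resp$r, 1)
  degen <- tibble::tibble(variant = c("a", "b", "c"), es = c(1, 2, 3), bs = rep(2, 3),
                          set = "Nt")
  expect_error(correlate_scores(degen, group_by_set = FALSE), "degenerate")
})
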