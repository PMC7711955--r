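#' Decode semiquantitative plus-symbol codes
#'
#' The published panels record trait severity as `+` (severe), `++` (mild)
#' or `+++` (neutral). Symbols are decoded positionally — the number of
#' plus signs is the code — independent of which trait or predictor they
#' annotate. Empty strings and `N.Det.` (not determined) decode to `NA`.
#'
#' @param x Character vector of symbols.
#' @return Integer vector of codes in `{1, 2, 3}` with `NA` for absent or
#'   undetermined entries.
#' @examples
#' decode_symbol(c("+", "++", "+++", "N.Det.", ""))
#' @export
decode_symbol <- function(x) {
  out <- dplyr::case_match(as.character(x),
    "+" ~ 1L, "++" ~ 2L, "+++" ~ 3L,
    c("", "N.Det.", "N.Det", "NA") ~ NA_integer_,
    .default = NA_integer_
  )
  bad <- !is.na(x) & !(as.character(x) %in% c("+", "++", "+++", "", "N.Det.", "N.Det", "NA"))
  if (any(bad)) stop("unrecognized code symbol: ", paste(unique(x[bad]), collapse = ", "),
                     call. = FALSE)
  out
}

#' Encode a quantitative trait measurement into the 1/2/3 rubric
#'
#' Deterministic mapping of a trait measurement to the semiquantitative
#' code used by the experimental score (3 = neutral, 2 = mild, 1 = severe),
#' with inclusive upper bounds on the neutral side:
#' * `expression` (% of WT soluble yield): >= 50 is 3, 20–50 is 2, < 20 is 1.
#' * `thermal` (delta Tm, °C vs WT): within 2 °C (or stabilized) is 3,
#'   2–5 °C lower is 2, more than 5 °C lower is 1.
#' * `proteolysis` (k_prot fold vs WT): <= 3-fold is 3 (0.65 kcal·mol^-1),
#'   3–30-fold is 2 (2 kcal·mol^-1), > 30-fold faster is 1.
#' * `fad_binding`, `dic_binding` (Kd fold vs WT): <= 3-fold is 3,
#'   3–10-fold higher is 2, > 10-fold higher is 1.
#'
#' Fold changes below 1 (tighter binding, slower proteolysis) and
#' stabilizing temperature shifts code 3: the rubric only penalizes the
#' deleterious direction.
#'
#' @param trait One of `"expression"`, `"thermal"`, `"proteolysis"`,
#'   `"fad_binding"`, `"dic_binding"`.
#' @param value The measurement, in the trait's units (%, °C or fold);
#'   vectorized. `NA` passes through (unmeasured trait).
#' @return Integer code(s) in `{1, 2, 3}`.
#' @examples
#' code_trait("expression", 95)
#' code_trait("thermal", -4.5)
#' code_trait("fad_binding", 12)
#' @export
code_trait <- function(trait, value) {
  trait <- match.arg(trait, c("expression", "thermal", "proteolysis",
                              "fad_binding", "dic_binding"))
  code1 <- function(v) {
    if (is.na(v)) return(NA_integer_)
    switch(trait,
      expression = if (v >= 50) 3L else if (v >= 20) 2L else 1L,
      thermal = if (v >= -2) 3L else if (v >= -5) 2L else 1L,
      proteolysis = if (v <= 3) 3L else if (v <= 30) 2L else 1L,
      fad_binding = ,
      dic_binding = if (v <= 3) 3L else if (v <= 10) 2L else 1L
    )
  }
  vapply(value, code1, integer(1))
}

#' Experimental pathogenicity score
#'
#' Arithmetic mean of the available trait codes; traits without a
#' measurement (e.g. every assay but expression for an insoluble variant)
#' are excluded. 1 corresponds to a severe variant, 3 to a neutral one.
#'
#' @param codes Numeric/integer vector of trait codes in `{1, 2, 3}`, `NA`
#'   allowed for unmeasured traits.
#' @return The experimental score (ES) in `[1, 3]`.
#' @examples
#' experimental_score(c(3, 2, 2, 1, 3))  # 2.2
#' @export
experimental_score <- function(codes) {
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0) stop("no trait codes available", call. = FALSE)
  if (any(!codes %in% 1:3)) stop("trait codes must be 1, 2 or 3", call. = FALSE)
  mean(codes)
}

#' Map a categorical predictor call to the 1/2/3 rubric
#'
#' Converts the categorical output of a pathogenicity predictor to a
#' semiquantitative code: 3 for benign/tolerated/neutral/polymorphism
#' calls, 1 for damaging/deleterious/pathogenic calls, and 2 for the
#' intermediate categories (`Possibly damaging`, `Unknown`).
#' `NotDetermined` (allowed only for the nucleotide-level predictor when
#' the substitution needs two nucleotide changes) maps to `NA` and is
#' excluded downstream.
#'
#' @param predictor One of `"polyphen2"`, `"sift"`, `"mutation_taster"`,
#'   `"provean"`, `"ponp2"`.
#' @param call The predictor's categorical output.
#' @return Integer code in `{1, 2, 3}` or `NA`.
#' @examples
#' map_predictor("ponp2", "Unknown")       # 2
#' map_predictor("polyphen2", "Benign")    # 3
#' @export
map_predictor <- function(predictor, call) {
  predictor <- match.arg(predictor, c("polyphen2", "sift", "mutation_taster",
                                      "provean", "ponp2"))
  valid <- list(
    polyphen2 = c("Benign" = 3L, "Possibly damaging" = 2L, "Probably damaging" = 1L),
    sift = c("Tolerated" = 3L, "Not tolerated" = 1L),
    mutation_taster = c("Polymorphism" = 3L, "Disease-causing" = 1L, "NotDetermined" = NA_integer_),
    provean = c("Neutral" = 3L, "Deleterious" = 1L),
    ponp2 = c("Neutral" = 3L, "Unknown" = 2L, "Pathogenic" = 1L)
  )[[predictor]]
  if (is.na(call)) return(NA_integer_)
  idx <- match(tolower(call), tolower(names(valid)))
  if (is.na(idx)) {
    stop(sprintf("invalid category '%s' for predictor %s", call, predictor), call. = FALSE)
  }
  unname(valid[idx])
}

#' Bioinformatic pathogenicity score
#'
#' Mean of the mapped predictor codes over determined predictors only.
#'
#' @param codes Integer vector of predictor codes (from [map_predictor()]
#'   or [decode_symbol()]), `NA` for undetermined predictors.
#' @return The bioinformatic score (BS) in `[1, 3]`.
#' @examples
#' bioinformatic_score(c(1, 1, NA, 3, 2))  # 1.75
#' @export
bioinformatic_score <- function(codes) {
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0) stop("all predictor calls undetermined", call. = FALSE)
  if (any(!codes %in% 1:3)) stop("predictor codes must be 1, 2 or 3", call. = FALSE)
  mean(codes)
}

#' Aggregate structure-based stability predictions
#'
#' Consensus of per-predictor stability changes for one variant, reported
#' as sample mean and standard deviation over the supplied predictors
#' (negative mean = destabilizing, matching the convention of the
#' structure-based tools).
#'
#' @param ddg Numeric vector of predicted stability changes,
#'   kcal·mol^-1 (>= 2 values).
#' @return List with `mean`, `sd` and `n`.
#' @examples
#' aggregate_stability_predictions(c(-1, -2))
#' @export
aggregate_stability_predictions <- function(ddg) {
  ddg <- ddg[!is.na(ddg)]
  if (length(ddg) < 2) stop("need at least 2 predictor values", call. = FALSE)
  list(mean = mean(ddg), sd = stats::sd(ddg), n = length(ddg))
}

#' Assign a variant to its mutation set
#'
#' Variants at position 187 form the `P187` set, those at 240 the `K240`
#' set, and the N-terminal-region variants characterized alongside them
#' form the `Nt` set.
#'
#' @param variant_id Character vector of variant labels.
#' @return Character vector with values `"Nt"`, `"P187"` or `"K240"`.
#' @export
variant_set <- function(variant_id) {
  dplyr::case_when(
    grepl("^P187", variant_id) ~ "P187",
    grepl("^K240", variant_id) ~ "K240",
    .default = "Nt"
  )
}

#' Regress experimental scores on bioinformatic scores
#'
#' Ordinary least-squares regression of ES on BS with Pearson correlation,
#' for the pooled variant set and (optionally) within each mutation set.
#'
#' @param pairs Data frame with columns `variant`, `es`, `bs` and
#'   optionally `set` (filled in by [variant_set()] when absent).
#' @param group_by_set Also fit each mutation set separately (default
#'   TRUE). Sets with fewer than 3 points are dropped with a message.
#' @return A tibble with one row per fitted line: `set` (`"all"` plus the
#'   group labels), `n`, `slope`, `slope_se`, `intercept`, `r` (Pearson),
#'   `p_value` (two-sided test of zero correlation).
#' @examples
#' panel <- score_published_panels()
#' correlate_scores(dplyr::transmute(panel, variant, es = es_recomputed,
#'                                   bs = bs_recomputed, set))
#' @export
correlate_scores <- function(pairs, group_by_set = TRUE) {
  stopifnot(is.data.frame(pairs))
  if (!all(c("es", "bs") %in% names(pairs))) stop("`pairs` needs columns es and bs", call. = FALSE)
  if (!"set" %in% names(pairs)) pairs$set <- variant_set(pairs$variant)
  fit_one <- function(df, label) {
    if (nrow(df) < 3) {
      message(sprintf("set %s has fewer than 3 pairs; skipped", label))
      return(NULL)
    }
    if (stats::sd(df$bs) < 1e-12 || stats::sd(df$es) < 1e-12) {
      stop(sprintf("degenerate (zero-variance) scores in set %s", label), call. = FALSE)
    }
    lm_fit <- stats::lm(es ~ bs, data = df)
    # perfectly collinear score pairs are valid input; the warning is benign
    est <- suppressWarnings(summary(lm_fit))$coefficients
    ct <- suppressWarnings(stats::cor.test(df$bs, df$es))
    tibble::tibble(set = label, n = nrow(df),
                   slope = unname(est["bs", "Estimate"]),
                   slope_se = unname(est["bs", "Std. Error"]),
                   intercept = unname(est["(Intercept)", "Estimate"]),
                   r = unname(ct$estimate), p_value = ct$p.value)
  }
  out <- list(fit_one(pairs, "all"))
  if (group_by_set) {
    for (s in unique(pairs$set)) out <- c(out, list(fit_one(pairs[pairs$set == s, ], s)))
  }
  dplyr::bind_rows(out)
}

#' Published semiquantitative code panels
#'
#' The packaged trait-code and predictor-code tables for the 22-variant
#' reference panel (the N-terminal set characterized in this pipeline plus
#' the P187 and K240 mutational series), as reported, including the printed
#' ES/BS columns.
#'
#' @return A tibble of plus-symbol codes with the printed score column.
#' @name published_panels
NULL

#' @rdname published_panels
#' @export
trait_code_panel <- function() {
  readr::read_csv(system.file("extdata", "nqo1_trait_codes.csv", package = "varitrait"),
                  col_types = readr::cols(.default = readr::col_character(),
                                          es_printed = readr::col_double()))
}

#' @rdname published_panels
#' @export
predictor_code_panel <- function() {
  readr::read_csv(system.file("extdata", "nqo1_predictor_codes.csv", package = "varitrait"),
                  col_types = readr::cols(.default = readr::col_character(),
                                          bs_printed = readr::col_double()))
}

#' Recompute ES and BS for the published panels
#'
#' Decodes the packaged plus-symbol panels, recomputes the experimental and
#' bioinformatic scores from the codes (excluding unmeasured traits and
#' undetermined predictors) and compares them with the printed values. One
#' known discrepancy is expected and surfaced rather than corrected: the
#' P187S predictor codes average 2.4 while the printed BS is 2.
#'
#' @return A tibble with one row per variant: `variant`, `set`,
#'   `es_recomputed`, `es_printed`, `es_match`, `bs_recomputed`,
#'   `bs_printed`, `bs_match` (logical, equality at printed precision), and
#'   convenience columns `es`/`bs` equal to the recomputed scores.
#' @examples
#' dplyr::filter(score_published_panels(), !bs_match)
#' @export
score_published_panels <- function() {
  traits <- trait_code_panel()
  preds <- predictor_code_panel()
  trait_cols <- c("expression", "thermal_stability", "proteolysis",
                  "fad_binding", "dic_binding")
  pred_cols <- c("polyphen2", "sift", "mutation_taster", "provean", "ponp2")
  es <- purrr::pmap_dbl(traits[trait_cols],
                        function(...) experimental_score(decode_symbol(c(...))))
  bs <- purrr::pmap_dbl(preds[pred_cols],
                        function(...) bioinformatic_score(decode_symbol(c(...))))
  out <- tibble::tibble(
    variant = traits$variant, set = traits$set,
    es_recomputed = es, es_printed = traits$es_printed,
    bs_recomputed = bs[match(traits$variant, preds$variant)],
    bs_printed = preds$bs_printed[match(traits$variant, preds$variant)]
  )
  out$es_match <- abs(out$es_recomputed - out$es_printed) < 0.05
  out$bs_match <- abs(out$bs_recomputed - out$bs_printed) < 0.05
  out$es <- out$es_recomputed
  out$bs <- out$bs_recomputed
  out
}
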