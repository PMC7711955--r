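#' Ground-truth parameter set for one protein variant
#'
#' Bundles the per-variant biophysical parameters from which every synthetic
#' assay dataset is generated: cofactor and inhibitor dissociation
#' constants, the second-order proteolysis rate constant, the apparent
#' melting temperature, the inhibitor-binding enthalpy and heat-capacity
#' change, and the soluble expression yield.
#'
#' @param variant_id Text label, e.g. `"T16M"`.
#' @param kd_fad FAD dissociation constant, µM (> 0).
#' @param kprot Second-order proteolysis rate constant, µM^-1·min^-1 (>= 0).
#' @param tm Apparent half-denaturation temperature, °C (must sit inside the
#'   20–70 °C scan window).
#' @param kd_dic Inhibitor dissociation constant, µM (> 0).
#' @param dh_bind Inhibitor-binding enthalpy at 25 °C, kcal·mol^-1.
#' @param dcp_bind Inhibitor-binding heat-capacity change,
#'   kcal·mol^-1·K^-1.
#' @param expression_pct Soluble yield as % of wild type (>= 0).
#' @return A one-row tibble of class `variant_truth`.
#' @examples
#' variant_truth("T16M", kd_fad = 3, tm = 49.5)
#' @export
variant_truth <- function(variant_id, kd_fad = 0.25, kprot = 0.05, tm = 54,
                          kd_dic = 0.03, dh_bind = -9, dcp_bind = -0.33,
                          expression_pct = 100) {
  stopifnot(is.character(variant_id), length(variant_id) == 1)
  if (kd_fad <= 0 || kd_dic <= 0) stop("dissociation constants must be positive", call. = FALSE)
  if (kprot < 0) stop("`kprot` must be non-negative", call. = FALSE)
  if (expression_pct < 0) stop("`expression_pct` must be non-negative", call. = FALSE)
  if (tm < 20 || tm > 70) stop("`tm` must lie inside the 20-70 C scan window", call. = FALSE)
  out <- tibble::tibble(variant_id = variant_id, kd_fad = kd_fad, kprot = kprot,
                        tm = tm, kd_dic = kd_dic, dh_bind = dh_bind,
                        dcp_bind = dcp_bind, expression_pct = expression_pct)
  class(out) <- c("variant_truth", class(out))
  out
}

#' Noise specification for synthetic datasets
#'
#' Additive zero-mean Gaussian noise, with a standard deviation expressed
#' relative to the signal amplitude of the assay being simulated. The same
#' (truth, design, seed) triple always produces a bit-identical dataset;
#' the seed is applied locally and does not disturb the caller's RNG state.
#'
#' @param sd_fraction Relative noise standard deviation (>= 0). The default
#'   2% is a typical replicate-level scatter for these assays.
#' @param seed Optional integer seed.
#' @return List with `sd_fraction` and `seed`.
#' @export
noise_spec <- function(sd_fraction = 0.02, seed = NULL) {
  if (sd_fraction < 0) stop("`sd_fraction` must be non-negative", call. = FALSE)
  list(sd_fraction = sd_fraction, seed = seed)
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default assay designs
#'
#' Designs mirror the bench protocols the analysis assumes: a 0.25 µM
#' protein solution titrated with 0–5 µM ligand (fluorescence titration);
#' ~10 µM protein digested by 0.2–1.2 µM thermolysin (proteolysis); a
#' 20–70 °C scan at 0.5 °C resolution (thermal denaturation); a small
#' 0.5 µL pre-injection followed by 21 injections of 1.75 µL of 120 µM
#' ligand into a 200 µL cell holding 10 µM protein (ITC).
#'
#' @return A named list of design parameters for the corresponding
#'   `simulate_*` function.
#' @name assay_designs
NULL

#' @rdname assay_designs
#' @param kd_hint Expected dissociation constant (µM) used to extend the
#'   ligand grid for weak binders: the titration runs to
#'   `max(5, 6 * kd_hint)` µM so the saturation plateau is reached, as an
#'   experimenter would titrate until the signal levels off. The default
#'   hint reproduces the standard 0–5 µM protocol.
#' @export
titration_design <- function(kd_hint = 0.25) {
  l_max <- max(5, 6 * kd_hint)
  list(protein_total_uM = 0.25,
       ligand_uM = l_max * c(0, 0.02, 0.04, 0.07, 0.1, 0.15, 0.2, 0.25, 0.3, 0.4,
                             0.5, 0.6, 0.7, 0.8, 0.9, 1),
       i_apo = 100, i_holo = 30)
}

#' @rdname assay_designs
#' @param kprot Second-order proteolysis rate constant (µM^-1·min^-1) used
#'   to scale the sampling times so the time grid spans the observable
#'   decay, as an experimenter would choose aliquot times; the grid covers
#'   roughly six half-lives at the median protease concentration.
#' @export
proteolysis_design <- function(kprot = 0.05) {
  protease <- c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2)
  t_half <- log(2) / (max(kprot, 1e-6) * stats::median(protease))
  list(protease_uM = protease,
       time_min = t_half * c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4.5, 6))
}

#' @rdname assay_designs
#' @export
thermal_design <- function() {
  list(temp_min = 20, temp_max = 70, step = 0.5, width = 1.2,
       pre_baseline = c(intercept = 50, slope = -0.10),
       post_baseline = c(intercept = 120, slope = -0.35))
}

#' @rdname assay_designs
#' @export
itc_design <- function() {
  list(cell_protein_uM = 10, syringe_ligand_uM = 120,
       injection_volumes_uL = c(0.5, rep(1.75, 21)),
       cell_volume_uL = 200, q_dil = -0.1, temperature_C = 25)
}

#' Simulate a fluorescence cofactor-binding titration
#'
#' Generates intensities from the quadratic tight-binding forward model
#' ([predict_intensity()]) plus additive Gaussian noise scaled to the
#' apo-holo intensity amplitude. A noiseless call returns the forward model
#' exactly.
#'
#' @param truth A [variant_truth()] row (uses `kd_fad`).
#' @param design List as from [titration_design()]; the ligand grid must be
#'   strictly increasing with at least 8 points.
#' @param noise A [noise_spec()].
#' @return Tibble with columns `ligand_total_uM`, `intensity_au`, and
#'   attribute `protein_total` (µM).
#' @export
simulate_titration <- function(truth, design = titration_design(), noise = noise_spec()) {
  L <- design$ligand_uM
  if (length(L) == 0) stop("ligand grid is empty", call. = FALSE)
  if (any(L < 0) || design$protein_total_uM <= 0) {
    stop("concentrations must be non-negative (protein positive)", call. = FALSE)
  }
  single_point <- length(L) == 1
  if (!single_point && (length(L) < 8 || any(diff(L) <= 0))) {
    stop("ligand grid must be strictly increasing with >= 8 points", call. = FALSE)
  }
  mu <- predict_intensity(L, truth$kd_fad, design$i_apo, design$i_holo,
                          design$protein_total_uM)
  sd <- noise$sd_fraction * abs(design$i_holo - design$i_apo)
  I <- with_local_seed(noise$seed, mu + stats::rnorm(length(mu), 0, sd))
  out <- tibble::tibble(ligand_total_uM = L, intensity_au = I)
  attr(out, "protein_total") <- design$protein_total_uM
  attr(out, "variant_id") <- truth$variant_id
  out
}

#' Simulate limited-proteolysis time courses
#'
#' For each protease concentration E, the intact fraction decays as
#' `exp(-kprot * E * t)`; additive Gaussian noise is scaled to the unit
#' amplitude of the densitometric fraction. The fraction at t = 0 is 1
#' before noise.
#'
#' @param truth A [variant_truth()] row (uses `kprot`).
#' @param design List as from [proteolysis_design()]; at least 3 protease
#'   concentrations, time grid must include 0.
#' @param noise A [noise_spec()].
#' @return Tibble with columns `protease_uM`, `time_min`, `intact_fraction`.
#' @export
simulate_proteolysis <- function(truth, design = proteolysis_design(), noise = noise_spec()) {
  E <- design$protease_uM
  t <- design$time_min
  if (any(t < 0) || any(E < 0)) stop("times and concentrations must be non-negative", call. = FALSE)
  if (length(E) < 3) stop("need at least 3 protease concentrations", call. = FALSE)
  if (!any(t == 0)) stop("time grid must include 0", call. = FALSE)
  grid <- tidyr::expand_grid(protease_uM = E, time_min = t)
  mu <- exp(-truth$kprot * grid$protease_uM * grid$time_min)
  frac <- with_local_seed(noise$seed,
                          mu + stats::rnorm(length(mu), 0, noise$sd_fraction))
  out <- grid
  out$intact_fraction <- frac
  attr(out, "variant_id") <- truth$variant_id
  out
}

#' Simulate a thermal denaturation scan
#'
#' Signal is a two-parameter logistic transition (midpoint `tm`, fixed
#' width) riding between linear pre- and post-transition baselines, plus
#' additive Gaussian noise scaled to the transition amplitude at the
#' midpoint. The midpoint of the noiseless normalized curve equals `tm`
#' exactly. Only the apparent midpoint is consumed downstream, so no
#' two-state thermodynamic parameters are implied.
#'
#' @param truth A [variant_truth()] row (uses `tm`).
#' @param design List as from [thermal_design()]; the scan window must
#'   contain `tm` with at least 5 °C margin.
#' @param noise A [noise_spec()].
#' @return Tibble with columns `temp_C`, `signal_au`.
#' @export
simulate_thermal <- function(truth, design = thermal_design(), noise = noise_spec()) {
  if (truth$tm < design$temp_min + 5 || truth$tm > design$temp_max - 5) {
    stop("`tm` must lie inside the scan window with a 5 C margin", call. = FALSE)
  }
  tt <- seq(design$temp_min, design$temp_max, by = design$step)
  pre <- design$pre_baseline[["intercept"]] + design$pre_baseline[["slope"]] * tt
  post <- design$post_baseline[["intercept"]] + design$post_baseline[["slope"]] * tt
  amp_mid <- abs((design$post_baseline[["intercept"]] + design$post_baseline[["slope"]] * truth$tm) -
                   (design$pre_baseline[["intercept"]] + design$pre_baseline[["slope"]] * truth$tm))
  if (amp_mid < 1e-12) stop("zero transition amplitude: no transition to simulate", call. = FALSE)
  f <- 1 / (1 + exp(-(tt - truth$tm) / design$width))
  mu <- pre + (post - pre) * f
  s <- with_local_seed(noise$seed,
                       mu + stats::rnorm(length(mu), 0, noise$sd_fraction * amp_mid))
  out <- tibble::tibble(temp_C = tt, signal_au = s)
  attr(out, "variant_id") <- truth$variant_id
  out
}

#' Simulate an isothermal titration calorimetry run
#'
#' Heats follow the single-site forward model
#' ([predict_injection_heats()]) with the binding enthalpy evaluated at the
#' run temperature via `dh_bind + dcp_bind * (T - 25)`, plus a dilution
#' heat proportional to injected volume and additive Gaussian noise scaled
#' to the largest binding heat.
#'
#' @param truth A [variant_truth()] row (uses `kd_dic`, `dh_bind`,
#'   `dcp_bind`).
#' @param design List as from [itc_design()]. The syringe concentration
#'   must exceed what is needed to saturate the cell protein by the final
#'   injection.
#' @param noise A [noise_spec()].
#' @return Tibble with columns `injection_index`, `volume_uL`, `heat_ucal`
#'   and design attributes (`cell_protein_uM`, `syringe_ligand_uM`,
#'   `cell_volume_uL`, `temperature_C`) consumed by [fit_itc()].
#' @export
simulate_itc <- function(truth, design = itc_design(), noise = noise_spec()) {
  if (design$cell_volume_uL <= 0) stop("cell volume must be positive", call. = FALSE)
  if (design$syringe_ligand_uM <= 0) stop("syringe concentration must be positive", call. = FALSE)
  if (design$cell_protein_uM < 0) stop("cell concentration must be non-negative", call. = FALSE)
  v <- design$injection_volumes_uL
  total_ligand <- design$syringe_ligand_uM * sum(v) / design$cell_volume_uL
  if (design$cell_protein_uM > 0 && total_ligand < design$cell_protein_uM) {
    stop("design does not reach saturation by the final injection", call. = FALSE)
  }
  dh_T <- truth$dh_bind + truth$dcp_bind * (design$temperature_C - 25)
  mu <- predict_injection_heats(1, truth$kd_dic, dh_T, design$q_dil,
                                design$cell_protein_uM, design$syringe_ligand_uM,
                                design$cell_volume_uL, v)
  amp <- max(abs(mu - design$q_dil * v))
  sd <- noise$sd_fraction * if (amp > 0) amp else 1
  q <- with_local_seed(noise$seed, mu + stats::rnorm(length(mu), 0, sd))
  out <- tibble::tibble(injection_index = seq_along(v), volume_uL = v, heat_ucal = q)
  attr(out, "cell_protein_uM") <- design$cell_protein_uM
  attr(out, "syringe_ligand_uM") <- design$syringe_ligand_uM
  attr(out, "cell_volume_uL") <- design$cell_volume_uL
  attr(out, "temperature_C") <- design$temperature_C
  attr(out, "variant_id") <- truth$variant_id
  out
}

#' Ground-truth panel for the wild type and the six purifiable variants
#'
#' Returns the built-in truth table used by the end-to-end tests and the
#' worked examples: the wild type plus six purifiable missense variants of
#' the N-terminal region, with fold-changes chosen to reproduce the
#' reported qualitative phenotypes (a 12-fold weaker FAD binder with a
#' 4–5 °C lower melting point for T16M, 6-fold weaker FAD binding for
#' A29T, a 1.5 °C thermal destabilization for V9I, and so on) when the
#' panel is pushed through the full simulate-fit-score pipeline.
#'
#' @return A `variant_truth` tibble with 7 rows (WT first).
#' @examples
#' build_fixture_panel()
#' @export
build_fixture_panel <- function() {
  dplyr::bind_rows(
    variant_truth("WT",   kd_fad = 0.25,  kprot = 0.05,  tm = 54.0, kd_dic = 0.030,
                  dh_bind = -9.0, dcp_bind = -0.33, expression_pct = 100),
    variant_truth("G3S",  kd_fad = 0.30,  kprot = 0.060, tm = 53.5, kd_dic = 0.036,
                  dh_bind = -9.1, dcp_bind = -0.34, expression_pct = 95),
    variant_truth("G3D",  kd_fad = 0.325, kprot = 0.065, tm = 53.4, kd_dic = 0.040,
                  dh_bind = -8.9, dcp_bind = -0.32, expression_pct = 90),
    variant_truth("V9I",  kd_fad = 0.275, kprot = 0.060, tm = 52.5, kd_dic = 0.033,
                  dh_bind = -9.0, dcp_bind = -0.33, expression_pct = 92),
    variant_truth("T16M", kd_fad = 3.0,   kprot = 0.32,  tm = 49.5, kd_dic = 0.039,
                  dh_bind = -9.3, dcp_bind = -0.35, expression_pct = 88),
    variant_truth("Y20N", kd_fad = 0.875, kprot = 0.098, tm = 49.8, kd_dic = 0.036,
                  dh_bind = -8.8, dcp_bind = -0.31, expression_pct = 90),
    variant_truth("A29T", kd_fad = 1.5,   kprot = 0.055, tm = 53.5, kd_dic = 0.033,
                  dh_bind = -9.2, dcp_bind = -0.34, expression_pct = 95)
  )
}
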