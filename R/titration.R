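#' Predict fluorescence intensity along a tight-binding titration
#'
#' Forward model for a fluorescence-monitored cofactor titration at protein
#' concentrations comparable to the dissociation constant, where the free
#' ligand concentration cannot be approximated by the total. The bound
#' fraction is the physical root of the single-site mass-balance quadratic,
#' so the predicted signal is
#' \deqn{I = I_{apo} + (I_{holo} - I_{apo})
#'   \frac{[P] + [L] + K_d - \sqrt{([P]+[L]+K_d)^2 - 4 [P][L]}}{2 [P]}}
#' with all concentrations in µM.
#'
#' @param ligand_total Total ligand concentration(s), µM (vectorized).
#' @param kd Dissociation constant, µM (>= 0; 0 gives the stoichiometric
#'   limit).
#' @param i_apo,i_holo Fluorescence intensities of the ligand-free and
#'   saturated protein, arbitrary units.
#' @param protein_total Total protein concentration, µM (> 0).
#' @return Numeric vector of predicted intensities, bounded between `i_apo`
#'   and `i_holo`.
#' @examples
#' predict_intensity(c(0, 0.5, 5), kd = 1, i_apo = 100, i_holo = 40,
#'                   protein_total = 0.25)
#' @export
predict_intensity <- function(ligand_total, kd, i_apo, i_holo, protein_total) {
  if (any(ligand_total < 0)) stop("ligand concentrations must be non-negative", call. = FALSE)
  if (kd < 0) stop("`kd` must be non-negative", call. = FALSE)
  if (protein_total <= 0) stop("`protein_total` must be positive", call. = FALSE)
  b <- protein_total + ligand_total + kd
  disc <- pmax(b^2 - 4 * protein_total * ligand_total, 0)
  bound_fraction <- (b - sqrt(disc)) / (2 * protein_total)
  i_apo + (i_holo - i_apo) * bound_fraction
}

#' Fit a fluorescence titration with the quadratic tight-binding isotherm
#'
#' Estimates the dissociation constant and the apo/holo intensity plateaus
#' by nonlinear least squares (Levenberg–Marquardt with a non-negativity
#' bound on Kd). Initial values are `i_apo` = first intensity, `i_holo` =
#' last intensity and `kd` = the midpoint ligand concentration, which is
#' robust for the monotone, sigmoid-free shape of the quadratic isotherm.
#'
#' @param curve Data frame with columns `ligand_total_uM` (strictly
#'   increasing, >= 5 points) and `intensity_au`.
#' @param protein_total Total protein concentration, µM.
#' @return An object of class `fad_binding_fit`: a list with `kd` (µM),
#'   `kd_se`, `i_apo`, `i_holo` (with standard errors), `residual_norm`
#'   (residual sum of squares), the underlying `nls` fit and the input data.
#' @examples
#' curve <- simulate_titration(variant_truth("WT", kd_fad = 1),
#'                             noise = noise_spec(0))
#' fit_titration(curve, protein_total = 0.25)$kd
#' @export
fit_titration <- function(curve, protein_total = attr(curve, "protein_total") %||% 0.25) {
  stopifnot(is.data.frame(curve))
  if (!all(c("ligand_total_uM", "intensity_au") %in% names(curve))) {
    stop("`curve` needs columns ligand_total_uM and intensity_au", call. = FALSE)
  }
  L <- curve$ligand_total_uM
  I <- curve$intensity_au
  if (length(L) < 5) stop("need at least 5 titration points", call. = FALSE)
  if (any(diff(L) <= 0)) stop("ligand_total_uM must be strictly increasing", call. = FALSE)
  if (stats::sd(I) < 1e-12 || abs(I[length(I)] - I[1]) < 1e-9 * (abs(I[1]) + 1e-12)) {
    stop("no binding signal: intensities are flat", call. = FALSE)
  }
  start <- list(kd = max(stats::median(L), 1e-3), i_apo = I[1], i_holo = I[length(I)])
  fit <- minpack.lm::nlsLM(
    intensity_au ~ predict_intensity(ligand_total_uM, kd, i_apo, i_holo, protein_total),
    data = curve, start = start,
    lower = c(kd = 0, i_apo = -Inf, i_holo = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- summary(fit)$coefficients
  out <- list(
    kd = est["kd", "Estimate"], kd_se = est["kd", "Std. Error"],
    i_apo = est["i_apo", "Estimate"], i_apo_se = est["i_apo", "Std. Error"],
    i_holo = est["i_holo", "Estimate"], i_holo_se = est["i_holo", "Std. Error"],
    protein_total = protein_total,
    residual_norm = sum(stats::residuals(fit)^2),
    fit = fit, data = tibble::as_tibble(curve)
  )
  if (abs(out$i_apo - out$i_holo) < 1e-9 * (abs(out$i_apo) + 1e-12)) {
    stop("no binding signal: fitted plateaus coincide", call. = FALSE)
  }
  class(out) <- "fad_binding_fit"
  out
}

#' @export
print.fad_binding_fit <- function(x, ...) {
  cat(sprintf("Tight-binding titration fit: Kd = %.4g +/- %.2g uM ([P] = %g uM)\n",
              x$kd, x$kd_se, x$protein_total))
  cat(sprintf("  I_apo = %.4g, I_holo = %.4g, RSS = %.3g\n",
              x$i_apo, x$i_holo, x$residual_norm))
  invisible(x)
}

#' Binding free energy from a dissociation constant
#'
#' Converts a dissociation constant to an apparent binding free energy using
#' \eqn{\Delta G = R T \ln K_d} with Kd expressed in molar. Note the sign
#' convention: the formula is applied as printed in the source rubric for
#' this assay family (no leading minus sign), so sub-molar dissociation
#' constants give negative values and only *differences* between variants
#' carry mechanistic meaning. The standard error, when a Kd error is given,
#' follows by linear propagation: \eqn{\sigma_{\Delta G} = RT \sigma_K / K}.
#'
#' @param kd_uM Dissociation constant in µM (> 0).
#' @param kd_se_uM Optional standard error of `kd_uM`.
#' @param constants Output of [thermo_constants()].
#' @return A list with `dg` (kcal·mol^-1) and `dg_se` (NA when no error is
#'   supplied).
#' @examples
#' binding_free_energy(1)$dg  # 1 uM -> about -8.18 kcal/mol
#' @export
binding_free_energy <- function(kd_uM, kd_se_uM = NA_real_, constants = thermo_constants()) {
  if (!is.finite(kd_uM) || kd_uM <= 0) stop("`kd_uM` must be positive", call. = FALSE)
  kd_M <- kd_uM * 1e-6
  dg <- constants$RT * log(kd_M)
  dg_se <- if (is.na(kd_se_uM)) NA_real_ else constants$RT * (kd_se_uM / kd_uM)
  list(dg = dg, dg_se = dg_se)
}

#' Mutational change in binding free energy
#'
#' \eqn{\Delta\Delta G = R T \ln(K_d^{mut} / K_d^{WT})}; positive values mean
#' the mutant binds more weakly. Antisymmetric under swapping the two
#' variants. Units of the two constants cancel, so any common concentration
#' unit may be used.
#'
#' @param kd_mut,kd_wt Dissociation constants for mutant and wild type
#'   (same units, > 0).
#' @param se_mut,se_wt Optional standard errors, propagated linearly.
#' @param constants Output of [thermo_constants()].
#' @return List with `ddg` (kcal·mol^-1) and `ddg_se`.
#' @examples
#' delta_delta_g(12, 1)$ddg  # 12-fold weaker: ~1.5 kcal/mol
#' @export
delta_delta_g <- function(kd_mut, kd_wt, se_mut = NA_real_, se_wt = NA_real_,
                          constants = thermo_constants()) {
  if (kd_mut <= 0 || kd_wt <= 0) stop("dissociation constants must be positive", call. = FALSE)
  ddg <- constants$RT * log(kd_mut / kd_wt)
  ddg_se <- if (is.na(se_mut) && is.na(se_wt)) NA_real_ else {
    constants$RT * sqrt(ifelse(is.na(se_mut), 0, (se_mut / kd_mut)^2) +
                          ifelse(is.na(se_wt), 0, (se_wt / kd_wt)^2))
  }
  list(ddg = ddg, ddg_se = ddg_se)
}

#' Flavin content per protein monomer from a normalized absorption spectrum
#'
#' The UV-visible spectrum is first normalized so that the 280 nm absorbance
#' equals the protein molar extinction coefficient (47,900 M^-1·cm^-1),
#' i.e. absorbances are expressed per mole of protein monomer. The FAD
#' occupancy is then the normalized 450 nm absorbance divided by the free
#' flavin extinction coefficient (11,300 M^-1·cm^-1).
#'
#' @param a450_normalized Absorbance at 450 nm from the normalized spectrum,
#'   M^-1·cm^-1 (i.e. already scaled to per-monomer units). Non-negative.
#' @param a280_normalized Normalized 280 nm absorbance; must be positive
#'   (zero protein is undefined). Defaults to the protein extinction
#'   coefficient, which is what normalization enforces.
#' @return Mol FAD per protein monomer.
#' @examples
#' fad_content(5650)  # 0.5 mol FAD per monomer
#' @export
fad_content <- function(a450_normalized, a280_normalized = EPS_PROTEIN_280) {
  if (a280_normalized <= 0) stop("protein absorbance must be positive", call. = FALSE)
  if (a450_normalized < 0) stop("`a450_normalized` must be non-negative", call. = FALSE)
  (a450_normalized * (EPS_PROTEIN_280 / a280_normalized)) / EPS_FAD_450
}
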