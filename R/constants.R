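#' Thermodynamic constants
#'
#' Gas constant and absolute temperature used by every `RT * ln` computation
#' in the package. The gas constant is expressed in kcal·mol^-1·K^-1 so that
#' all derived free energies are in kcal·mol^-1, the unit in which variant
#' effects in this field are conventionally reported.
#'
#' @param temperature_K Absolute temperature in kelvin. Defaults to 298.15 K
#'   (25 °C), the temperature at which the binding and proteolysis assays
#'   are run.
#' @return A list with elements `R` (1.987e-3 kcal·mol^-1·K^-1), `T`
#'   (temperature in K) and `RT` (their product, kcal·mol^-1).
#' @examples
#' thermo_constants()$RT  # ~0.592 kcal/mol at 25 C
#' @export
thermo_constants <- function(temperature_K = 298.15) {
  if (!is.numeric(temperature_K) || length(temperature_K) != 1 || temperature_K <= 0) {
    stop("`temperature_K` must be a single positive number", call. = FALSE)
  }
  R <- 1.987e-3
  list(R = R, T = temperature_K, RT = R * temperature_K)
}

#' Per-residue structure-energetics coefficients and intrinsic binding terms
#'
#' Coefficients used to convert conformational enthalpy and heat-capacity
#' contributions into a number of residues folding upon ligand binding, plus
#' the intrinsic (rigid-body) binding enthalpy and heat-capacity change
#' estimated from buried surface area of the inhibitor complex. These are
#' imported literature parametrizations, not fitted quantities.
#'
#' @return A list with `dh_intrinsic` (-5.8 kcal·mol^-1 at 25 °C),
#'   `dcp_intrinsic` (-0.14 kcal·mol^-1·K^-1), `dh_per_residue`
#'   (0.215 kcal·mol^-1 per residue) and `dcp_per_residue`
#'   (0.0138 kcal·mol^-1·K^-1 per residue).
#' @export
structure_energetics_constants <- function() {
  list(
    dh_intrinsic   = -5.8,
    dcp_intrinsic  = -0.14,
    dh_per_residue = 0.215,
    dcp_per_residue = 0.0138
  )
}

# Extinction coefficients (M^-1 cm^-1) used for flavin-content determination.
EPS_PROTEIN_280 <- 47900
EPS_FAD_450 <- 11300
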