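#' Diagnostic plots for fitted assay objects
#'
#' `autoplot()` methods draw the data with the fitted model overlaid:
#' titration points with the fitted tight-binding isotherm, observed rate
#' constants with the second-order line, the normalized unfolded-fraction
#' curve with its midpoint, and the enthalpogram with the fitted
#' single-site model.
#'
#' @param object A fitted object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name varitrait-autoplot
NULL

#' @rdname varitrait-autoplot
#' @method autoplot fad_binding_fit
#' @export
autoplot.fad_binding_fit <- function(object, ...) {
  grid <- tibble::tibble(ligand_total_uM = seq(min(object$data$ligand_total_uM),
                                               max(object$data$ligand_total_uM),
                                               length.out = 200))
  grid$intensity_au <- predict_intensity(grid$ligand_total_uM, object$kd,
                                         object$i_apo, object$i_holo,
                                         object$protein_total)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$ligand_total_uM, .data$intensity_au)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "total ligand (µM)", y = "fluorescence (a.u.)",
                  title = sprintf("Kd = %.3g µM", object$kd)) +
    ggplot2::theme_minimal()
}

#' @rdname varitrait-autoplot
#' @method autoplot proteolysis_fit
#' @export
autoplot.proteolysis_fit <- function(object, ...) {
  df <- tibble::tibble(protease_uM = object$protease_uM, k_obs = object$k_obs)
  ggplot2::ggplot(df, ggplot2::aes(.data$protease_uM, .data$k_obs)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$k_prot,
                         colour = "firebrick") +
    ggplot2::labs(x = "thermolysin (µM)", y = expression(k[obs] ~ (min^-1)),
                  title = sprintf("k_prot = %.3g µM⁻¹ min⁻¹",
                                  object$k_prot)) +
    ggplot2::theme_minimal()
}

#' @rdname varitrait-autoplot
#' @method autoplot tm_result
#' @export
autoplot.tm_result <- function(object, ...) {
  ggplot2::ggplot(object$fraction_curve, ggplot2::aes(.data$temp_C, .data$fraction)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$tm, colour = "firebrick") +
    ggplot2::labs(x = "temperature (°C)", y = "apparent unfolded fraction",
                  title = sprintf("Tm = %.2f °C", object$tm)) +
    ggplot2::theme_minimal()
}

#' @rdname varitrait-autoplot
#' @method autoplot itc_fit
#' @export
autoplot.itc_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- predict_injection_heats(object$n_sites, object$kd, object$dh,
                                      object$q_dil, object$design$cell_protein_uM,
                                      object$design$syringe_ligand_uM,
                                      object$design$cell_volume_uL, d$volume_uL)
  ggplot2::ggplot(d, ggplot2::aes(.data$injection_index, .data$heat_ucal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "injection", y = "heat (µcal)",
                  title = sprintf("N = %.2f, Kd = %.3g µM, ΔH = %.2f kcal/mol",
                                  object$n_sites, object$kd, object$dh)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of experimental versus bioinformatic scores
#'
#' Draws the ES-versus-BS scatter with the pooled regression line (solid)
#' and per-set lines (dashed), mirroring the usual presentation of this
#' correlation.
#'
#' @param pairs Data frame with columns `es`, `bs` and optionally `set`
#'   and `variant`.
#' @return A ggplot object.
#' @examples
#' plot_scores(score_published_panels())
#' @export
plot_scores <- function(pairs) {
  if (!"set" %in% names(pairs)) pairs$set <- variant_set(pairs$variant)
  ggplot2::ggplot(pairs, ggplot2::aes(.data$bs, .data$es)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black") +
    ggplot2::geom_smooth(ggplot2::aes(colour = .data$set), method = "lm",
                         formula = y ~ x, se = FALSE, linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$set), size = 2) +
    ggplot2::labs(x = "bioinformatic score (BS)", y = "experimental score (ES)") +
    ggplot2::coord_cartesian(xlim = c(1, 3), ylim = c(1, 3)) +
    ggplot2::theme_minimal()
}
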