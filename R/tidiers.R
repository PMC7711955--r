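#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||% .data
NULL

#' Tidy methods for fitted assay objects
#'
#' Broom-style one-row-per-parameter summaries (`tidy()`) and one-row
#' model summaries (`glance()`) for the fit objects produced by
#' [fit_titration()], [fit_proteolysis_series()]/[fit_second_order()],
#' [extract_tm()], [fit_itc()] and [run_pipeline()].
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name varitrait-tidiers
NULL

#' @rdname varitrait-tidiers
#' @method tidy fad_binding_fit
#' @export
tidy.fad_binding_fit <- function(x, ...) {
  tibble::tibble(term = c("kd", "i_apo", "i_holo"),
                 estimate = c(x$kd, x$i_apo, x$i_holo),
                 std.error = c(x$kd_se, x$i_apo_se, x$i_holo_se))
}

#' @rdname varitrait-tidiers
#' @method glance fad_binding_fit
#' @export
glance.fad_binding_fit <- function(x, ...) {
  tibble::tibble(kd = x$kd, kd_se = x$kd_se, residual_norm = x$residual_norm,
                 protein_total = x$protein_total, nobs = nrow(x$data))
}

#' @rdname varitrait-tidiers
#' @method tidy proteolysis_fit
#' @export
tidy.proteolysis_fit <- function(x, ...) {
  tibble::tibble(term = c("k_prot", "intercept"),
                 estimate = c(x$k_prot, x$intercept),
                 std.error = c(x$k_prot_se, x$intercept_se))
}

#' @rdname varitrait-tidiers
#' @method glance proteolysis_fit
#' @export
glance.proteolysis_fit <- function(x, ...) {
  tibble::tibble(k_prot = x$k_prot, k_prot_se = x$k_prot_se,
                 linearity_r2 = x$linearity_r2, nobs = length(x$k_obs))
}

#' @rdname varitrait-tidiers
#' @method tidy tm_result
#' @export
tidy.tm_result <- function(x, ...) {
  tibble::tibble(term = "tm", estimate = x$tm, std.error = x$tm_se)
}

#' @rdname varitrait-tidiers
#' @method glance tm_result
#' @export
glance.tm_result <- function(x, ...) {
  tibble::tibble(tm = x$tm, tm_se = x$tm_se, nobs = nrow(x$fraction_curve))
}

#' @rdname varitrait-tidiers
#' @method tidy itc_fit
#' @export
tidy.itc_fit <- function(x, ...) {
  tibble::tibble(
    term = c("n_sites", "kd", "dh", "q_dil"),
    estimate = c(x$n_sites, x$kd, x$dh, x$q_dil),
    std.error = c(x$n_sites_se, x$kd_se, x$dh_se, x$q_dil_se))
}

#' @rdname varitrait-tidiers
#' @method glance itc_fit
#' @export
glance.itc_fit <- function(x, ...) {
  tibble::tibble(n_sites = x$n_sites, kd = x$kd, ka = x$ka, dh = x$dh,
                 dg = x$dg, ds = x$ds, c_value = x$c_value,
                 temperature_C = x$temperature_C, residual_norm = x$residual_norm)
}

#' @rdname varitrait-tidiers
#' @method tidy variant_report
#' @export
tidy.variant_report <- function(x, ...) {
  dplyr::left_join(x$codes, x$scores, by = "variant_id")
}

#' @rdname varitrait-tidiers
#' @method glance variant_report
#' @export
glance.variant_report <- function(x, ...) {
  pooled <- if (is.null(x$regression)) NULL else x$regression[x$regression$set == "all", ]
  tibble::tibble(n_variants = nrow(x$traits),
                 seed = x$provenance$seed, noise_sd = x$provenance$noise_sd,
                 pooled_slope = pooled$slope %||% NA_real_,
                 pooled_r = pooled$r %||% NA_real_)
}
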