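#' Normalize a thermal denaturation scan with linear baselines
#'
#' Fits linear pre- and post-transition baselines to the flanks of the scan
#' and converts the raw fluorescence signal to an apparent unfolded fraction
#' \eqn{f(T) = (S(T) - pre(T)) / (post(T) - pre(T))}. Because denaturation
#' here is irreversible, the fraction curve is apparent (operational), and
#' only its midpoint is interpreted downstream.
#'
#' @param scan Data frame with columns `temp_C` (monotone increasing, >= 20
#'   points) and `signal_au`.
#' @param pre_window,post_window Length-2 numeric ranges (°C) used to fit
#'   the baselines; defaults are the first and last 15% of the scanned
#'   range. Each window must contain at least 4 points and the two must be
#'   disjoint.
#' @return A tibble with columns `temp_C`, `signal_au`, `fraction`, plus
#'   attributes `pre_baseline` and `post_baseline` (intercept/slope pairs).
#' @examples
#' scan <- simulate_thermal(variant_truth("WT", tm = 54), noise = noise_spec(0))
#' head(normalize_scan(scan))
#' @export
normalize_scan <- function(scan, pre_window = NULL, post_window = NULL) {
  stopifnot(is.data.frame(scan))
  if (!all(c("temp_C", "signal_au") %in% names(scan))) {
    stop("`scan` needs columns temp_C and signal_au", call. = FALSE)
  }
  tt <- scan$temp_C
  ss <- scan$signal_au
  if (length(tt) < 20) stop("need at least 20 scan points", call. = FALSE)
  if (any(diff(tt) <= 0)) stop("temp_C must be strictly increasing", call. = FALSE)
  rng <- range(tt)
  span <- diff(rng)
  if (is.null(pre_window)) pre_window <- c(rng[1], rng[1] + 0.15 * span)
  if (is.null(post_window)) post_window <- c(rng[2] - 0.15 * span, rng[2])
  if (pre_window[2] >= post_window[1]) stop("baseline windows must be disjoint", call. = FALSE)
  pre_idx <- tt >= pre_window[1] & tt <= pre_window[2]
  post_idx <- tt >= post_window[1] & tt <= post_window[2]
  if (sum(pre_idx) < 4 || sum(post_idx) < 4) {
    stop("each baseline window needs at least 4 points", call. = FALSE)
  }
  pre_fit <- stats::lm(ss[pre_idx] ~ tt[pre_idx])
  post_fit <- stats::lm(ss[post_idx] ~ tt[post_idx])
  pre <- unname(stats::coef(pre_fit))   # intercept, slope
  post <- unname(stats::coef(post_fit))
  pre_v <- pre[1] + pre[2] * tt
  post_v <- post[1] + post[2] * tt
  amp <- post_v - pre_v
  mid <- tt > pre_window[2] & tt < post_window[1]
  scale0 <- mean(abs(ss)) + 1e-12
  if (all(abs(amp) < 1e-6 * scale0)) {
    stop("baselines indistinguishable: no transition amplitude", call. = FALSE)
  }
  if (any(sign(amp[mid]) != sign(amp[mid][1]))) {
    stop("baselines cross inside the transition region", call. = FALSE)
  }
  out <- tibble::tibble(temp_C = tt, signal_au = ss, fraction = (ss - pre_v) / amp)
  attr(out, "pre_baseline") <- c(intercept = pre[1], slope = pre[2])
  attr(out, "post_baseline") <- c(intercept = post[1], slope = post[2])
  out
}

#' Extract the apparent half-denaturation temperature
#'
#' Locates the temperature at which the normalized unfolded fraction crosses
#' 0.5. The crossing is found by a local linear fit of the fraction against
#' temperature over the transition region (points with fraction between
#' `band[1]` and `band[2]`), which interpolates the midpoint robustly in the
#' presence of measurement noise. The curve must pass through 0.5 exactly
#' once at the resolution of the transition; flat or multi-phasic curves
#' raise an error. When replicate midpoints are supplied via `replicates`,
#' their standard deviation is reported as the standard error.
#'
#' @param fraction_curve Output of [normalize_scan()] (columns `temp_C`,
#'   `fraction`), or any data frame with those columns.
#' @param band Fraction band defining the transition region used for the
#'   local interpolation (default 0.25–0.75).
#' @param replicates Optional numeric vector of midpoints from replicate
#'   scans, used only for the scatter-based standard error.
#' @return An object of class `tm_result`: list with `tm` (°C), `tm_se`,
#'   the baseline attributes carried over, and the fraction curve.
#' @examples
#' scan <- simulate_thermal(variant_truth("WT", tm = 54), noise = noise_spec(0))
#' extract_tm(normalize_scan(scan))$tm
#' @export
extract_tm <- function(fraction_curve, band = c(0.25, 0.75), replicates = NULL) {
  stopifnot(is.data.frame(fraction_curve))
  if (!all(c("temp_C", "fraction") %in% names(fraction_curve))) {
    stop("`fraction_curve` needs columns temp_C and fraction", call. = FALSE)
  }
  tt <- fraction_curve$temp_C
  f <- fraction_curve$fraction
  in_band <- f >= band[1] & f <= band[2]
  if (sum(in_band) < 2) stop("no resolvable 0.5 crossing in the fraction curve", call. = FALSE)
  # the band must be a single contiguous run: multiple runs mean multiple
  # transitions (or a non-monotone curve), which an apparent Tm cannot summarize
  runs <- rle(in_band)
  if (sum(runs$values) > 1) stop("multiple 0.5 crossings: curve is not single-transition", call. = FALSE)
  before <- f[seq_len(which(in_band)[1] - 1)]
  after <- f[seq((max(which(in_band)) + 1), length(f))]
  if (length(before) == 0 || length(after) == 0 ||
      (stats::median(before) > 0.5) == (stats::median(after) > 0.5)) {
    stop("fraction curve does not cross 0.5", call. = FALSE)
  }
  loc <- stats::lm(f[in_band] ~ tt[in_band])
  b <- unname(stats::coef(loc))
  if (abs(b[2]) < 1e-12) stop("flat transition region: cannot interpolate midpoint", call. = FALSE)
  tm <- (0.5 - b[1]) / b[2]
  if (tm < min(tt) || tm > max(tt)) stop("interpolated midpoint outside scan window", call. = FALSE)
  out <- list(
    tm = tm,
    tm_se = if (is.null(replicates)) NA_real_ else stats::sd(replicates),
    pre_baseline = attr(fraction_curve, "pre_baseline"),
    post_baseline = attr(fraction_curve, "post_baseline"),
    fraction_curve = tibble::as_tibble(fraction_curve[c("temp_C", "fraction")])
  )
  class(out) <- "tm_result"
  out
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("Apparent half-denaturation temperature: Tm = %.2f C", x$tm))
  if (!is.na(x$tm_se)) cat(sprintf(" +/- %.2f", x$tm_se))
  cat("\n")
  invisible(x)
}

#' Change in apparent melting temperature between mutant and wild type
#'
#' @param tm_mut,tm_wt Apparent midpoints, °C. Negative result = mutant
#'   destabilized.
#' @return `tm_mut - tm_wt`, °C.
#' @examples
#' delta_tm(49.5, 54)
#' @export
delta_tm <- function(tm_mut, tm_wt) {
  stopifnot(is.finite(tm_mut), is.finite(tm_wt))
  tm_mut - tm_wt
}
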