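# Nonlinear reception model: intermodulation frequency algebra, the
# second-order IMD power law with intercept-point fitting, and the
# flux-product model of the received beat signal.

#' Define a transmitted tone pair
#'
#' @param f1,f2 Tone frequencies in Hz, `f2 > f1 > 0`.
#' @param p1_dbm,p2_dbm Tone powers (dBm into 50 ohm).
#' @return An object of class `bpt_tone_pair`.
#' @examples
#' tone_pair(2400e6, 2527.8e6)
#' @export
tone_pair <- function(f1, f2, p1_dbm = 0, p2_dbm = 0) {
  stopifnot(f1 > 0, f2 > f1)
  structure(list(f1 = f1, f2 = f2, p1_dbm = p1_dbm, p2_dbm = p2_dbm),
            class = "bpt_tone_pair")
}

#' Intermodulation product frequency
#'
#' A nonlinearity fed with tones at `f1` and `f2` produces products at
#' `m f2 + n f1` for signed integers `m`, `n`. The second-order difference
#' product (`m = 1, n = -1`) of a 2400/2527.8 MHz pair lands at 127.8 MHz -
#' inside a 3T receiver band. A negative raw value is reported as its
#' magnitude with `conjugated = TRUE` (the observable line is at |f|).
#'
#' @param m,n Signed integers, not both zero.
#' @param pair A [tone_pair()].
#' @return A tibble row: `m`, `n`, `frequency_hz`, `conjugated`, `order`.
#' @examples
#' imd_frequency(1, -1, tone_pair(2400e6, 2527.8e6))
#' @export
imd_frequency <- function(m, n, pair) {
  stopifnot(m == round(m), n == round(n))
  if (m == 0 && n == 0) stop("m and n must not both be zero")
  f <- m * pair$f2 + n * pair$f1
  tibble::tibble(m = m, n = n, frequency_hz = abs(f), conjugated = f < 0,
                 order = abs(m) + abs(n))
}

#' Enumerate intermodulation products
#'
#' All products with `|m| + |n| <= max_order`, optionally filtered to a
#' frequency window - the standard way to check which product falls in the
#' receiver band. Each physical spectral line is listed once: of the
#' conjugate pair (m, n) / (-m, -n), only the product with a positive raw
#' frequency is kept.
#'
#' @param pair A [tone_pair()].
#' @param max_order Maximum `|m| + |n|`.
#' @param window Optional `c(low, high)` Hz filter on the product frequency.
#' @return A tibble of products sorted by frequency.
#' @export
imd_products <- function(pair, max_order = 3, window = NULL) {
  grid <- tidyr::expand_grid(m = -max_order:max_order,
                             n = -max_order:max_order)
  grid <- dplyr::filter(grid, abs(.data$m) + abs(.data$n) <= max_order,
                        !(.data$m == 0 & .data$n == 0))
  out <- purrr::pmap_dfr(grid, function(m, n) imd_frequency(m, n, pair))
  out <- dplyr::filter(out, !.data$conjugated)
  if (!is.null(window)) {
    out <- dplyr::filter(out, .data$frequency_hz >= window[1],
                         .data$frequency_hz <= window[2])
  }
  dplyr::arrange(out, .data$frequency_hz)
}

#' Define a preamplifier model
#'
#' A memoryless nonlinearity characterised by its linear gain and
#' output-referred second-order intercept point (IP2). The equivalent
#' polynomial `y = a1 x + a2 x^2` (50-ohm convention) is derived from
#' `(gain, ip2)` and kept alongside.
#'
#' @param gain_db Linear gain in dB.
#' @param ip2_dbm Output-referred IP2 in dBm.
#' @return An object of class `bpt_preamp` with fields `gain_db`, `ip2_dbm`,
#'   `a1`, `a2`.
#' @details Two tones `A1 cos(w1 t) + A2 cos(w2 t)` through `a1 x + a2 x^2`
#'   yield a difference-frequency line of amplitude `a2 A1 A2`, so in mW
#'   `P_IMD = P1_out P2_out / P_IP2` exactly, i.e. in dBm
#'   `P_IMD = (p1 + gain) + (p2 + gain) - IP2`. That identity fixes
#'   `a1 = 10^(gain_db/20)` and `a2 = a1^2 / A_ip2`, where `A_ip2` is the
#'   peak amplitude of a tone of power IP2 into 50 ohm.
#' @export
preamp_model <- function(gain_db = 0, ip2_dbm = 50) {
  a1 <- 10^(gain_db / 20)
  a_ip2 <- dbm_to_amplitude(ip2_dbm)
  structure(
    list(gain_db = gain_db, ip2_dbm = ip2_dbm,
         a1 = a1, a2 = a1^2 / a_ip2),
    class = "bpt_preamp"
  )
}

# dBm <-> peak amplitude in volts across 50 ohm (P = A^2 / (2 R))
dbm_to_amplitude <- function(p_dbm) sqrt(2 * 50 * 10^(p_dbm / 10) * 1e-3)
amplitude_to_dbm <- function(a) 10 * log10(a^2 / (2 * 50) / 1e-3)

#' Second-order intermodulation product power
#'
#' Output power of the difference-frequency product for a two-tone input,
#' under the output-referred IP2 convention:
#' `P_IMD = (p1 + gain) + (p2 + gain) - IP2` (all dBm/dB). Raising both
#' inputs by 1 dB raises the product by 2 dB (the slope-2 law); the product
#' meets the fundamental at the intercept point.
#'
#' @param p1_dbm,p2_dbm Input tone powers (dBm).
#' @param preamp A [preamp_model()].
#' @return IMD output power in dBm.
#' @export
imd2_power <- function(p1_dbm, p2_dbm, preamp) {
  (p1_dbm + preamp$gain_db) + (p2_dbm + preamp$gain_db) - preamp$ip2_dbm
}

#' Apply a memoryless polynomial nonlinearity to a waveform
#'
#' Pointwise `a1 x + a2 x^2 (+ a3 x^3)` on a uniformly sampled real
#' waveform - the time-domain ground truth against which the dB-domain
#' power law is checked. Squaring doubles the occupied bandwidth, so the
#' requested product frequency must stay below Nyquist.
#'
#' @param x Real waveform (uniform sampling).
#' @param poly_coeffs Numeric `c(a1, a2)` or `c(a1, a2, a3)`.
#' @param sample_rate Sampling rate (Hz); required with `max_product_hz`.
#' @param max_product_hz Highest product frequency of interest; an error is
#'   raised if it exceeds Nyquist (aliasing guard).
#' @return The distorted waveform.
#' @export
apply_polynomial_nonlinearity <- function(x, poly_coeffs,
                                          sample_rate = NULL,
                                          max_product_hz = NULL) {
  stopifnot(is.numeric(x), length(poly_coeffs) >= 2)
  if (!is.null(max_product_hz)) {
    if (is.null(sample_rate)) stop("`sample_rate` needed for aliasing guard")
    if (max_product_hz > sample_rate / 2) {
      stop("requested product frequency exceeds Nyquist")
    }
  }
  a1 <- poly_coeffs[1]; a2 <- poly_coeffs[2]
  a3 <- if (length(poly_coeffs) >= 3) poly_coeffs[3] else 0
  a1 * x + a2 * x^2 + a3 * x^3
}

#' Fit gain and second-order intercept point from a power sweep
#'
#' Fits lines of fixed slope 1 (fundamental) and 2 (second-order product)
#' to measured output powers over an input power sweep, and extrapolates
#' their crossing - the output-referred IP2. With slopes constrained, each
#' fit reduces to a mean offset; the unconstrained slopes are also checked
#' and a warning is raised if they deviate by more than 0.3 from 1 and 2
#' (a sign of gain compression contaminating the sweep).
#'
#' @param input_powers_dbm Input tone power per sweep point (dBm); the two
#'   tones are assumed equal, as in a standard two-tone test.
#' @param fundamental_powers_dbm Measured fundamental output powers (dBm).
#' @param imd_powers_dbm Measured second-order product powers (dBm).
#' @return A list with `gain_db`, `ip2_dbm`, `slope_fundamental`,
#'   `slope_imd` (unconstrained check fits).
#' @export
fit_intercept_point <- function(input_powers_dbm, fundamental_powers_dbm,
                                imd_powers_dbm) {
  n <- length(input_powers_dbm)
  stopifnot(length(fundamental_powers_dbm) == n, length(imd_powers_dbm) == n)
  if (n < 2) stop("at least 2 sweep points are required")
  gain_db <- mean(fundamental_powers_dbm - input_powers_dbm)
  # slope-2 line: P_imd = 2 p_in + b; crossing with P_fund = p_in + gain
  b <- mean(imd_powers_dbm - 2 * input_powers_dbm)
  # at the intercept, P_out = p + gain = 2 p + b  =>  p = gain - b,
  # output-referred IP2 = p + gain = 2 gain - b
  ip2_dbm <- 2 * gain_db - b
  sf <- unname(stats::coef(stats::lm(fundamental_powers_dbm ~
                                       input_powers_dbm))[2])
  si <- unname(stats::coef(stats::lm(imd_powers_dbm ~ input_powers_dbm))[2])
  if (abs(sf - 1) > 0.3 || abs(si - 2) > 0.3) {
    warning("fitted slopes deviate from 1/2; compression suspected")
  }
  list(gain_db = gain_db, ip2_dbm = ip2_dbm,
       slope_fundamental = sf, slope_imd = si)
}

#' Received beat signal as a flux product
#'
#' The second-order difference product sensed by a coil is modelled as the
#' per-sample product `conj(flux_f1) * flux_f2`, so its magnitude is
#' `|Phi_1||Phi_2|` and its phase the tone phase difference. Accepts two
#' complex vectors or a sweep tibble from [sweep_coil_positions()] (in
#' which case the product is formed per coil across the two frequencies).
#'
#' @param flux_f1,flux_f2 Equal-length complex flux series for the lower
#'   and upper tone, same coil and axis.
#' @return A complex vector of the same length.
#' @export
bpt_rx_product <- function(flux_f1, flux_f2) {
  if (length(flux_f1) != length(flux_f2)) {
    stop("flux series must share the same axis")
  }
  Conj(flux_f1) * flux_f2
}

#' Beat product per coil from a flux sweep table
#'
#' Convenience wrapper applying [bpt_rx_product()] within each coil of a
#' [sweep_coil_positions()] result for one tone-pair.
#'
#' @param sweep Tibble with `coil_id`, `frequency_hz`, `offset_m`, `flux`.
#' @param f1,f2 The two tone frequencies present in `sweep` (Hz).
#' @return Tibble `coil_id`, `offset_m`, `bpt_rx` (complex).
#' @export
sweep_bpt_product <- function(sweep, f1, f2) {
  pick <- function(f) {
    dplyr::arrange(
      dplyr::filter(sweep, abs(.data$frequency_hz - f) < 0.5),
      .data$coil_id, .data$offset_m)
  }
  s1 <- pick(f1); s2 <- pick(f2)
  if (nrow(s1) == 0 || nrow(s2) == 0 || nrow(s1) != nrow(s2)) {
    stop("sweep does not contain matching series at f1 and f2")
  }
  tibble::tibble(coil_id = s1$coil_id, offset_m = s1$offset_m,
                 bpt_rx = bpt_rx_product(s1$flux, s2$flux))
}
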