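# Synthetic multicoil raw acquisitions with embedded pilot/beat tones, and
# per-readout-line tone extraction. A tone transmitted continuously lands in
# the receiver band but outside the band occupied by the MR signal; it
# appears as a spectral peak in the Fourier transform of every k-space line
# and its per-line complex amplitude is the motion navigator.

#' Acquisition parameter set
#'
#' @param n_lines Number of readout lines.
#' @param n_coils Number of receiver coils.
#' @param n_samples Samples per line.
#' @param bandwidth_hz Receiver bandwidth (Hz); dwell time is its inverse.
#'   Default 250 kHz.
#' @param tr_s Line repetition time (s). Default 4.4 ms.
#' @param image_band_hz `c(low, high)` band of frequency offsets occupied by
#'   the MR signal, within the receiver band.
#' @return A list of class `bpt_acq_params`.
#' @export
acq_params <- function(n_lines = 256, n_coils = 3, n_samples = 256,
                       bandwidth_hz = 250e3, tr_s = 4.4e-3,
                       image_band_hz = c(-50e3, 50e3)) {
  stopifnot(n_lines >= 1, n_coils >= 1, n_samples >= 2, bandwidth_hz > 0,
            tr_s > 0)
  if (image_band_hz[1] >= image_band_hz[2] ||
      image_band_hz[1] < -bandwidth_hz / 2 ||
      image_band_hz[2] > bandwidth_hz / 2) {
    stop("image band must be an increasing interval inside the receiver band")
  }
  structure(
    list(n_lines = n_lines, n_coils = n_coils, n_samples = n_samples,
         bandwidth_hz = bandwidth_hz, dwell_time = 1 / bandwidth_hz,
         tr_s = tr_s, image_band_hz = image_band_hz),
    class = "bpt_acq_params"
  )
}

# smooth random band-limited spectrum, identical on every line: a 1-D
# pseudo-object standing in for the MR content (no 2-D encoding)
mr_content_line <- function(params, amplitude, rng) {
  n <- params$n_samples
  fax <- fft_freq_axis(n, params$bandwidth_hz)
  inband <- fax >= params$image_band_hz[1] & fax <= params$image_band_hz[2]
  spec <- rep(0 + 0i, n)
  k <- sum(inband)
  raw <- complex(real = rng(k), imaginary = rng(k))
  # smooth the spectrum so the pseudo-object is compact
  w <- stats::filter(c(0, Mod(raw), 0), rep(1 / 3, 3), sides = 2)[2:(k + 1)]
  spec[inband] <- raw / pmax(Mod(raw), 1e-12) * as.numeric(w)
  amplitude * stats::fft(spec, inverse = TRUE) / sqrt(n)
}

# FFT bin frequency offsets for n samples at bandwidth bw (fftshift order not
# applied; bin i has offset ((i-1+n/2) %% n - n/2) * bw/n)
fft_freq_axis <- function(n, bw) {
  (((seq_len(n) - 1 + n %/% 2) %% n) - n %/% 2) * bw / n
}

#' Synthesize a raw multicoil acquisition with embedded tones
#'
#' Builds a `lines x coils x samples` complex array containing band-limited
#' MR pseudo-content plus one or more continuous-wave tones, each scaled per
#' line and coil by a complex envelope (the motion signal), plus circular
#' complex Gaussian noise. Tone phase is continuous in absolute time across
#' lines (transmitters share a clock with the scanner), so line-to-line
#' phase is deterministic.
#'
#' @param params An [acq_params()].
#' @param tones A list of tone specs, each
#'   `list(label =, frequency_offset = Hz, envelope =)` where `envelope` is
#'   a complex (or real) matrix `n_lines x n_coils`, a vector recycled over
#'   coils, or a single number.
#' @param mr_amplitude Amplitude of the MR pseudo-content (0 disables).
#' @param noise_sigma Standard deviation per real/imaginary component of the
#'   added complex Gaussian noise.
#' @param seed Integer seed; the output is bit-identical for a fixed seed.
#' @return An object of class `bpt_raw`: list with `data` (complex array),
#'   `params`, `line_times`, `tones` (labels and offsets).
#' @export
synthesize_raw <- function(params, tones = list(), mr_amplitude = 0,
                           noise_sigma = 0, seed = 1) {
  stopifnot(inherits(params, "bpt_acq_params"))
  for (tn in tones) {
    f <- tn$frequency_offset
    if (abs(f) > params$bandwidth_hz / 2) stop("tone outside receiver band")
    if (f >= params$image_band_hz[1] && f <= params$image_band_hz[2]) {
      stop("tone frequency offset lies inside the image band")
    }
  }
  nl <- params$n_lines; nc <- params$n_coils; ns <- params$n_samples
  set.seed(seed)
  data <- array(0 + 0i, dim = c(nl, nc, ns))
  line_times <- (seq_len(nl) - 1) * params$tr_s
  tau <- (seq_len(ns) - 1) * params$dwell_time

  if (mr_amplitude > 0) {
    mr <- mr_content_line(params, mr_amplitude, stats::rnorm)
    for (ci in seq_len(nc)) {
      data[, ci, ] <- data[, ci, ] +
        matrix(mr, nl, ns, byrow = TRUE)
    }
  }
  for (tn in tones) {
    env <- tn$envelope
    if (is.null(dim(env))) env <- matrix(env, nl, nc)
    stopifnot(nrow(env) == nl, ncol(env) == nc)
    f <- tn$frequency_offset
    carrier <- exp(2i * pi * f * outer(line_times, tau, `+`)) # nl x ns
    for (ci in seq_len(nc)) {
      data[, ci, ] <- data[, ci, ] + env[, ci] * carrier
    }
  }
  if (noise_sigma > 0) {
    data <- data + array(complex(real = stats::rnorm(nl * nc * ns, 0,
                                                     noise_sigma),
                                 imaginary = stats::rnorm(nl * nc * ns, 0,
                                                          noise_sigma)),
                         dim = c(nl, nc, ns))
  }
  structure(
    list(data = data, params = params, line_times = line_times,
         tones = purrr::map_dfr(tones, ~ tibble::tibble(
           label = .x$label %||% NA_character_,
           frequency_offset = .x$frequency_offset)),
         seed = seed),
    class = "bpt_raw"
  )
}

#' @export
print.bpt_raw <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bpt_raw> %d lines x %d coils x %d samples, BW %.0f kHz, TR %.2f ms\n",
              d[1], d[2], d[3], x$params$bandwidth_hz / 1e3,
              x$params$tr_s * 1e3))
  if (nrow(x$tones)) {
    cat("  tones at offsets (kHz):",
        paste(sprintf("%.2f", x$tones$frequency_offset / 1e3),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract a tone from a raw acquisition
#'
#' Per line and coil, the complex amplitude at `frequency_offset` via exact
#' single-frequency correlation (a matched filter) against the line's
#' samples - no FFT-bin scalloping for off-grid tones. The line start time
#' is the phase reference, so with `demodulate = TRUE` the known
#' line-to-line carrier phase `exp(2 pi i f t_line)` is removed and the
#' values are direct estimates of the injected envelope. The magnitude is
#' invariant to the line start phase either way.
#'
#' @param raw A `bpt_raw`.
#' @param frequency_offset Tone offset (Hz) within the receiver band.
#' @param demodulate Remove the deterministic line-start carrier phase
#'   (default TRUE).
#' @param method "correlation" (default, exact single-frequency matched
#'   filter) or "fft_bin" (nearest FFT bin, as in peak-picking a line
#'   spectrum).
#' @return A tibble of class `bpt_series`: `line`, `line_time_s`, `coil`,
#'   `value` (complex), with the offset in `attr(, "frequency_offset")`.
#' @export
extract_tone <- function(raw, frequency_offset, demodulate = TRUE,
                         method = c("correlation", "fft_bin")) {
  stopifnot(inherits(raw, "bpt_raw"))
  method <- match.arg(method)
  p <- raw$params
  if (abs(frequency_offset) > p$bandwidth_hz / 2) {
    stop("frequency offset outside receiver band")
  }
  if (frequency_offset >= p$image_band_hz[1] &&
      frequency_offset <= p$image_band_hz[2]) {
    warning("frequency offset lies inside the declared image band")
  }
  nl <- p$n_lines; nc <- p$n_coils; ns <- p$n_samples
  if (method == "correlation") {
    tau <- (seq_len(ns) - 1) * p$dwell_time
    kern <- exp(-2i * pi * frequency_offset * tau) / ns
    vals <- matrix(0 + 0i, nl, nc)
    for (ci in seq_len(nc)) {
      vals[, ci] <- coil_lines(raw, ci) %*% kern
    }
  } else {
    fax <- fft_freq_axis(ns, p$bandwidth_hz)
    bin <- which.min(abs(fax - frequency_offset))
    vals <- matrix(0 + 0i, nl, nc)
    for (ci in seq_len(nc)) {
      sp <- t(apply(coil_lines(raw, ci), 1, stats::fft)) / ns
      vals[, ci] <- sp[, bin]
    }
  }
  if (demodulate) {
    vals <- vals * exp(-2i * pi * frequency_offset * raw$line_times)
  }
  out <- tibble::tibble(
    line = rep(seq_len(nl), times = nc),
    line_time_s = rep(raw$line_times, times = nc),
    coil = rep(seq_len(nc), each = nl),
    value = as.vector(vals))
  attr(out, "frequency_offset") <- frequency_offset
  class(out) <- c("bpt_series", class(out))
  out
}

# bpt_series tibble -> n_lines x n_coils complex matrix
series_matrix <- function(series, value = c("complex", "magnitude")) {
  value <- match.arg(value)
  wide <- tidyr::pivot_wider(
    dplyr::select(series, "line", "coil", "value"),
    names_from = "coil", values_from = "value")
  m <- as.matrix(wide[, -1])
  m <- matrix(as.complex(m), nrow(m), ncol(m))
  if (value == "magnitude") Mod(m) else m
}

#' Remove a tone from a raw acquisition
#'
#' Projects the complex exponential at `frequency_offset` (and, if
#' `width_bins > 0`, its `width_bins` FFT-bin neighbours on each side) out
#' of every line and coil, returning a cleaned copy. The MR image band is
#' untouched up to the projection's out-of-band leakage.
#'
#' @param raw A `bpt_raw`.
#' @param frequency_offset Tone offset (Hz).
#' @param width_bins Number of neighbouring FFT bins on each side to project
#'   out as well (default 0: the single exact frequency).
#' @return A `bpt_raw` copy with the tone removed.
#' @export
notch_tone <- function(raw, frequency_offset, width_bins = 0) {
  stopifnot(inherits(raw, "bpt_raw"))
  p <- raw$params
  if (abs(frequency_offset) > p$bandwidth_hz / 2) {
    stop("frequency offset outside receiver band")
  }
  df <- p$bandwidth_hz / p$n_samples
  freqs <- frequency_offset + df * seq(-width_bins, width_bins)
  if (any(freqs >= p$image_band_hz[1] & freqs <= p$image_band_hz[2])) {
    stop("notch width overlaps the image band")
  }
  ns <- p$n_samples
  tau <- (seq_len(ns) - 1) * p$dwell_time
  E <- sapply(freqs, function(f) exp(2i * pi * f * tau))   # ns x k
  # orthonormalise the (nearly orthogonal) exponentials, project out
  qr_e <- qr(E)
  Q <- qr.Q(qr_e)
  out <- raw
  for (ci in seq_len(p$n_coils)) {
    X <- coil_lines(raw, ci)                                # nl x ns
    out$data[, ci, ] <- X - (X %*% Conj(Q)) %*% t(Q)
  }
  out
}

#' Energy of a raw acquisition inside a frequency band
#'
#' Total spectral energy of all lines and coils within `band` (Hz offsets),
#' used to verify that tone notching leaves the image band unchanged.
#'
#' @param raw A `bpt_raw`. @param band `c(low, high)` in Hz.
#' @return A single number.
#' @export
band_energy <- function(raw, band = raw$params$image_band_hz) {
  p <- raw$params
  fax <- fft_freq_axis(p$n_samples, p$bandwidth_hz)
  sel <- fax >= band[1] & fax <= band[2]
  tot <- 0
  for (ci in seq_len(p$n_coils)) {
    sp <- t(apply(coil_lines(raw, ci), 1, stats::fft))
    tot <- tot + sum(Mod(sp[, sel])^2)
  }
  tot
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one coil's lines as an n_lines x n_samples matrix (robust to n_lines == 1)
coil_lines <- function(raw, ci) {
  d <- dim(raw$data)
  matrix(raw$data[, ci, ], d[1], d[3])
}
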