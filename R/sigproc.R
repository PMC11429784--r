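# Low-level signal transforms used throughout the analysis chain:
# percent modulation, zero-group-delay filtering, Savitzky-Golay smoothing,
# relative phase by complex least squares, accelerometer double integration,
# repeat alignment, and linear artifact regression.

#' Percent modulation of multichannel signals
#'
#' Converts each channel to percent modulation about its mean:
#' `(x / mean(x) - 1) * 100`. The output is scale-invariant and has mean 0
#' per channel. Channels whose |mean| falls below `low_mean_threshold`
#' times the median |mean| across channels are flagged `excluded` (their
#' percent modulation would be artificially large); a channel with mean
#' exactly zero is always excluded rather than divided.
#'
#' @param x A numeric vector (one channel) or matrix / data frame
#'   (samples x channels) of real signal magnitudes.
#' @param low_mean_threshold Exclusion threshold relative to the median
#'   channel |mean| (default 0.1).
#' @return A tibble: `sample`, `channel`, `pct_mod`, `excluded`.
#' @examples
#' percent_modulation(c(1, 3))
#' @export
percent_modulation <- function(x, low_mean_threshold = 0.1) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  x <- as.matrix(x)
  mu <- colMeans(x)
  med <- stats::median(abs(mu))
  excluded <- abs(mu) < low_mean_threshold * med | mu == 0
  pct <- sapply(seq_len(ncol(x)), function(j) {
    if (excluded[j]) rep(NA_real_, nrow(x)) else (x[, j] / mu[j] - 1) * 100
  })
  tibble::tibble(
    sample = rep(seq_len(nrow(x)), times = ncol(x)),
    channel = rep(seq_len(ncol(x)), each = nrow(x)),
    pct_mod = as.vector(pct),
    excluded = rep(excluded, each = nrow(x)))
}

#' Modulation range and sensitivity ratio
#'
#' `modulation_range()` returns `max - min` of a percent-modulation trace;
#' `sensitivity_ratio()` is the ratio of two such ranges, the standard way
#' to compare motion sensitivity between transmit frequencies. E.g. ranges
#' of -89..84% against -21..25% give a 3.8x sensitivity increase.
#'
#' @param x Numeric trace (percent modulation), NAs dropped.
#' @return A single number.
#' @export
modulation_range <- function(x) {
  x <- x[is.finite(x)]
  max(x) - min(x)
}

#' @rdname modulation_range
#' @param range_high,range_low Either full traces or length-2 `c(min, max)`
#'   range summaries for the more and less modulated condition.
#' @export
sensitivity_ratio <- function(range_high, range_low) {
  span <- function(r) if (length(r) == 2) r[2] - r[1] else modulation_range(r)
  span(range_high) / span(range_low)
}

# forward-backward filtering with reflection padding at both ends, so the
# composite filter has zero group delay and the squared designed response.
# Each pass is anchored at the signal's initial value (the filter sees the
# deviation from it, and the value itself passes through with the DC gain),
# which removes the zero-state step transient; the padding length scales
# with the slowest pole's time constant.
filtfilt_reflect <- function(filt, x) {
  rmax <- max(Mod(polyroot(rev(filt$a))))
  rmax <- min(max(rmax, 0.5), 1 - 1e-6)
  npad <- min(length(x) - 1, max(50, ceiling(-23 / log(rmax))))
  if (npad >= 1) {
    # reflect about the end points to suppress edge transients
    pre <- 2 * x[1] - rev(x[2:(npad + 1)])
    post <- 2 * x[length(x)] - rev(x[(length(x) - npad):(length(x) - 1)])
    xe <- c(pre, x, post)
  } else {
    xe <- x
  }
  g <- sum(filt$b) / sum(filt$a)
  one_pass <- function(z) {
    as.numeric(signal::filter(filt, z - z[1])) + z[1] * g
  }
  y <- rev(one_pass(rev(one_pass(xe))))
  y[(npad + 1):(npad + length(x))]
}

#' Zero-group-delay Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass forward and backward (with reflection
#' padding), so the net filter has exactly zero group delay and the squared
#' magnitude response of the design. This is the smoothing applied to all
#' extracted tone magnitudes before percent modulation.
#'
#' @param x Real signal vector.
#' @param cutoff_hz -3 dB cutoff of the one-pass design (Hz).
#' @param sample_rate Sampling rate (Hz).
#' @param order Butterworth order of the one-pass design (default 5).
#' @return Filtered vector, same length.
#' @export
zero_phase_lowpass <- function(x, cutoff_hz, sample_rate, order = 5) {
  if (cutoff_hz <= 0 || cutoff_hz >= sample_rate / 2) {
    stop("cutoff must lie in (0, Nyquist)")
  }
  bf <- signal::butter(order, 2 * cutoff_hz / sample_rate, type = "low")
  filtfilt_reflect(bf, x)
}

#' Zero-group-delay Butterworth high-pass filter
#' @inheritParams zero_phase_lowpass
#' @return Filtered vector, same length.
#' @export
zero_phase_highpass <- function(x, cutoff_hz, sample_rate, order = 5) {
  if (cutoff_hz <= 0 || cutoff_hz >= sample_rate / 2) {
    stop("cutoff must lie in (0, Nyquist)")
  }
  bf <- signal::butter(order, 2 * cutoff_hz / sample_rate, type = "high")
  filtfilt_reflect(bf, x)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing; the defaults (window 11,
#' order 4) are the settings used to denoise frame-averaged tone data and
#' registration parameters before PCA.
#'
#' @param x Signal vector or matrix (smoothed per column).
#' @param window Odd window length (samples).
#' @param order Polynomial order, `< window`.
#' @return Smoothed vector/matrix.
#' @export
savgol_smooth <- function(x, window = 11, order = 4) {
  if (window %% 2 != 1 || window < 1) stop("`window` must be odd and >= 1")
  if (order >= window) stop("`order` must be < `window`")
  if (window == 1) return(x)
  if (is.matrix(x)) return(apply(x, 2, savgol_smooth, window = window,
                                 order = order))
  as.numeric(signal::sgolayfilt(x, p = order, n = window))
}

#' Relative phase of coil channels by complex least squares
#'
#' For each coil, estimates the complex scale `c_i(t)` that best maps the
#' reference coil onto it over a sliding window (least squares, i.e. the
#' pseudo-inverse of the reference within the window), and returns the
#' unwrapped phase of that scale. The reference coil yields identically
#' zero phase; a global phase common to all coils cancels. With
#' `reference = "auto"` the highest-energy coil is used.
#'
#' @param series A `bpt_series` tibble (from [extract_tone()]) or a complex
#'   matrix `samples x coils`.
#' @param reference Reference coil index, or "auto".
#' @param window Sliding-window length in samples; `Inf` (default) uses the
#'   full record, giving one scale per coil applied to every sample.
#' @return A tibble: `sample`, `coil`, `phase_rad` (unwrapped).
#' @export
phase_extract <- function(series, reference = "auto", window = Inf) {
  m <- if (is.matrix(series)) series else series_matrix(series)
  n <- nrow(m); nc <- ncol(m)
  if (nc < 2) stop("at least 2 coils are required")
  energy <- colSums(Mod(m)^2)
  ref <- if (identical(reference, "auto")) which.max(energy) else reference
  if (energy[ref] == 0) stop("reference coil has zero energy")
  w <- if (is.infinite(window)) n else min(window, n)
  half <- (w - 1) %/% 2
  phase <- matrix(0, n, nc)
  for (ci in seq_len(nc)) {
    if (ci == ref) next
    if (is.infinite(window)) {
      c_hat <- sum(Conj(m[, ref]) * m[, ci]) / sum(Mod(m[, ref])^2)
      phase[, ci] <- Arg(c_hat)
    } else {
      ph <- numeric(n)
      for (t in seq_len(n)) {
        idx <- max(1, t - half):min(n, t + half)
        ph[t] <- Arg(sum(Conj(m[idx, ref]) * m[idx, ci]) /
                       sum(Mod(m[idx, ref])^2))
      }
      phase[, ci] <- unwrap_phase(ph)
    }
  }
  tibble::tibble(sample = rep(seq_len(n), times = nc),
                 coil = rep(seq_len(nc), each = n),
                 phase_rad = as.vector(phase))
}

unwrap_phase <- function(p) {
  d <- diff(p)
  adj <- cumsum(c(0, -2 * pi * round(d / (2 * pi))))
  p + adj
}

#' Displacement from acceleration by double integration
#'
#' Zero-phase high-pass filters the acceleration (removing gravity and
#' drift), then integrates twice with the trapezoidal rule, de-meaning
#' after each integration to bound drift. This is the displacement
#' ballistocardiogram (dBCG) computation; cutoffs of 2.5 Hz (coil
#' vibration) and 4 Hz (cardiac recoil) are typical.
#'
#' @param accel Acceleration trace (m/s^2 or any consistent unit).
#' @param sample_rate Sampling rate (Hz).
#' @param highpass_cutoff High-pass cutoff (Hz), default 2.5.
#' @param order Butterworth order of the high-pass design.
#' @return Displacement trace (unit = accel unit x s^2).
#' @export
accel_to_displacement <- function(accel, sample_rate, highpass_cutoff = 2.5,
                                  order = 5) {
  a <- zero_phase_highpass(accel, highpass_cutoff, sample_rate, order = order)
  t <- (seq_along(a) - 1) / sample_rate
  v <- pracma::cumtrapz(t, a)
  v <- v - mean(v)
  d <- pracma::cumtrapz(t, as.numeric(v))
  as.numeric(d - mean(d))
}

#' Align repeated motion traces and average them
#'
#' Aligns each repeat to the first by the integer lag maximising their
#' cross-correlation, crops all to the common support, and returns the
#' pointwise mean and standard deviation - the standard presentation of a
#' repeated-motion experiment (mean curve with SD error bars). The reported
#' `lag_i` is the shift such that repeat i resembles the reference advanced
#' by `lag_i` samples: `x_i[t] ~ ref[t + lag_i]`.
#'
#' @param repeats A list of numeric vectors (>= 2) of comparable length.
#' @param max_lag Largest |lag| searched (default: half the shortest repeat).
#' @return A list: `mean` and `sd` vectors over the common support, and the
#'   integer `lags` per repeat.
#' @export
align_and_average <- function(repeats, max_lag = NULL) {
  if (length(repeats) < 2) stop("at least 2 repeats are required")
  ref <- as.numeric(repeats[[1]])
  if (is.null(max_lag)) max_lag <- min(lengths(repeats)) %/% 2
  best_lag <- function(x) {
    x <- as.numeric(x)
    cors <- vapply(-max_lag:max_lag, function(l) {
      # x[t] ~ ref[t + l]: overlap in x-index space
      i_lo <- max(1, 1 - l)
      i_hi <- min(length(x), length(ref) - l)
      if (i_hi - i_lo < 8) return(-Inf)
      xs <- x[i_lo:i_hi]
      rs <- ref[(i_lo + l):(i_hi + l)]
      if (stats::sd(xs) == 0 || stats::sd(rs) == 0) return(-Inf)
      stats::cor(xs, rs)
    }, numeric(1))
    (-max_lag:max_lag)[which.max(cors)]
  }
  lags <- purrr::map_int(repeats, ~ as.integer(best_lag(.x)))
  # crop to the reference-index range valid for every repeat:
  # x_i[r - lag_i] = ref[r]
  r_min <- max(1 + lags, 1)
  r_max <- min(lengths(repeats) + lags)
  if (r_max < r_min) stop("no common support after alignment")
  aligned <- purrr::map2(repeats, lags, function(x, l) {
    x[(r_min - l):(r_max - l)]
  })
  m <- do.call(cbind, aligned)
  list(mean = rowMeans(m),
       sd = apply(m, 1, stats::sd),
       lags = lags)
}

#' Remove a linearly coupled artifact from a trace
#'
#' Ordinary least-squares projection of a trace onto supplied regressors
#' (plus an intercept); the residual is the corrected trace. Used to
#' subtract gradient-vibration artifacts per coil with the gradient
#' activity surrogate as the regressor. Rank-deficient regressor sets fall
#' back to the pseudo-inverse with a warning.
#'
#' @param trace Numeric vector.
#' @param regressors Numeric vector or matrix (same number of samples), or
#'   NULL for intercept-only (pure de-meaning).
#' @return A list: `corrected` residual trace, `coefficients` (including
#'   the intercept), `fitted`.
#' @export
artifact_linear_correct <- function(trace, regressors = NULL) {
  n <- length(trace)
  X <- if (is.null(regressors)) matrix(1, n, 1) else
    cbind(1, as.matrix(regressors))
  if (nrow(X) != n) stop("regressors must match the trace length")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("rank-deficient regressors; using pseudo-inverse")
    beta <- as.numeric(pracma::pinv(X) %*% trace)
  } else {
    beta <- as.numeric(qr.coef(qx, trace))
  }
  fitted <- as.numeric(X %*% beta)
  list(corrected = trace - fitted, coefficients = beta, fitted = fitted)
}
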