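# Independent oracles used by the tests; deliberately written with different
# algorithms from the implementation they check.

# m-th positive root of J_n (or of J'_n) by plain bisection on a fine grid
bisect_bessel_root <- function(n, m, derivative = FALSE) {
  f <- if (derivative) {
    if (n == 0) function(x) -besselJ(x, 1) else
      function(x) (besselJ(x, n - 1) - besselJ(x, n + 1)) / 2
  } else {
    function(x) besselJ(x, n)
  }
  xs <- seq(1e-8, n + (m + 3) * pi + 5, by = 0.01)
  fx <- f(xs)
  idx <- which(fx[-1] * fx[-length(fx)] < 0)[m]
  lo <- xs[idx]; hi <- xs[idx + 1]
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# dBm of the f2-f1 spectral line after y = a1 x + a2 x^2, measured on a
# DFT-aligned time grid (both tones at equal power p_dbm)
oracle_imd_dbm <- function(p_dbm, preamp, f1 = 2.4e9, f2 = 2.5278e9,
                           fs = 20e9, n = 1e5) {
  t <- (0:(n - 1)) / fs
  A <- sqrt(2 * 50 * 10^(p_dbm / 10) * 1e-3)
  x <- A * cos(2 * pi * f1 * t) + A * cos(2 * pi * f2 * t)
  y <- preamp$a1 * x + preamp$a2 * x^2
  sp <- stats::fft(y) / n
  f <- (0:(n - 1)) * fs / n
  amp <- 2 * Mod(sp[which.min(abs(f - (f2 - f1)))])
  10 * log10(amp^2 / (2 * 50) / 1e-3)
}

# complex amplitude of the f2-f1 line for complex tone envelopes phi1, phi2
oracle_beat_line <- function(phi1, phi2, a2, f1 = 2.0e6, f2 = 2.5e6,
                             fs = 20e6, n = 4e4) {
  t <- (0:(n - 1)) / fs
  x <- Mod(phi1) * cos(2 * pi * f1 * t + Arg(phi1)) +
    Mod(phi2) * cos(2 * pi * f2 * t + Arg(phi2))
  y <- a2 * x^2
  sp <- stats::fft(y) / n
  f <- (0:(n - 1)) * fs / n
  2 * sp[which.min(abs(f - (f2 - f1)))]
}

# exhaustive max-margin separator for small 2-D separable sets: the optimal
# plane is supported by one point of each class (perpendicular bisector) or
# by two of one class and one of the other
brute_force_margin <- function(X, y) {
  stopifnot(ncol(X) == 2, all(y %in% c(-1, 1)))
  A <- X[y == -1, , drop = FALSE]
  B <- X[y == 1, , drop = FALSE]
  best <- -Inf
  eval_plane <- function(w, b) {
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(-Inf)
    d <- (X %*% w + b) / nw
    if (all(sign(d) == y)) min(abs(d)) else -Inf
  }
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    w <- B[j, ] - A[i, ]
    b <- -sum(w * (A[i, ] + B[j, ]) / 2)
    best <- max(best, eval_plane(w, b))
  }
  pair_planes <- function(P, Q) {
    # two support points in P, one in Q: plane parallel to the P-P edge
    if (nrow(P) < 2) return(invisible(NULL))
    for (i in seq_len(nrow(P) - 1)) for (j in (i + 1):nrow(P)) {
      e <- P[j, ] - P[i, ]
      if (sum(e^2) == 0) next
      for (k in seq_len(nrow(Q))) {
        v <- Q[k, ] - P[i, ]
        w <- v - e * sum(v * e) / sum(e^2)   # normal to the edge
        mid <- P[i, ] + w / 2
        b <- -sum(w * mid)
        best <<- max(best, eval_plane(w, b))
      }
    }
  }
  pair_planes(A, B)
  pair_planes(B, A)
  best
}

# damping ratio from the logarithmic decrement of successive ring peaks
log_decrement_zeta <- function(x) {
  pk <- pracma::findpeaks(x, minpeakheight = 0.05 * max(x))
  h <- pk[, 1]
  delta <- mean(diff(-log(h)))
  delta / sqrt(4 * pi^2 + delta^2)
}

# small fast scenario configs shared across test files
small_sweep_config <- function(seed = 7, ...) {
  scenario_config("translation_sweep", seed = seed,
                  pair = c(2400e6, 2527.8e6), n_offsets = 15,
                  n_quad_max = 16, rel_tol = 1e-3, n_lines = 120,
                  n_samples = 64, ...)
}

cached_small_sweep <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- gen_translation_sweep(small_sweep_config())
    cache
  }
})
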