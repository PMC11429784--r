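# Signal transforms: percent modulation, zero-phase filtering, smoothing,
# relative phase, double integration, alignment and artifact regression.

test_that("percent modulation matches hand values and is scale invariant", {
  pm <- percent_modulation(c(1, 3))
  expect_equal(pm$pct_mod, c(-50, 50))
  expect_equal(percent_modulation(rep(4, 10))$pct_mod, rep(0, 10))
  x <- stats::runif(50, 1, 2)
  expect_equal(percent_modulation(x)$pct_mod,
               percent_modulation(7.3 * x)$pct_mod, tolerance = 1e-12)
  # output mean is zero per included channel
  expect_lt(abs(mean(percent_modulation(x)$pct_mod)), 1e-10)
})

test_that("low-mean and zero-mean channels are excluded, not divided", {
  x <- cbind(a = rep(10, 20), b = rep(10, 20), c = rep(0.001, 20))
  pm <- percent_modulation(x)
  expect_equal(unique(pm$excluded[pm$channel == 3]), TRUE)
  expect_equal(unique(pm$excluded[pm$channel == 1]), FALSE)
  z <- cbind(rep(1, 10), sin(seq_len(10)) - mean(sin(seq_len(10))))
  pmz <- percent_modulation(z)
  expect_true(all(pmz$excluded[pmz$channel == 2]))
  expect_true(all(is.na(pmz$pct_mod[pmz$channel == 2])))
})

test_that("modulation range ratio reproduces the printed sensitivity factor", {
  # simulated ranges: -21..25 % at the pilot frequency, -89..84 % at the beat
  expect_equal(round(sensitivity_ratio(c(-89, 84), c(-21, 25)), 1), 3.8)
  expect_equal(modulation_range(c(-21, 5, 25)), 46)
})

test_that("zero-phase low-pass has unit DC gain, symmetric impulse, squared response", {
  fs <- 100
  x <- rep(2.5, 400)
  expect_equal(zero_phase_lowpass(x, 2, fs), x, tolerance = 1e-9)

  # impulse response symmetric about the impulse
  imp <- numeric(801); imp[401] <- 1
  y <- zero_phase_lowpass(imp, 5, fs)
  expect_equal(y[401 + 1:200], y[401 - 1:200], tolerance = 1e-9)

  # sinusoid far above cutoff attenuated by the squared designed response
  ord <- 2
  f_test <- 20; cutoff <- 2
  t <- (0:9999) / fs
  s <- sin(2 * pi * f_test * t)
  yf <- zero_phase_lowpass(s, cutoff, fs, order = ord)
  bf <- signal::butter(ord, 2 * cutoff / fs, type = "low")
  # designed response evaluated directly at the test frequency
  w <- 2 * pi * f_test / fs
  Hf <- function(cf) sum(cf * exp(-1i * w * (seq_along(cf) - 1)))
  expected_gain <- Mod(Hf(bf$b) / Hf(bf$a))^2
  mid <- 3000:7000
  measured_gain <- sqrt(mean(yf[mid]^2) / mean(s[mid]^2))
  expect_equal(measured_gain, expected_gain, tolerance = 0.02)

  # applying the filter twice equals the squared one-pass response per tone
  freqs <- c(1, 3, 6)
  amp_of <- function(sig, f) {
    b <- stats::lm(sig[mid] ~ sin(2 * pi * f * t[mid]) +
                     cos(2 * pi * f * t[mid]))
    sqrt(sum(stats::coef(b)[2:3]^2))
  }
  for (f in freqs) {
    s1 <- sin(2 * pi * f * t)
    y1 <- zero_phase_lowpass(s1, 4, fs)
    y2 <- zero_phase_lowpass(y1, 4, fs)
    g1 <- amp_of(y1, f)
    g2 <- amp_of(y2, f)
    expect_equal(g2, g1^2, tolerance = 1e-6)
  }
  expect_error(zero_phase_lowpass(x, 60, fs), "Nyquist")
})

test_that("Savitzky-Golay smoothing is a polynomial projection", {
  t <- seq(-1, 1, length.out = 101)
  p4 <- 1 + t - 2 * t^2 + 0.5 * t^4
  sm <- savgol_smooth(p4, window = 11, order = 4)
  expect_equal(sm[6:96], p4[6:96], tolerance = 1e-10)
  expect_identical(savgol_smooth(p4, window = 1, order = 0), p4)
  expect_error(savgol_smooth(p4, window = 10, order = 4), "odd")
  expect_error(savgol_smooth(p4, window = 11, order = 11), "order")

  # white-noise variance reduced by the kernel norm ||h||^2
  imp <- numeric(101); imp[51] <- 1
  h <- savgol_smooth(imp, 11, 4)
  set.seed(1)
  noise <- stats::rnorm(20000)
  ratio <- stats::var(savgol_smooth(noise, 11, 4)) / stats::var(noise)
  expect_equal(ratio, sum(h^2), tolerance = 0.05)
})

test_that("relative phase extraction recovers a known slow phase", {
  n <- 400
  t <- seq_len(n)
  ref <- exp(1i * 0.3 * sin(2 * pi * t / 150)) * (2 + 0.1 * cos(t / 50))
  theta <- 0.8 * sin(2 * pi * t / 200)
  m <- cbind(ref, ref * exp(1i * theta))

  # identical coils: zero phase everywhere
  ph0 <- phase_extract(cbind(ref, ref), window = 21)
  expect_lt(max(abs(ph0$phase_rad)), 1e-12)

  ph <- phase_extract(m, reference = 1, window = 3)
  got <- ph$phase_rad[ph$coil == 2]
  expect_lt(max(abs(got - theta)[10:(n - 10)]), 1e-3)

  # a common global phase cancels
  g <- exp(1i * 0.5 * cos(t / 30))
  ph2 <- phase_extract(m * cbind(g, g), reference = 1, window = 3)
  expect_equal(ph2$phase_rad[ph2$coil == 2], got, tolerance = 1e-9)

  expect_error(phase_extract(cbind(ref * 0, ref), reference = 1),
               "zero energy")
  expect_error(phase_extract(matrix(ref, ncol = 1)), "2 coils")
})

test_that("double integration of acceleration recovers displacement", {
  fs <- 500
  t <- (0:(10 * fs)) / fs
  w <- 2 * pi * 10
  a <- -w^2 * sin(w * t)
  d <- accel_to_displacement(a, fs, highpass_cutoff = 2.5)
  mid <- (2 * fs):(8 * fs)
  amp <- sqrt(2 * mean(d[mid]^2))
  expect_equal(amp, 1, tolerance = 0.02)

  # constant acceleration is rejected by the high-pass
  d0 <- accel_to_displacement(rep(3, length(t)), fs)
  expect_lt(max(abs(d0)), 1e-6)

  # linearity
  expect_equal(accel_to_displacement(4 * a, fs), 4 * d, tolerance = 1e-9)
})

test_that("repeat alignment recovers lags and averages correctly", {
  set.seed(2)
  base <- sin(seq(0, 6 * pi, length.out = 300)) +
    0.3 * sin(seq(0, 26 * pi, length.out = 300))
  five <- replicate(5, base, simplify = FALSE)
  out <- align_and_average(five)
  expect_equal(out$sd, rep(0, length(out$mean)))
  expect_equal(out$mean, base)

  # known integer shifts are recovered exactly
  lags_true <- c(0, 4, -7, 11)
  shifted <- lapply(lags_true, function(l) {
    i <- seq_len(250) + 25 + l
    base[i]
  })
  out2 <- align_and_average(shifted)
  expect_equal(out2$lags - out2$lags[1], lags_true)
  expect_lt(max(out2$sd), 1e-12)

  # independent white noise: mean SD across repeats approaches sigma
  sigma <- 0.7
  reps <- replicate(16, stats::rnorm(1000, 0, sigma), simplify = FALSE)
  out3 <- align_and_average(reps, max_lag = 10)
  expect_equal(mean(out3$sd), sigma, tolerance = 0.1)

  expect_error(align_and_average(list(base)), "at least 2")
})

test_that("linear artifact correction is exact OLS", {
  set.seed(4)
  n <- 500
  motion <- sin(2 * pi * (1:n) / 120)
  artifact <- stats::rnorm(n)
  # orthogonalise the artifact against the intercept and the motion so the
  # planted coefficient is recovered exactly
  artifact <- unname(stats::resid(stats::lm(artifact ~ motion)))
  trace <- motion + 0.7 * artifact
  fit <- artifact_linear_correct(trace, artifact)
  expect_gt(stats::cor(fit$corrected, motion), 0.999)
  expect_equal(fit$coefficients[2], 0.7, tolerance = 1e-10)

  # intercept-only regressors de-mean the input
  fit0 <- artifact_linear_correct(trace)
  expect_equal(fit0$corrected, trace - mean(trace), tolerance = 1e-12)

  expect_warning(artifact_linear_correct(trace, cbind(artifact, artifact)),
                 "rank")
  expect_error(artifact_linear_correct(trace, artifact[1:10]), "length")
})
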