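# Tone embedding into raw lines and matched-filter extraction.

params_small <- function(...) {
  acq_params(n_lines = 64, n_coils = 2, n_samples = 128, ...)
}

test_that("synthesis is additive, deterministic, and guards the image band", {
  p <- params_small()
  # no tones, no noise: data is the MR content exactly, identical per line
  raw <- synthesize_raw(p, mr_amplitude = 1, seed = 5)
  expect_equal(raw$data[1, 1, ], raw$data[40, 1, ])
  expect_equal(raw$data[1, 1, ], raw$data[1, 2, ])

  # pure on-bin tone: single nonzero spectral line per line spectrum
  df <- p$bandwidth_hz / p$n_samples
  f0 <- 45 * df
  raw2 <- synthesize_raw(p, tones = list(list(label = "T",
                                              frequency_offset = f0,
                                              envelope = 1)))
  sp <- Mod(stats::fft(raw2$data[1, 1, ]))
  expect_equal(which(sp > 1e-6), 46)

  # determinism: identical arrays for the same seed
  mk <- function() synthesize_raw(p, tones = list(list(
    label = "T", frequency_offset = f0, envelope = 1)),
    mr_amplitude = 0.5, noise_sigma = 0.1, seed = 11)
  expect_identical(mk()$data, mk()$data)

  expect_error(synthesize_raw(p, tones = list(list(
    label = "bad", frequency_offset = 0, envelope = 1))), "image band")
  expect_error(synthesize_raw(p, tones = list(list(
    label = "bad", frequency_offset = 2 * p$bandwidth_hz, envelope = 1))),
    "receiver band")
})

test_that("noiseless round trip recovers injected envelopes to 1e-9", {
  p <- params_small()
  set.seed(8)
  env <- matrix(complex(real = stats::rnorm(p$n_lines * p$n_coils, 2),
                        imaginary = stats::rnorm(p$n_lines * p$n_coils)),
                p$n_lines, p$n_coils)
  f0 <- 87.3e3   # deliberately off any FFT bin
  raw <- synthesize_raw(p, tones = list(list(label = "T",
                                             frequency_offset = f0,
                                             envelope = env)))
  ser <- extract_tone(raw, f0)
  got <- beatpilot:::series_matrix(ser)
  expect_lt(max(Mod(got - env)) / max(Mod(env)), 1e-9)

  # fft_bin mode suffers scalloping but tracks magnitude within a few dB
  ser_bin <- extract_tone(raw, f0, method = "fft_bin")
  got_bin <- beatpilot:::series_matrix(ser_bin)
  expect_gt(stats::cor(as.vector(Mod(got_bin)), as.vector(Mod(env))), 0.99)
})

test_that("a slow amplitude modulation is recovered to within 1%", {
  # 1 Hz sinusoidal envelope, 10% depth, 4.4 ms line spacing
  p <- acq_params(n_lines = 512, n_coils = 1, n_samples = 64, tr_s = 4.4e-3)
  tl <- (seq_len(p$n_lines) - 1) * p$tr_s
  env <- matrix(1 + 0.10 * sin(2 * pi * 1 * tl), ncol = 1)
  raw <- synthesize_raw(p, tones = list(list(label = "T",
                                             frequency_offset = 60e3,
                                             envelope = env)))
  got <- Mod(beatpilot:::series_matrix(extract_tone(raw, 60e3)))
  depth <- (max(got) - min(got)) / (max(got) + min(got))
  expect_equal(depth, 0.10, tolerance = 0.01)
})

test_that("cross-talk between two tones equals the correlation-kernel leakage", {
  p <- params_small()
  df <- p$bandwidth_hz / p$n_samples
  fa <- 40 * df          # on-bin
  fb <- fa + 12.5 * df   # 12.5 bins away, off-bin
  raw_b <- synthesize_raw(p, tones = list(list(label = "B",
                                               frequency_offset = fb,
                                               envelope = 2)))
  leak_measured <- max(Mod(beatpilot:::series_matrix(
    extract_tone(raw_b, fa)))) / 2
  tau <- (seq_len(p$n_samples) - 1) * p$dwell_time
  leak_kernel <- Mod(sum(exp(2i * pi * (fb - fa) * tau))) / p$n_samples
  expect_equal(leak_measured, leak_kernel, tolerance = 1e-9)

  # integer-bin separation: kernels orthogonal, cross-talk at machine zero
  raw_c <- synthesize_raw(p, tones = list(list(label = "C",
                                               frequency_offset = 52 * df,
                                               envelope = 2)))
  leak_int <- max(Mod(beatpilot:::series_matrix(
    extract_tone(raw_c, fa)))) / 2
  expect_lt(leak_int, 1e-3)   # < -60 dB
})

test_that("extraction is linear and behaves under noise like averaging", {
  p <- params_small()
  f0 <- 70e3
  env1 <- matrix(1 + 0i, p$n_lines, p$n_coils)
  env2 <- matrix(0.5 - 0.2i, p$n_lines, p$n_coils)
  r1 <- synthesize_raw(p, tones = list(list(label = "T",
                                            frequency_offset = f0,
                                            envelope = env1)))
  r2 <- synthesize_raw(p, tones = list(list(label = "T",
                                            frequency_offset = f0,
                                            envelope = env2)))
  r12 <- synthesize_raw(p, tones = list(list(label = "T",
                                             frequency_offset = f0,
                                             envelope = env1 + env2)))
  m1 <- beatpilot:::series_matrix(extract_tone(r1, f0))
  m2 <- beatpilot:::series_matrix(extract_tone(r2, f0))
  m12 <- beatpilot:::series_matrix(extract_tone(r12, f0))
  expect_equal(m12, m1 + m2, tolerance = 1e-12)

  # noisy case: estimation error stays within 6 sigma / sqrt(n_samples)
  sigma <- 0.5
  pn <- acq_params(n_lines = 1000, n_coils = 1, n_samples = 128)
  rn <- synthesize_raw(pn, tones = list(list(label = "T",
                                             frequency_offset = f0,
                                             envelope = 1)),
                       noise_sigma = sigma, seed = 21)
  err <- Mod(beatpilot:::series_matrix(extract_tone(rn, f0)) - 1)
  expect_lt(max(err), 6 * sigma / sqrt(pn$n_samples))
  expect_lt(abs(mean(err^2) - 2 * sigma^2 / pn$n_samples),
            0.2 * 2 * sigma^2 / pn$n_samples)
})

test_that("notching removes a tone without touching the image band", {
  p <- params_small()
  # tone-free data pass through a bin-aligned notch unchanged: the notch
  # kernel is orthogonal to every occupied image-band bin
  df <- p$bandwidth_hz / p$n_samples
  raw0 <- synthesize_raw(p, mr_amplitude = 1, seed = 9)
  out0 <- notch_tone(raw0, 56 * df)
  expect_lt(max(Mod(out0$data - raw0$data)) / max(Mod(raw0$data)), 1e-9)

  # synthesize -> notch -> extract: residual < 1e-6 of injected (off-grid)
  f0 <- 87.3e3
  raw <- synthesize_raw(p, tones = list(list(label = "T",
                                             frequency_offset = f0,
                                             envelope = 3)),
                        seed = 9)
  cleaned <- notch_tone(raw, f0)
  resid <- max(Mod(beatpilot:::series_matrix(extract_tone(cleaned, f0))))
  expect_lt(resid, 1e-6 * 3)

  # bin-aligned tone on top of MR content: the notch kernel is orthogonal to
  # every image-band bin, so in-band energy is untouched
  fb <- 56 * df
  raw2 <- synthesize_raw(p, tones = list(list(label = "T",
                                              frequency_offset = fb,
                                              envelope = 3)),
                         mr_amplitude = 1, seed = 9)
  cleaned2 <- notch_tone(raw2, fb)
  e_before <- band_energy(raw2)
  e_after <- band_energy(cleaned2)
  expect_lt(abs(e_after - e_before) / e_before, 1e-6)
  # and the tone itself is gone
  expect_lt(max(Mod(beatpilot:::series_matrix(extract_tone(cleaned2, fb)))),
            1e-9)

  expect_error(notch_tone(raw, 55e3, width_bins = 5), "image band")
})
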