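# End-to-end scenario generators.

test_that("translation sweep: zero travel gives flat envelopes", {
  sc0 <- gen_translation_sweep(
    scenario_config("translation_sweep", seed = 3,
                    pair = c(2400e6, 2527.8e6), travel = 0, n_offsets = 3,
                    n_quad_max = 16, rel_tol = 1e-3, n_lines = 40,
                    n_samples = 64))
  pm <- percent_modulation(Mod(sc0$envelopes$bpt))
  expect_lt(max(abs(pm$pct_mod)), 1e-9)
})

test_that("translation sweep: beat channels are more modulated, structured and coil-diverse than the pilot", {
  sc <- cached_small_sweep()
  pt <- dplyr::filter(sc$sweep, .data$frequency_hz == 127.8e6)
  bpt <- sweep_bpt_product(sc$sweep, 2400e6, 2527.8e6)

  norm_env <- function(x) x / mean(x)
  per_coil <- function(tbl, col) {
    lapply(split(tbl, tbl$coil_id), function(d) norm_env(Mod(d[[col]])))
  }
  pt_env <- per_coil(pt, "flux")
  bpt_env <- per_coil(bpt, "bpt_rx")

  range_of <- function(env) max(env) * 100 - min(env) * 100
  expect_gt(min(sapply(bpt_env, range_of)), max(sapply(pt_env, range_of)))

  # adjacent-coil shape difference (normalised RMS) larger for the beat tone
  rms_diff <- function(envs) {
    mean(sapply(seq_len(length(envs) - 1), function(i) {
      sqrt(mean((envs[[i]] - envs[[i + 1]])^2))
    }))
  }
  expect_gt(rms_diff(bpt_env), rms_diff(pt_env))

  # same seed reproduces identical raw data and flux
  sc2 <- gen_translation_sweep(small_sweep_config())
  expect_identical(sc2$raw$data, sc$raw$data)
  expect_identical(sc2$sweep$flux, sc$sweep$flux)
  expect_match(sc$hash, "^[0-9a-f]{8}$")
})

test_that("vibration events ring down with the configured damping", {
  cfg <- scenario_config("vibration", seed = 5, zeta = 0.03,
                         accel_noise = 0, noise_sigma = 0)
  sc <- gen_vibration_event(cfg)
  fs <- 1 / diff(sc$displacement$time_s[1:2])

  # extract the tone, isolate the first ring-down, estimate the damping
  ser <- extract_tone(sc$raw, sc$raw$tones$frequency_offset[1])
  env <- rowMeans(beatpilot:::series_matrix(ser, "magnitude"))
  t <- sc$displacement$time_s
  seg <- t > sc$events[1] + 0.05 & t < sc$events[1] + 3
  ring <- env[seg] - mean(env[t > sc$events[1] + 3 & t < sc$events[2] - 0.2])
  zeta_hat <- log_decrement_zeta(ring / max(ring))
  expect_equal(zeta_hat, 0.03, tolerance = 0.05)

  # the second event is more heavily damped
  seg2 <- t > sc$events[2] + 0.05 & t < sc$events[2] + 3
  ring2 <- -(env[seg2] - mean(env[t > sc$events[2] + 3]))
  zeta2_hat <- log_decrement_zeta(ring2 / max(ring2))
  expect_gt(zeta2_hat, zeta_hat)

  # infinite-damping limit: no ringing, pure step
  sc_inf <- gen_vibration_event(
    scenario_config("vibration", seed = 5, zeta = 50, zeta2 = 50,
                    accel_noise = 0, noise_sigma = 0))
  d <- sc_inf$displacement
  after <- d$time_s > sc_inf$events[1] + 0.1 & d$time_s < sc_inf$events[2] - 0.2
  expect_lt(max(abs(d$value[after] - 10)), 0.01 * 10)

  expect_error(gen_vibration_event(scenario_config("vibration", zeta = -1)),
               "positive")
})

test_that("synthetic accelerometer double-integrates to the tone envelope", {
  cfg <- scenario_config("vibration", seed = 6, accel_noise = 0.01,
                         noise_sigma = 0.001)
  sc <- gen_vibration_event(cfg)
  fs <- 1 / diff(sc$accel$time_s[1:2])
  disp_hat <- accel_to_displacement(sc$accel$value, fs,
                                    highpass_cutoff = 2.5)
  ser <- extract_tone(sc$raw, sc$raw$tones$frequency_offset[1])
  env <- rowMeans(beatpilot:::series_matrix(ser, "magnitude"))
  envf <- zero_phase_highpass(zero_phase_lowpass(env, 25, fs), 2.5, fs)
  expect_gt(stats::cor(envf, disp_hat), 0.95)
})

test_that("physiological generator separates mechanisms by frequency and stiffness", {
  base <- list(seed = 8, duration_s = 30, hr_bpm = 72, noise_sigma = 0)

  # high transmit frequency, stiff coil: sharp multi-peak dBCG each beat
  sc_hi <- gen_physio(do.call(scenario_config,
                              c(list(kind = "physio",
                                     pair = c(2400e6, 2527.8e6)), base)))
  card <- sc_hi$traces$value[sc_hi$traces$name == "cardiac"]
  tt <- sc_hi$traces$time_s[sc_hi$traces$name == "cardiac"]
  fs <- 1 / diff(tt[1:2])
  pk <- pracma::findpeaks(card, minpeakheight = 0.6 * max(card))
  beat_gap <- stats::median(diff(sort(pk[, 2]))) / fs
  hr_hat <- 60 / beat_gap
  expect_lt(abs(hr_hat - 72), 1)

  # peaks per beat > 1 at high frequency (dBCG), = 1 at low frequency
  peaks_per_beat <- function(sc) {
    card <- sc$traces$value[sc$traces$name == "cardiac"]
    one_beat <- abs(card[tt >= 5 & tt < 5 + 60 / 72])
    beatpilot:::count_peaks(one_beat,
                            min_prominence = 0.1 * diff(range(one_beat)))
  }
  expect_gt(peaks_per_beat(sc_hi), 1)
  sc_lo <- gen_physio(do.call(scenario_config,
                              c(list(kind = "physio",
                                     pair = c(400e6, 527.8e6)), base)))
  expect_equal(peaks_per_beat(sc_lo), 1)

  # stiffness 0 reverts high-frequency channels to the blood-volume shape
  sc_soft <- gen_physio(do.call(scenario_config,
                                c(list(kind = "physio",
                                       pair = c(2400e6, 2527.8e6),
                                       stiffness = 0), base)))
  expect_equal(peaks_per_beat(sc_soft), 1)

  # zero cardiac amplitude: cardiac-band power falls to the noise floor
  sc_resp <- gen_physio(do.call(scenario_config,
                                c(list(kind = "physio",
                                       pair = c(2400e6, 2527.8e6),
                                       cardiac_amplitude = 0), base)))
  band_power <- function(sc, lo, hi) {
    ser <- extract_tone(sc$raw, sc$raw$tones$frequency_offset[1])
    env <- rowMeans(beatpilot:::series_matrix(ser, "magnitude"))
    n <- length(env)
    hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    sp <- Mod(stats::fft((env - mean(env)) * hann))^2
    f <- (seq_len(n) - 1) * fs / n
    sum(sp[f >= lo & f <= hi & f <= fs / 2])
  }
  expect_lt(band_power(sc_resp, 0.9, 5) / band_power(sc_hi, 0.9, 5), 1e-4)

  expect_error(gen_physio(scenario_config("physio", pair = c(4e8, 5.278e8),
                                          hr_bpm = -10)), "positive")
})

test_that("MIMO head-motion pipeline recovers registration components", {
  sc <- gen_mimo_head(scenario_config("mimo_head", seed = 9))
  expect_equal(dim(sc$calibration$bpt$matrix), c(115, 44))
  expect_equal(dim(sc$inference$bpt$matrix), c(50, 44))

  prep <- function(fr) {
    f <- fr; f$matrix <- savgol_smooth(fr$matrix); f
  }
  cal <- prep(sc$calibration$bpt)
  model <- pca_fit(cal, n_pc = 3)
  reg_pcs <- pca_fit(savgol_smooth(as.matrix(sc$truth$calibration)),
                     n_pc = 3)$scores

  # regression to each registration PC with both antennas: r >= 0.95
  r_both <- sapply(1:3, function(k) {
    regress_multicoil(cal, reg_pcs[, k])$pearson_r
  })
  expect_true(all(abs(r_both) >= 0.95))

  # in-sample nested-model property: both antennas >= each single antenna
  blocks <- mimo_split(cal)
  for (k in 1:3) {
    for (blk in blocks) {
      expect_gte(abs(regress_multicoil(cal, reg_pcs[, k])$pearson_r) + 1e-12,
                 abs(regress_multicoil(blk, reg_pcs[, k])$pearson_r))
    }
  }

  # zero motion in the inference scan gives constant frames
  sc0 <- gen_mimo_head(scenario_config("mimo_head", seed = 9,
                                       inf_scale = 0, bpt_noise = 0,
                                       pt_noise = 0))
  expect_lt(stats::sd(sc0$inference$bpt$matrix), 1e-12)

  expect_error(gen_mimo_head(scenario_config("mimo_head", box_mm = -1)),
               "positive")
})

test_that("nod and shake trajectories form crossing one-dimensional paths in PC space", {
  sc <- gen_mimo_head(scenario_config("mimo_head", seed = 9))
  prep <- function(fr) { f <- fr; f$matrix <- savgol_smooth(fr$matrix); f }
  model <- pca_fit(prep(sc$calibration$bpt), n_pc = 3)
  scores <- pca_project(model, prep(sc$inference$bpt))
  lab <- sc$inference$bpt$labels

  # each motion is nearly one-dimensional in score space
  for (l in unique(lab)) {
    p <- pca_fit(scores[lab == l, ], n_pc = 1)
    expect_gt(p$explained[1], 0.9)
  }
  # the two paths are distinct: their dominant directions differ clearly
  d1 <- pca_fit(scores[lab == "nod", ], n_pc = 1)$components
  d2 <- pca_fit(scores[lab == "shake", ], n_pc = 1)$components
  expect_lt(abs(sum(d1 * d2)), 0.8)
  # and they intersect near the shared rest pose: the closest pair of
  # points across paths is much closer than the typical path extent
  dmat <- as.matrix(stats::dist(scores))
  cross <- dmat[lab == "nod", lab == "shake"]
  expect_lt(min(cross), 0.2 * max(dmat))
})
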