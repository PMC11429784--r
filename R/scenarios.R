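# Seeded synthetic experiment generators. Each wires the bore model, the
# nonlinear-reception model and the k-space embedding together to emulate one
# experiment class: coil translation sweeps, coil vibration events,
# respiratory/cardiac physiology, and a two-antenna head-motion
# calibration/inference pair. Generators are deterministic given the seed.

#' The canonical tone frequency set (Hz)
#'
#' Pilot tone at 127.8 MHz plus the beat tone pairs whose difference is
#' 127.8 MHz, spanning 400 MHz to 2.5278 GHz.
#' @export
bpt_frequency_set <- function() {
  list(pt = 127.8e6,
       pairs = list(c(400e6, 527.8e6), c(800e6, 927.8e6),
                    c(1200e6, 1327.8e6), c(1800e6, 1927.8e6),
                    c(2400e6, 2527.8e6)))
}

#' Build a scenario configuration
#'
#' @param kind One of "translation_sweep", "vibration", "physio",
#'   "mimo_head".
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @param ... Kind-specific parameter overrides (see the `gen_*` functions
#'   for the parameters and their defaults).
#' @return A `bpt_scenario_config` list.
#' @export
scenario_config <- function(kind = c("translation_sweep", "vibration",
                                     "physio", "mimo_head"),
                            seed = 1, ...) {
  kind <- match.arg(kind)
  structure(c(list(kind = kind, seed = as.integer(seed)), list(...)),
            class = "bpt_scenario_config")
}

# polynomial rolling hash of the deparsed config, for provenance metadata
config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) {
    h <- (h * 131 + b) %% 2147483629
  }
  sprintf("%08x", h)
}

cfg_get <- function(config, name, default) config[[name]] %||% default

# complex linear interpolation of a flux series onto query offsets
interp_complex <- function(x, y, xout) {
  if (length(unique(x)) == 1) return(rep(y[1], length(xout)))
  complex(real = stats::approx(x, Re(y), xout, rule = 2)$y,
          imaginary = stats::approx(x, Im(y), xout, rule = 2)$y)
}

# triangular back-and-forth motion over [0, travel], n_repeats periods
triangle_motion <- function(t, period, travel) {
  ph <- (t %% period) / period
  travel * (1 - abs(2 * ph - 1))
}

#' Generate a coil translation-sweep experiment
#'
#' A 3-coil posterior array is swept 10 cm along the bore axis through the
#' standing-wave field of a pilot tone (127.8 MHz, below the bore cutoff)
#' and a beat-tone pair (2400/2527.8 MHz by default, above cutoff). The
#' per-coil pilot flux and beat flux-product envelopes are embedded as
#' tones in a raw acquisition; the motion repeats for five periods.
#'
#' Key config fields (with defaults): `pair` (`c(2400e6, 2527.8e6)`),
#' `pt_frequency` (127.8e6), `n_offsets` (41), `travel` (0.10 m),
#' `n_repeats` (5), `n_coils` (3), `noise_sigma` (0), quadrature controls
#' `rel_tol` (1e-4) and `n_quad_max` (32).
#'
#' @param config A [scenario_config()] of kind "translation_sweep".
#' @return A list: `sweep` (flux tibble), `envelopes` (per-line complex
#'   envelope matrices per tone), `raw` (`bpt_raw` with PT and BPT tones),
#'   `truth` (tibble line/time/offset), `config`, `hash`.
#' @export
gen_translation_sweep <- function(config = scenario_config("translation_sweep")) {
  stopifnot(config$kind == "translation_sweep")
  set.seed(config$seed)
  pair <- cfg_get(config, "pair", c(2400e6, 2527.8e6))
  f_pt <- cfg_get(config, "pt_frequency", 127.8e6)
  n_off <- cfg_get(config, "n_offsets", 41)
  travel <- cfg_get(config, "travel", 0.10)
  n_rep <- cfg_get(config, "n_repeats", 5)
  n_coils <- cfg_get(config, "n_coils", 3)
  noise_sigma <- cfg_get(config, "noise_sigma", 0)
  rel_tol <- cfg_get(config, "rel_tol", 1e-4)
  n_quad_max <- cfg_get(config, "n_quad_max", 32)

  bore <- bore_model()
  freqs <- c(f_pt, pair)
  sources <- purrr::map(freqs, ~ rf_source(
    rho = 0.30, phi = pi / 2, z = 0.45, frequency = .x,
    orientation = c(0, 1, 1)))
  coil_z <- seq(-0.15, 0.15, length.out = n_coils) - travel / 2
  coils <- purrr::imap(coil_z, ~ coil_surface(
    coil_id = paste0("coil", .y), rho = 0.22, phi = -pi / 2, z = .x))
  offsets <- seq(0, travel, length.out = n_off)

  sweep <- sweep_coil_positions(bore, sources, coils, offsets,
                                rel_tol = rel_tol, n_start = 8,
                                n_max = n_quad_max)
  bpt_env <- sweep_bpt_product(sweep, pair[1], pair[2])
  pt_env <- dplyr::filter(sweep, .data$frequency_hz == f_pt)

  # five triangular periods of the 10 cm motion, one sample per line
  params <- acq_params(
    n_lines = cfg_get(config, "n_lines", 40 * n_rep),
    n_coils = n_coils,
    n_samples = cfg_get(config, "n_samples", 128))
  t_line <- (seq_len(params$n_lines) - 1) * params$tr_s
  period <- max(t_line) / n_rep
  line_offsets <- triangle_motion(t_line, period, travel)

  coil_ids <- purrr::map_chr(coils, ~ as.character(.x$coil_id))
  env_of <- function(tbl, valcol) {
    sapply(coil_ids, function(cid) {
      sub <- dplyr::arrange(tbl[tbl$coil_id == cid, ], .data$offset_m)
      interp_complex(sub$offset_m, sub[[valcol]], line_offsets)
    })
  }
  env_bpt <- env_of(bpt_env, "bpt_rx")
  env_pt <- env_of(pt_env, "flux")
  env_bpt <- env_bpt / mean(Mod(env_bpt))
  env_pt <- env_pt / mean(Mod(env_pt))

  # place the tones on exact DFT bins of the readout window so the two
  # extraction kernels are orthogonal (no cross-talk between PT and BPT)
  df <- params$bandwidth_hz / params$n_samples
  f_bin <- df * round(0.35 * params$n_samples)
  raw <- synthesize_raw(
    params,
    tones = list(
      list(label = "PT", frequency_offset = -f_bin, envelope = env_pt),
      list(label = "BPT", frequency_offset = f_bin, envelope = env_bpt)),
    mr_amplitude = cfg_get(config, "mr_amplitude", 0),
    noise_sigma = noise_sigma, seed = config$seed)

  list(sweep = sweep,
       envelopes = list(pt = env_pt, bpt = env_bpt),
       raw = raw,
       truth = tibble::tibble(line = seq_len(params$n_lines),
                              time_s = t_line, offset_m = line_offsets),
       config = config, hash = config_hash(config))
}

#' Generate a coil vibration event
#'
#' The scanner cradle steps 1 cm at 100 mm/s, exciting a damped coil
#' oscillation, rests 5 s, then steps back with a more heavily damped
#' response. The displacement modulates the coil flux linearly; a synthetic
#' accelerometer records the same motion.
#'
#' Key config fields (defaults): `f0` (12 Hz oscillation), `zeta` (0.04)
#' and `zeta2` (2.5 x zeta), `step_mm` (10), `speed_mm_s` (100),
#' `ring_mm` (0.5), `rest_s` (5), `coupling_per_mm` (0.02),
#' `accel_noise` (0.02), `noise_sigma` (0.002).
#'
#' @param config A [scenario_config()] of kind "vibration".
#' @return A list: `displacement` and `accel` trace tibbles
#'   (`time_s`, `value`), `raw` (`bpt_raw`), `events` (step times), `config`,
#'   `hash`.
#' @export
gen_vibration_event <- function(config = scenario_config("vibration")) {
  stopifnot(config$kind == "vibration")
  set.seed(config$seed)
  f0 <- cfg_get(config, "f0", 12)
  zeta <- cfg_get(config, "zeta", 0.04)
  zeta2 <- cfg_get(config, "zeta2", 2.5 * zeta)
  if (zeta <= 0 || zeta2 <= 0) stop("damping ratios must be positive")
  step_mm <- cfg_get(config, "step_mm", 10)
  speed <- cfg_get(config, "speed_mm_s", 100)
  ring_mm <- cfg_get(config, "ring_mm", 0.5)
  rest_s <- cfg_get(config, "rest_s", 5)
  tr_s <- cfg_get(config, "tr_s", 4.4e-3)
  fs <- 1 / tr_s

  ramp_s <- step_mm / speed
  t_ev <- c(0.5, 0.5 + ramp_s + rest_s)       # step out, then step back
  total_s <- t_ev[2] + ramp_s + rest_s
  t <- seq(0, total_s, by = 1 / fs)

  ring <- function(t0, zet, sgn) {
    tt <- pmax(t - t0, 0)
    on <- as.numeric(t >= t0)
    wd <- 2 * pi * f0 * sqrt(max(1 - min(zet, 1)^2, 1e-12))
    sgn * ring_mm * on * exp(-2 * pi * f0 * zet * tt) * sin(wd * tt)
  }
  ramp <- function(t0, sgn) {
    sgn * step_mm * pmin(pmax(t - t0, 0) / ramp_s, 1)
  }
  d <- ramp(t_ev[1], 1) + ring(t_ev[1] + ramp_s, zeta, 1) +
    ramp(t_ev[2], -1) + ring(t_ev[2] + ramp_s, zeta2, -1)

  accel <- c(0, 0, diff(diff(d))) * fs^2
  accel <- accel + stats::rnorm(length(accel), 0,
                                cfg_get(config, "accel_noise", 0.02) *
                                  max(abs(accel)))

  coupling <- cfg_get(config, "coupling_per_mm", 0.02)
  n_coils <- cfg_get(config, "n_coils", 2)
  gains <- 1 + 0.3 * stats::runif(n_coils)
  env <- sapply(gains, function(g) g * (1 + coupling * d))
  params <- acq_params(n_lines = length(t), n_coils = n_coils,
                       n_samples = cfg_get(config, "n_samples", 64),
                       tr_s = tr_s)
  raw <- synthesize_raw(
    params,
    tones = list(list(label = "BPT", frequency_offset = 80e3,
                      envelope = env)),
    noise_sigma = cfg_get(config, "noise_sigma", 0.002),
    seed = config$seed)

  list(displacement = tibble::tibble(time_s = t, value = d),
       accel = tibble::tibble(time_s = t, value = accel),
       raw = raw, events = t_ev + ramp_s,
       config = config, hash = config_hash(config))
}

# one beat of the cardiac waveform on a relative time axis (s since beat)
beat_template <- function(tt, kind = c("blood_volume", "dbcg")) {
  kind <- match.arg(kind)
  g <- function(mu, sd) exp(-0.5 * ((tt - mu) / sd)^2)
  if (kind == "blood_volume") {
    g(0.30, 0.12)
  } else {
    # I/J/K-like wave train: sharp down-up-down complex
    -0.45 * g(0.16, 0.022) + 1.0 * g(0.24, 0.025) - 0.55 * g(0.32, 0.028)
  }
}

cardiac_trace <- function(t, hr_bpm, kind) {
  period <- 60 / hr_bpm
  tt <- t %% period
  beat_template(tt, kind)
}

#' Generate a physiological-motion experiment
#'
#' Respiration (slow quasi-sinusoid; chest, stomach or rapid-shallow
#' regimes), optional bulk-motion steps, and a cardiac component whose
#' shape depends on the transmit frequency: a smooth blood-volume wave
#' (one peak per beat) below ~1.2 GHz blending into a sharp multi-peak
#' dBCG-like wave train above it. A `stiffness` parameter scales the dBCG
#' contribution (rigid coils amplify body vibration; flexible ones damp it).
#'
#' Key config fields (defaults): `duration_s` (30), `hr_bpm` (60),
#' `resp_hz` (0.25), `breathing` ("chest"), `pair` (`c(2400e6, 2527.8e6)`),
#' `stiffness` (1), `cardiac_amplitude` (0.05), `resp_amplitude` (0.15),
#' `bulk_times` (numeric(0)), `bulk_amplitude` (0.3), `n_coils` (8),
#' `noise_sigma` (0.002).
#'
#' @param config A [scenario_config()] of kind "physio".
#' @return A list: `traces` (long tibble `time_s`, `name`, `value` with
#'   respiration / bulk / cardiac / dbcg components), `envelopes`
#'   (lines x coils), `raw`, `config`, `hash`.
#' @export
gen_physio <- function(config = scenario_config("physio")) {
  stopifnot(config$kind == "physio")
  set.seed(config$seed)
  dur <- cfg_get(config, "duration_s", 30)
  hr <- cfg_get(config, "hr_bpm", 60)
  resp_hz <- cfg_get(config, "resp_hz", 0.25)
  if (hr <= 0 || resp_hz <= 0) stop("rates must be positive")
  breathing <- cfg_get(config, "breathing", "chest")
  pair <- cfg_get(config, "pair", c(2400e6, 2527.8e6))
  stiffness <- cfg_get(config, "stiffness", 1)
  a_card <- cfg_get(config, "cardiac_amplitude", 0.05)
  a_resp <- cfg_get(config, "resp_amplitude", 0.15)
  bulk_times <- cfg_get(config, "bulk_times", numeric(0))
  a_bulk <- cfg_get(config, "bulk_amplitude", 0.3)
  n_coils <- cfg_get(config, "n_coils", 8)
  tr_s <- cfg_get(config, "tr_s", 4.4e-3)

  t <- seq(0, dur, by = tr_s)
  resp_shape <- switch(
    breathing,
    chest = sin(2 * pi * resp_hz * t),
    stomach = sin(2 * pi * resp_hz * t)^3 * 1.2,
    rapid = 0.5 * sin(2 * pi * 2 * resp_hz * t),
    stop("unknown breathing regime"))
  resp <- a_resp * resp_shape

  bulk <- numeric(length(t))
  for (bt in bulk_times) {
    bulk <- bulk + a_bulk * (1 / (1 + exp(-(t - bt) / 0.05)))
  }
  bulk <- bulk - if (length(bulk_times)) mean(bulk) else 0

  # frequency-dependent cardiac mechanism: smooth blood-volume wave at low
  # transmit frequency blending into sharp dBCG above ~1.2 GHz
  f_mean <- mean(pair)
  w_dbcg <- 1 / (1 + exp(-(f_mean - 1.2e9) / 0.2e9))
  bv <- cardiac_trace(t, hr, "blood_volume")
  dbcg <- cardiac_trace(t, hr, "dbcg")
  cardiac <- a_card * ((1 - w_dbcg) * bv +
                         w_dbcg * stiffness * dbcg)
  if (stiffness == 0 && w_dbcg > 0.5) {
    # fully damped vibration: the residual cardiac signal is blood volume
    cardiac <- a_card * bv
  }

  w_resp <- stats::runif(n_coils, 0.5, 1.5)
  w_bulk <- stats::runif(n_coils, 0.5, 1.5)
  w_card <- stats::runif(n_coils, 0.5, 1.5)
  env <- sapply(seq_len(n_coils), function(ci) {
    1 + w_resp[ci] * resp + w_bulk[ci] * bulk + w_card[ci] * cardiac
  })

  params <- acq_params(n_lines = length(t), n_coils = n_coils,
                       n_samples = cfg_get(config, "n_samples", 64),
                       tr_s = tr_s)
  raw <- synthesize_raw(
    params,
    tones = list(list(label = "BPT", frequency_offset = 80e3,
                      envelope = env)),
    noise_sigma = cfg_get(config, "noise_sigma", 0.002),
    seed = config$seed)

  traces <- dplyr::bind_rows(
    tibble::tibble(time_s = t, name = "respiration", value = resp),
    tibble::tibble(time_s = t, name = "bulk", value = bulk),
    tibble::tibble(time_s = t, name = "cardiac", value = cardiac),
    tibble::tibble(time_s = t, name = "dbcg_template",
                   value = a_card * stiffness * dbcg))
  list(traces = traces, envelopes = env, raw = raw,
       config = config, hash = config_hash(config))
}

# triangle wave in [-1, 1]
tri_wave <- function(x) 2 * abs(2 * (x - floor(x + 0.5))) - 1

# smooth per-channel response surface: affine + quadratic in the 6 rigid
# parameters (normalised to the calibration box)
channel_response <- function(p_norm, lin, quad, base) {
  n <- nrow(p_norm)
  out <- numeric(n)
  for (i in seq_len(n)) {
    v <- p_norm[i, ]
    out[i] <- base + sum(lin * v) + as.numeric(t(v) %*% quad %*% v)
  }
  out
}

#' Generate a MIMO head-motion calibration/inference pair
#'
#' Emulates a two-antenna, 22-coil rigid head coil experiment: a
#' calibration scan rasters the six rigid-body parameters over a
#' +/-3 mm / +/-4 degree box (115 frames), and an inference scan contains
#' two one-dimensional motions - shaking "no" (yaw) and nodding "yes"
#' (pitch) - of 25 frames each, both passing through the rest pose.
#' Channel envelopes are smooth seeded quadratic response surfaces of the
#' rigid parameters; pilot-tone channels carry more noise than beat-tone
#' channels.
#'
#' Key config fields (defaults): `n_cal` (115), `n_inf` (50), `n_coils`
#' (22), `n_antennas` (2), `box_mm` (3), `box_deg` (4), `bpt_noise`
#' (0.005), `pt_noise` (0.02), `lin_scale` (0.08), `quad_scale` (0.02).
#'
#' @param config A [scenario_config()] of kind "mimo_head".
#' @return A list with `calibration` and `inference` (each a list of
#'   stacked `bpt_frames` named `bpt` and `pt`), `truth` (list of rigid
#'   parameter tibbles), `config`, `hash`.
#' @export
gen_mimo_head <- function(config = scenario_config("mimo_head")) {
  stopifnot(config$kind == "mimo_head")
  set.seed(config$seed)
  n_cal <- cfg_get(config, "n_cal", 115)
  n_inf <- cfg_get(config, "n_inf", 50)
  n_coils <- cfg_get(config, "n_coils", 22)
  n_ant <- cfg_get(config, "n_antennas", 2)
  box_mm <- cfg_get(config, "box_mm", 3)
  box_deg <- cfg_get(config, "box_deg", 4)
  if (box_mm <= 0 || box_deg <= 0) stop("calibration box must be positive")
  bpt_noise <- cfg_get(config, "bpt_noise", 0.005)
  pt_noise <- cfg_get(config, "pt_noise", 0.02)
  lin_scale <- cfg_get(config, "lin_scale", 0.08)
  quad_scale <- cfg_get(config, "quad_scale", 0.02)

  par_names <- c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg")
  box <- c(rep(box_mm, 3), rep(box_deg, 3))

  # calibration: raster coverage via incommensurate triangle waves
  tt <- seq(0, 1, length.out = n_cal)
  rates <- c(1.0, 2.3, 3.7, 5.1, 6.9, 8.3)
  phases <- stats::runif(6)
  cal <- sapply(seq_len(6), function(j) {
    box[j] * tri_wave(rates[j] * tt + phases[j])
  })
  colnames(cal) <- par_names

  # inference: shake (yaw, rz) then nod (pitch, rx), both through rest pose
  n_half <- n_inf %/% 2
  ti <- seq(0, 1, length.out = n_half)
  inf <- matrix(0, n_inf, 6, dimnames = list(NULL, par_names))
  inf[seq_len(n_half), "rz_deg"] <- box_deg * sin(2 * pi * 2 * ti)
  inf[seq_len(n_half), "ty_mm"] <- 0.3 * box_mm * sin(2 * pi * 2 * ti)
  ni <- (n_half + 1):n_inf
  ti2 <- seq(0, 1, length.out = length(ni))
  inf[ni, "rx_deg"] <- box_deg * sin(2 * pi * 2 * ti2)
  inf[ni, "tz_mm"] <- 0.3 * box_mm * sin(2 * pi * 2 * ti2)
  inf <- inf * cfg_get(config, "inf_scale", 1)
  labels <- c(rep("shake", n_half), rep("nod", n_inf - n_half))

  norm_cal <- sweep(cal, 2, box, `/`)
  norm_inf <- sweep(inf, 2, box, `/`)

  # response surfaces must be identical between calibration and inference:
  # draw them once, evaluate on both trajectories
  set.seed(config$seed + 17)
  surfaces <- purrr::map(seq_len(n_ant), function(a) {
    purrr::map(seq_len(n_coils), function(ci) {
      lin <- stats::rnorm(6)
      quad <- matrix(stats::rnorm(36, 0, 1), 6, 6)
      list(lin = lin_scale * lin, quad = quad_scale * (quad + t(quad)) / 2)
    })
  })
  eval_block <- function(p_norm, noise, seed_off) {
    set.seed(config$seed + seed_off)
    purrr::map(seq_len(n_ant), function(a) {
      m <- sapply(seq_len(n_coils), function(ci) {
        s <- surfaces[[a]][[ci]]
        channel_response(p_norm, s$lin, s$quad, base = 1)
      })
      m + matrix(stats::rnorm(length(m), 0, noise), nrow(m))
    })
  }

  mk_frames <- function(blocks, labels = NULL) {
    mimo_stack(purrr::imap(blocks, function(m, a) {
      new_frames(m, labels = labels, antenna_id = paste0("ant", a))
    }))
  }
  calibration <- list(
    bpt = mk_frames(eval_block(norm_cal, bpt_noise, 101)),
    pt = mk_frames(eval_block(norm_cal, pt_noise, 102)))
  inference <- list(
    bpt = mk_frames(eval_block(norm_inf, bpt_noise, 103), labels),
    pt = mk_frames(eval_block(norm_inf, pt_noise, 104), labels))

  list(calibration = calibration, inference = inference,
       truth = list(calibration = tibble::as_tibble(cal),
                    inference = dplyr::mutate(tibble::as_tibble(inf),
                                              label = labels)),
       config = config, hash = config_hash(config))
}
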