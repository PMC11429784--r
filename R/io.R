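# Configuration, container and report plumbing. A simulation run is stored
# as a plain-text run directory: CSV for arrays and traces, JSON for
# metadata, reports and the run manifest, YAML for scenario configs.
# Doubles destined for exact round trips are serialised with 17 significant
# digits, which is lossless for IEEE binary64.

fmt_dbl <- function(x) sprintf("%.17g", x)

#' Read / write a scenario configuration (YAML)
#'
#' @param path File path.
#' @param strict Validate required fields (default TRUE when reading).
#' @return A `bpt_scenario_config`.
#' @export
read_scenario_config <- function(path, strict = TRUE) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$kind)) stop("scenario config field 'kind' is missing")
  cfg <- do.call(scenario_config,
                 c(list(kind = cfg$kind, seed = cfg$seed %||% 1),
                   cfg[setdiff(names(cfg), c("kind", "seed"))]))
  if (strict) validate_scenario_config(cfg)
  cfg
}

#' @rdname read_scenario_config
#' @param config A `bpt_scenario_config`.
#' @export
write_scenario_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a scenario configuration
#'
#' Checks field presence and types, raising an error that names the
#' offending field. Transmitting scenarios ("translation_sweep", "physio")
#' must state their tone frequency pair explicitly when loaded from file.
#'
#' @param config A `bpt_scenario_config`.
#' @return The config, invisibly.
#' @export
validate_scenario_config <- function(config) {
  kinds <- c("translation_sweep", "vibration", "physio", "mimo_head")
  if (!config$kind %in% kinds) {
    stop("scenario config field 'kind' must be one of: ",
         paste(kinds, collapse = ", "))
  }
  if (!is.numeric(config$seed)) {
    stop("scenario config field 'seed' must be an integer")
  }
  if (config$kind %in% c("translation_sweep", "physio")) {
    if (is.null(config$pair)) {
      stop("scenario config field 'pair' (tone frequency pair, Hz) is missing")
    }
    if (length(config$pair) != 2 || !is.numeric(config$pair) ||
        config$pair[2] <= config$pair[1]) {
      stop("scenario config field 'pair' must be two increasing frequencies")
    }
  }
  invisible(config)
}

# ---- CSV interfaces ---------------------------------------------------------

#' Write / read a flux sweep as CSV
#'
#' Columns: `coil_id`, `frequency_hz`, `offset_m`, `flux_real`, `flux_imag`.
#' @param sweep Tibble from [sweep_coil_positions()]. @param path File path.
#' @export
write_flux_csv <- function(sweep, path) {
  readr::write_csv(
    dplyr::mutate(sweep, flux_real = fmt_dbl(Re(.data$flux)),
                  flux_imag = fmt_dbl(Im(.data$flux)), flux = NULL),
    path)
  invisible(path)
}

#' @rdname write_flux_csv
#' @export
read_flux_csv <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path))
  dplyr::mutate(d, flux = complex(real = .data$flux_real,
                                  imaginary = .data$flux_imag),
                flux_real = NULL, flux_imag = NULL)
}

#' Write / read an extracted tone series as CSV
#'
#' Columns: `line`, `line_time_s`, `coil_id`, `real`, `imag`. The numeric
#' round trip is bit-exact.
#' @param series A `bpt_series`. @param path File path.
#' @export
write_series_csv <- function(series, path) {
  readr::write_csv(
    tibble::tibble(line = series$line,
                   line_time_s = fmt_dbl(series$line_time_s),
                   coil_id = series$coil, real = fmt_dbl(Re(series$value)),
                   imag = fmt_dbl(Im(series$value))),
    path)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  d <- utils::read.csv(path)
  out <- tibble::tibble(line = d$line, line_time_s = d$line_time_s,
                        coil = d$coil_id,
                        value = complex(real = d$real, imaginary = d$imag))
  class(out) <- c("bpt_series", class(out))
  out
}

#' Write / read a named trace as CSV (`time_s`, `value`)
#' @param trace Tibble with `time_s` and `value`. @param path File path.
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(trace[, c("time_s", "value")], path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

# ---- Raw container ----------------------------------------------------------

#' Write / read a raw acquisition container
#'
#' A raw acquisition is stored as a directory: `raw_data.csv` (long form:
#' line, coil, sample, real, imag), `raw_meta.json` (dimensions, dwell time,
#' line times, bands, tones). The numeric round trip is exact.
#'
#' @param raw A `bpt_raw`. @param dir Directory (created if needed).
#' @export
write_raw <- function(raw, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(raw$data)
  idx <- expand.grid(line = seq_len(d[1]), coil = seq_len(d[2]),
                     sample = seq_len(d[3]))
  readr::write_csv(
    tibble::tibble(line = idx$line, coil = idx$coil, sample = idx$sample,
                   real = fmt_dbl(Re(as.vector(raw$data))),
                   imag = fmt_dbl(Im(as.vector(raw$data)))),
    file.path(dir, "raw_data.csv"))
  p <- raw$params
  meta <- list(
    n_lines = p$n_lines, n_coils = p$n_coils, n_samples = p$n_samples,
    bandwidth_hz = p$bandwidth_hz, tr_s = p$tr_s,
    image_band_hz = p$image_band_hz, line_times = raw$line_times,
    tones = raw$tones, seed = raw$seed)
  jsonlite::write_json(meta, file.path(dir, "raw_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_raw
#' @export
read_raw <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "raw_meta.json"),
                              simplifyVector = TRUE)
  d <- utils::read.csv(file.path(dir, "raw_data.csv"))
  params <- acq_params(n_lines = meta$n_lines, n_coils = meta$n_coils,
                       n_samples = meta$n_samples,
                       bandwidth_hz = meta$bandwidth_hz, tr_s = meta$tr_s,
                       image_band_hz = meta$image_band_hz)
  data <- array(complex(real = d$real, imaginary = d$imag),
                dim = c(meta$n_lines, meta$n_coils, meta$n_samples))
  tones <- tibble::as_tibble(meta$tones)
  structure(list(data = data, params = params,
                 line_times = meta$line_times, tones = tones,
                 seed = meta$seed),
            class = "bpt_raw")
}

# ---- Manifest ---------------------------------------------------------------

#' Write a run manifest
#'
#' Every run directory carries exactly one `manifest.json` recording the
#' command, config hash, seed, inputs/outputs, package version and
#' timestamp, so any output is regenerable.
#'
#' @param command Command name (e.g. "simulate").
#' @param config A `bpt_scenario_config`.
#' @param out_dir Run directory.
#' @param inputs,outputs Character vectors of paths.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(command, config, out_dir, inputs = character(),
                           outputs = character()) {
  manifest <- list(
    command = command,
    config_hash = config_hash(config),
    seed = config$seed,
    inputs = inputs, outputs = outputs,
    package_version = as.character(utils::packageVersion("beatpilot")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# ---- Pipeline entry points --------------------------------------------------

#' Simulate a scenario and write a run directory
#'
#' Runs the scenario named in the config end to end and writes the run
#' directory: scenario config (YAML), raw container (CSV + JSON), flux /
#' trace / truth CSVs, and the run manifest. Outputs are byte-identical
#' for a fixed config.
#'
#' @param config A `bpt_scenario_config` or path to a YAML config.
#' @param out_dir Output directory (created).
#' @return The scenario result list, invisibly, with `$out_dir` attached.
#' @export
bpt_simulate <- function(config, out_dir) {
  if (is.character(config)) config <- read_scenario_config(config)
  validate_scenario_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- switch(config$kind,
                translation_sweep = gen_translation_sweep(config),
                vibration = gen_vibration_event(config),
                physio = gen_physio(config),
                mimo_head = gen_mimo_head(config))
  write_scenario_config(config, file.path(out_dir, "config.yaml"))
  outputs <- "config.yaml"
  if (!is.null(res$raw)) {
    write_raw(res$raw, file.path(out_dir, "raw"))
    outputs <- c(outputs, "raw/")
  }
  if (!is.null(res$sweep)) {
    write_flux_csv(res$sweep, file.path(out_dir, "flux.csv"))
    outputs <- c(outputs, "flux.csv")
  }
  if (!is.null(res$truth)) {
    readr::write_csv(res$truth, file.path(out_dir, "truth.csv"))
    outputs <- c(outputs, "truth.csv")
  }
  if (!is.null(res$displacement)) {
    write_trace_csv(res$displacement, file.path(out_dir, "displacement.csv"))
    write_trace_csv(res$accel, file.path(out_dir, "accel.csv"))
    outputs <- c(outputs, "displacement.csv", "accel.csv")
  }
  if (!is.null(res$traces)) {
    readr::write_csv(res$traces, file.path(out_dir, "traces.csv"))
    outputs <- c(outputs, "traces.csv")
  }
  if (config$kind == "mimo_head") {
    for (nm in c("calibration", "inference")) {
      readr::write_csv(res$truth[[nm]],
                       file.path(out_dir, paste0("truth_", nm, ".csv")))
      for (sig in c("bpt", "pt")) {
        readr::write_csv(tibble::as_tibble(res[[nm]][[sig]]$matrix,
                                           .name_repair = "unique_quiet"),
                         file.path(out_dir,
                                   paste0("frames_", nm, "_", sig, ".csv")))
      }
    }
    outputs <- c(outputs, "truth_calibration.csv", "truth_inference.csv")
  }
  write_manifest("simulate", config, out_dir, outputs = outputs)
  res$out_dir <- out_dir
  invisible(res)
}

# count local maxima whose height above the higher of the two flanking
# minima exceeds `min_prominence`
count_peaks <- function(x, min_prominence = 0.05 * (max(x) - min(x))) {
  n <- length(x)
  if (n < 3) return(0L)
  is_max <- which(diff(sign(diff(x))) < 0) + 1
  cnt <- 0L
  for (i in is_max) {
    left <- min(x[1:i])
    right <- min(x[i:n])
    if (x[i] - max(left, right) >= min_prominence) cnt <- cnt + 1L
  }
  cnt
}

# dominant spectral frequency of a trace within a band (Hz)
spectral_peak_hz <- function(x, sample_rate, band = c(0.05, 2)) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) * sample_rate / n
  sel <- f >= band[1] & f <= band[2] & f <= sample_rate / 2
  f[sel][which.max(sp[sel])]
}

#' Analyze a simulated run
#'
#' Re-extracts the embedded tones from a run directory (or an in-memory
#' result of [bpt_simulate()]), runs the signal-processing chain, and
#' produces a report: percent-modulation summaries, modulation ranges and
#' peak counts per coil, and scenario-specific analytics (displacement
#' correlation for vibration runs, respiratory-rate recovery for physio
#' runs, PCA/regression/separability for head-motion runs). The report is
#' written as `report.json` when `out_dir` is given.
#'
#' @param run A run directory path or a [bpt_simulate()] result.
#' @param out_dir Optional output directory for `report.json` and tables.
#' @param lowpass_hz Low-pass cutoff for extracted magnitudes (Hz),
#'   default 2.
#' @return The report as a list.
#' @export
bpt_analyze <- function(run, out_dir = NULL, lowpass_hz = 2) {
  if (is.character(run)) {
    cfg <- read_scenario_config(file.path(run, "config.yaml"),
                                strict = FALSE)
    res <- switch(cfg$kind,
                  translation_sweep = gen_translation_sweep(cfg),
                  vibration = gen_vibration_event(cfg),
                  physio = gen_physio(cfg),
                  mimo_head = gen_mimo_head(cfg))
    if (!is.null(res$raw) && dir.exists(file.path(run, "raw"))) {
      res$raw <- read_raw(file.path(run, "raw"))
    }
  } else {
    res <- run
    cfg <- res$config
  }
  report <- list(kind = cfg$kind, seed = cfg$seed,
                 config_hash = config_hash(cfg))

  if (cfg$kind == "mimo_head") {
    report <- c(report, analyze_mimo(res))
  } else {
    if (is.null(res$raw) || nrow(res$raw$tones) == 0) {
      stop("no tones declared in the acquisition; nothing to extract")
    }
    fs <- 1 / res$raw$params$tr_s
    per_tone <- purrr::pmap(res$raw$tones, function(label, frequency_offset) {
      ser <- extract_tone(res$raw, frequency_offset)
      mag <- series_matrix(ser, "magnitude")
      magf <- apply(mag, 2, zero_phase_lowpass, cutoff_hz = lowpass_hz,
                    sample_rate = fs)
      pm <- percent_modulation(magf)
      byc <- dplyr::summarise(
        dplyr::group_by(pm, .data$channel),
        range_pct = if (all(is.na(.data$pct_mod))) NA_real_ else
          modulation_range(.data$pct_mod),
        peaks = if (all(is.na(.data$pct_mod))) NA_integer_ else
          count_peaks(.data$pct_mod[!is.na(.data$pct_mod)]),
        .groups = "drop")
      list(label = label, frequency_offset = frequency_offset,
           percent_modulation = byc,
           max_range_pct = max(byc$range_pct, na.rm = TRUE),
           max_peaks = max(byc$peaks, na.rm = TRUE))
    })
    names(per_tone) <- res$raw$tones$label
    report$tones <- per_tone
    if (all(c("BPT", "PT") %in% names(per_tone))) {
      report$sensitivity_ratio <-
        per_tone$BPT$max_range_pct / per_tone$PT$max_range_pct
    }
    if (cfg$kind == "vibration") {
      fs_acc <- 1 / diff(res$accel$time_s[1:2])
      disp_hat <- accel_to_displacement(res$accel$value, fs_acc,
                                        highpass_cutoff = 2.5)
      ser <- extract_tone(res$raw, res$raw$tones$frequency_offset[1])
      env <- rowMeans(series_matrix(ser, "magnitude"))
      envf <- zero_phase_highpass(
        zero_phase_lowpass(env, 25, fs), 2.5, fs)
      report$vibration <- list(
        displacement_correlation = stats::cor(envf, disp_hat))
    }
    if (cfg$kind == "physio") {
      ser <- extract_tone(res$raw, res$raw$tones$frequency_offset[1])
      env <- rowMeans(series_matrix(ser, "magnitude"))
      rr <- spectral_peak_hz(env, fs, band = c(0.05, 1.2))
      report$physio <- list(respiratory_rate_hz = rr)
    }
  }
  validate_report(report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    write_manifest("analyze", cfg, out_dir, outputs = "report.json")
  }
  report
}

analyze_mimo <- function(res) {
  prep <- function(frames) {
    f2 <- frames
    f2$matrix <- savgol_smooth(frames$matrix)
    f2
  }
  cal_bpt <- prep(res$calibration$bpt)
  inf_bpt <- prep(res$inference$bpt)
  model <- pca_fit(cal_bpt, n_pc = 3)
  scores_inf <- pca_project(model, inf_bpt)

  reg_truth <- savgol_smooth(as.matrix(res$truth$calibration))
  reg_pcs <- pca_fit(reg_truth, n_pc = 3)$scores

  fit_both <- purrr::map(1:3, ~ regress_multicoil(cal_bpt, reg_pcs[, .x]))
  per_ant <- mimo_split(cal_bpt)
  fit_single <- purrr::map(per_ant, function(blk) {
    purrr::map_dbl(1:3, ~ regress_multicoil(blk, reg_pcs[, .x])$pearson_r)
  })
  plane <- separability_plane(scores_inf, res$inference$bpt$labels)
  list(mimo = list(
    explained_fraction = sum(model$explained),
    regression_r_both = purrr::map_dbl(fit_both, "pearson_r"),
    regression_r_single = fit_single,
    inference_loo_accuracy = plane$loo_accuracy,
    inference_separable = plane$separable))
}

#' Validate an analysis report against the expected schema
#'
#' Checks the presence and types of the required fields for the report's
#' scenario kind, erroring with the field name otherwise.
#'
#' @param report A report list from [bpt_analyze()].
#' @return The report, invisibly.
#' @export
validate_report <- function(report) {
  need <- function(field, check = Negate(is.null)) {
    if (!check(report[[field]])) {
      stop("report field '", field, "' is missing or invalid")
    }
  }
  need("kind", function(x) is.character(x) && length(x) == 1)
  need("seed")
  need("config_hash", is.character)
  if (report$kind == "mimo_head") {
    if (is.null(report$mimo$regression_r_both)) {
      stop("report field 'mimo.regression_r_both' is missing or invalid")
    }
  } else {
    need("tones", is.list)
  }
  invisible(report)
}
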