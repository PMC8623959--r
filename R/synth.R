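#' Simulation configuration for synthetic laser-induced vibration records
#'
#' Builds the parameter set of the generative signal model used by
#' [simulate_record()] and [simulate_dataset()]. Each laser pulse excites a
#' sum of exponentially damped sinusoid modes; the dominant mode frequency
#' follows a logarithmic law in peak insertion torque,
#' `f1 = torque_freq_intercept + torque_freq_slope * log(torque)`,
#' and a movable (polyaxial) screw head adds a tilt-dependent frequency
#' shift plus pulse-to-pulse jitter. Secondary modes sit at fixed frequency
#' ratios of the dominant mode and respond to tilt with reduced sensitivity,
#' so part of the torque information in the spectrum survives head motion —
#' the property the machine-learning analysis exploits.
#'
#' @param preset `"polyaxial"` (movable head, tilt shifts active) or
#'   `"monoaxial"` (fixed head: no tilt shifts, small residual jitter).
#' @param sampling_rate Samples per second (Hz).
#' @param record_duration Record length in seconds.
#' @param pulse_rate Laser pulse repetition rate (Hz);
#'   `pulse_rate * record_duration` must be a whole number of pulses.
#' @param n_modes Number of damped modes per pulse (1..length of the mode
#'   vectors).
#' @param torque_freq_intercept Dominant-mode frequency at 1 Nm (Hz).
#' @param torque_freq_slope Frequency change per unit `log(torque)` (Hz per
#'   ln(Nm)).
#' @param mode_freq_ratios Frequency of each mode as a multiple of the
#'   dominant-mode frequency (first entry must be 1).
#' @param mode_tilt_sensitivity Multiple of the tilt shift and jitter each
#'   mode receives (first entry 1). Modes differ in how much of their shape
#'   involves the movable head, so their frequencies respond to a tilt with
#'   different strengths; the mix of strongly and weakly tilt-coupled modes
#'   is what lets a whole-spectrum analysis separate the head-tilt
#'   perturbation from the torque signal.
#' @param damping_rates Exponential decay rate of each mode (1/s), all > 0.
#' @param mode_amplitudes Relative amplitude of each mode, all >= 0.
#' @param mode_amp_tilt_sensitivity Per-mode log-amplitude response to the
#'   realized tilt shift (per kHz of shift). A tilted head changes the
#'   screw's center of gravity and hence the natural mode shapes, so the
#'   relative intensity of the modes — not just their frequencies — depends
#'   strongly on the tilt: across the tilt range different modes dominate
#'   the spectrum, as seen when a movable-head screw is measured in
#'   different head positions. This intensity pattern is what lets a
#'   whole-spectrum analysis separate the head-tilt perturbation from the
#'   torque signal.
#' @param tilt_shift_horizontal Mean dominant-peak shift for a horizontal
#'   head tilt (Hz, negative).
#' @param tilt_shift_vertical Mean shift for a vertical tilt (Hz, positive).
#' @param tilt_jitter_sd Standard deviation (Hz) of the per-record realized
#'   tilt shift around its direction mean: the run-to-run variation seen when
#'   a movable head is re-tilted between measurements.
#' @param pulse_jitter_sd Standard deviation (Hz) of the small pulse-to-pulse
#'   frequency wobble within one record. The head does not move between the
#'   pulses of a single record, so this is much smaller than
#'   `tilt_jitter_sd`; it mildly broadens spectral peaks without decohering
#'   the averaged impulse response.
#' @param noise_sd Standard deviation of additive white measurement noise,
#'   relative to the unit dominant-mode amplitude.
#' @param rng_seed Default integer seed used when `simulate_record()` is not
#'   given one explicitly.
#'
#' @return A list of class `lrfa_sim_config`.
#' @seealso [simulate_record()], [simulate_dataset()]
#' @export
#' @examples
#' cfg <- sim_config("polyaxial")
#' cfg$torque_freq_intercept
sim_config <- function(preset = c("polyaxial", "monoaxial"),
                       sampling_rate = 1e5,
                       record_duration = 2,
                       pulse_rate = 10,
                       n_modes = 6,
                       torque_freq_intercept = NULL,
                       torque_freq_slope = NULL,
                       mode_freq_ratios = c(1, 1.85, 0.35, 2.6, 1.45, 0.16),
                       mode_tilt_sensitivity = c(1, 0.35, 0.1, 0.6, 0.8, 0.05),
                       damping_rates = c(40, 60, 80, 90, 70, 50),
                       mode_amplitudes = c(1, 0.45, 0.3, 0.25, 0.35, 0.2),
                       mode_amp_tilt_sensitivity = c(-0.3, 0.4, 0.2, -0.25, 0.3, 0.1),
                       tilt_shift_horizontal = NULL,
                       tilt_shift_vertical = NULL,
                       tilt_jitter_sd = NULL,
                       pulse_jitter_sd = 10,
                       noise_sd = 0.02,
                       rng_seed = 1L) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    polyaxial = list(intercept = 6700, slope = 1200,
                     horiz = -800, vert = 800, jitter = 150),
    monoaxial = list(intercept = 3500, slope = 500,
                     horiz = 0, vert = 0, jitter = 40)
  )
  cfg <- list(
    preset = preset,
    sampling_rate = sampling_rate,
    record_duration = record_duration,
    pulse_rate = pulse_rate,
    n_modes = n_modes,
    torque_freq_intercept = torque_freq_intercept %||% defaults$intercept,
    torque_freq_slope = torque_freq_slope %||% defaults$slope,
    mode_freq_ratios = mode_freq_ratios,
    mode_tilt_sensitivity = mode_tilt_sensitivity,
    damping_rates = damping_rates,
    mode_amplitudes = mode_amplitudes,
    mode_amp_tilt_sensitivity = mode_amp_tilt_sensitivity,
    tilt_shift_horizontal = tilt_shift_horizontal %||% defaults$horiz,
    tilt_shift_vertical = tilt_shift_vertical %||% defaults$vert,
    tilt_jitter_sd = tilt_jitter_sd %||% defaults$jitter,
    pulse_jitter_sd = pulse_jitter_sd,
    noise_sd = noise_sd,
    rng_seed = rng_seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "lrfa_sim_config")
}

validate_sim_config <- function(cfg) {
  n_pulses <- cfg$pulse_rate * cfg$record_duration
  if (n_pulses <= 0 || !is_whole(n_pulses)) {
    abort_config(
      "`pulse_rate * record_duration` must be a positive whole number of pulses."
    )
  }
  if (cfg$n_modes < 1 || cfg$n_modes > length(cfg$mode_freq_ratios)) {
    abort_config("`n_modes` must be between 1 and length(mode_freq_ratios).")
  }
  if (any(cfg$damping_rates[seq_len(cfg$n_modes)] <= 0)) {
    abort_config("All `damping_rates` must be > 0.")
  }
  if (any(cfg$mode_amplitudes[seq_len(cfg$n_modes)] < 0)) {
    abort_config("All `mode_amplitudes` must be >= 0.")
  }
  if (cfg$mode_freq_ratios[1] != 1 || cfg$mode_tilt_sensitivity[1] != 1) {
    abort_config("The first mode is the dominant one: ratio and sensitivity must be 1.")
  }
  if (cfg$tilt_jitter_sd < 0 || cfg$pulse_jitter_sd < 0 || cfg$noise_sd < 0) {
    abort_config("`tilt_jitter_sd`, `pulse_jitter_sd` and `noise_sd` must be >= 0.")
  }
  invisible(cfg)
}

tilt_labels <- c("center", "horizontal", "vertical", "skew")

tilt_mean_shift <- function(label, cfg) {
  switch(label,
    center = 0,
    horizontal = cfg$tilt_shift_horizontal,
    vertical = cfg$tilt_shift_vertical,
    # a diagonal tilt sits between the horizontal and vertical extremes
    skew = (cfg$tilt_shift_horizontal + cfg$tilt_shift_vertical) / 2
  )
}

#' Realize a screw-head tilt state
#'
#' Draws the realized dominant-peak frequency shift for one measurement of a
#' polyaxial screw whose head is tilted in a given direction. The shift is
#' Gaussian around a direction-specific mean: zero at the center position,
#' negative for a horizontal tilt, positive for a vertical tilt, and in
#' between (zero mean) for a skew tilt. Repeated draws at the same label
#' differ, reproducing the run-to-run spectral variation seen when a movable
#' head is re-tilted to nominally the same direction.
#'
#' @param label One of `"center"`, `"horizontal"`, `"vertical"`, `"skew"`.
#' @param cfg A [sim_config()] object.
#' @param seed Optional integer seed for the draw.
#' @return A list of class `lrfa_tilt_state` with fields `label` and
#'   `realized_shift` (Hz).
#' @export
tilt_state <- function(label = tilt_labels, cfg = sim_config(), seed = NULL) {
  label <- match.arg(label)
  shift <- with_seed(seed, stats::rnorm(1, tilt_mean_shift(label, cfg), cfg$tilt_jitter_sd))
  structure(list(label = label, realized_shift = shift),
            class = "lrfa_tilt_state")
}

as_tilt_state <- function(tilt, cfg) {
  if (inherits(tilt, "lrfa_tilt_state")) {
    return(tilt)
  }
  if (is.character(tilt) && length(tilt) == 1L && tilt %in% tilt_labels) {
    # drawn under the ambient RNG (simulate_record seeds it first)
    shift <- stats::rnorm(1, tilt_mean_shift(tilt, cfg), cfg$tilt_jitter_sd)
    return(structure(list(label = tilt, realized_shift = shift),
                     class = "lrfa_tilt_state"))
  }
  abort_config("`tilt` must be a tilt label or a tilt_state() object.")
}

#' Simulate one laser-induced vibration record
#'
#' Generates the voltage trace a laser-Doppler vibrometer would record over
#' `record_duration` seconds: a train of impulse responses (one per laser
#' pulse), each a sum of exponentially damped sinusoids, plus additive white
#' noise. The dominant mode frequency is
#' `torque_freq_intercept + torque_freq_slope * log(torque) +
#' realized tilt shift + per-pulse jitter`; secondary modes sit at fixed
#' ratios and receive a reduced share of the tilt perturbation. Deterministic
#' given the seed.
#'
#' @param torque Peak insertion torque in Nm (> 0), the stability index the
#'   downstream pipeline predicts.
#' @param tilt A tilt label (`"center"`, `"horizontal"`, `"vertical"`,
#'   `"skew"`) or a [tilt_state()] object with an already-realized shift.
#' @param cfg A [sim_config()] object.
#' @param seed Integer seed; defaults to `cfg$rng_seed`.
#' @param id Record identifier stored on the result.
#'
#' @return A tibble of class `lrfa_record` with columns `time_s` and
#'   `voltage` and attributes `acquisition` (an [acquisition_config()]),
#'   `record_id`, `torque_nm` and `tilt` (the realized `lrfa_tilt_state`).
#' @export
#' @examples
#' cfg <- sim_config(record_duration = 0.2, noise_sd = 0)
#' rec <- simulate_record(1.05, "center", cfg, seed = 7)
#' nrow(rec) # sampling_rate * record_duration
simulate_record <- function(torque, tilt = "center", cfg = sim_config(),
                            seed = cfg$rng_seed, id = "record") {
  if (!is.numeric(torque) || length(torque) != 1L || !is.finite(torque) ||
      torque <= 0) {
    abort_data("`torque` must be a single positive number (Nm).")
  }
  validate_sim_config(cfg)
  sr <- cfg$sampling_rate
  n_pulses <- as.integer(round(cfg$pulse_rate * cfg$record_duration))
  samples_per_pulse <- sr / cfg$pulse_rate
  if (!is_whole(samples_per_pulse)) {
    abort_config("`sampling_rate / pulse_rate` must be a whole number of samples.")
  }
  samples_per_pulse <- as.integer(round(samples_per_pulse))

  m <- seq_len(cfg$n_modes)
  ratios <- cfg$mode_freq_ratios[m]
  sens <- cfg$mode_tilt_sensitivity[m]
  amps <- cfg$mode_amplitudes[m]
  amp_sens <- cfg$mode_amp_tilt_sensitivity[m]
  gammas <- cfg$damping_rates[m]
  f1 <- cfg$torque_freq_intercept + cfg$torque_freq_slope * log(torque)

  with_seed(seed, {
    tilt <- as_tilt_state(tilt, cfg)
    # mode-shape change with tilt: log-linear amplitude response
    amps_t <- amps * exp(amp_sens * tilt$realized_shift / 1000)
    jitter <- stats::rnorm(n_pulses, 0, cfg$pulse_jitter_sd)
    t_pulse <- (seq_len(samples_per_pulse) - 1) / sr
    envelopes <- exp(-outer(t_pulse, gammas)) # samples x modes
    voltage <- vector("list", n_pulses)
    for (p in seq_len(n_pulses)) {
      freqs <- ratios * f1 + sens * (tilt$realized_shift + jitter[p])
      if (any(freqs >= sr / 2)) {
        abort_config(sprintf(
          "Mode frequency %.0f Hz violates the Nyquist limit (%.0f Hz).",
          max(freqs), sr / 2
        ))
      }
      if (any(freqs <= 0)) {
        abort_config("A mode frequency fell below 0 Hz; check tilt shifts and slope.")
      }
      phases <- outer(t_pulse, 2 * pi * freqs)
      voltage[[p]] <- as.vector((envelopes * sin(phases)) %*% amps_t)
    }
    voltage <- unlist(voltage, use.names = FALSE)
    if (cfg$noise_sd > 0) {
      voltage <- voltage + stats::rnorm(length(voltage), 0, cfg$noise_sd)
    }
    acq <- acquisition_config(
      sampling_rate = sr,
      record_duration = cfg$record_duration,
      pulse_rate = cfg$pulse_rate
    )
    new_vibration_record(voltage, acq, id = id, torque_nm = torque, tilt = tilt)
  })
}

#' Simulate a measurement campaign
#'
#' Draws `n` torques log-uniformly across `torque_range` (both endpoints are
#' always included, so downstream fold construction can keep the extremes in
#' the training fold), assigns each measurement a head-tilt direction from
#' `tilt_policy`, and simulates one vibration record per measurement.
#'
#' @param n Number of measurements (>= 2).
#' @param torque_range Length-2 positive interval in Nm.
#' @param tilt_policy Named probability weights over the tilt labels. The
#'   default tilts the head uniformly at random, emulating a campaign in
#'   which the movable head lands in an uncontrolled direction each time.
#' @param cfg A [sim_config()] object.
#' @param seed Master seed; per-record seeds are derived from it.
#'
#' @return A tibble with one row per measurement: `record_id`, `torque_nm`,
#'   `tilt`, `seed`, and a `record` list-column of `lrfa_record` objects.
#' @export
simulate_dataset <- function(n, torque_range = c(0.06, 3),
                             tilt_policy = c(center = 1, horizontal = 1,
                                             vertical = 1, skew = 1),
                             cfg = sim_config(), seed = cfg$rng_seed) {
  if (n < 2) {
    abort_data("`n` must be at least 2 (both torque-range endpoints are included).")
  }
  if (length(torque_range) != 2L || any(torque_range <= 0) ||
      diff(torque_range) < 0) {
    abort_data("`torque_range` must be a positive, non-decreasing length-2 interval.")
  }
  if (is.null(names(tilt_policy)) || !all(names(tilt_policy) %in% tilt_labels)) {
    abort_config("`tilt_policy` must be named with tilt labels.")
  }
  with_seed(seed, {
    interior <- if (n > 2) {
      exp(stats::runif(n - 2, log(torque_range[1]), log(torque_range[2])))
    } else {
      numeric(0)
    }
    torques <- c(torque_range[1], torque_range[2], interior)
    tilts <- sample(names(tilt_policy), n, replace = TRUE,
                    prob = tilt_policy / sum(tilt_policy))
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    ids <- sprintf("r%03d", seq_len(n))
    records <- purrr::pmap(
      list(torques, tilts, seeds, ids),
      function(tq, tl, sd, id) simulate_record(tq, tl, cfg, seed = sd, id = id)
    )
    tibble::tibble(
      record_id = ids,
      torque_nm = torques,
      tilt = tilts,
      seed = seeds,
      record = records
    )
  })
}

#' Write a simulated dataset to plain-text files
#'
#' Writes each record as two-column delimited text (`time_s`, `voltage`), a
#' sidecar `metadata.tsv` (record_id, torque_nm, tilt, seed) and a run-level
#' `config.yaml` holding the simulation parameters.
#'
#' @param dataset A tibble from [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @param cfg The [sim_config()] used, stored for provenance.
#' @return `dir`, invisibly.
#' @export
write_vibration_dataset <- function(dataset, dir, cfg = sim_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(dataset))) {
    readr::write_tsv(
      dataset$record[[i]],
      file.path(dir, paste0(dataset$record_id[i], ".tsv"))
    )
  }
  meta <- dplyr::select(dataset, "record_id", "torque_nm", "tilt", "seed")
  readr::write_tsv(meta, file.path(dir, "metadata.tsv"))
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read one vibration record written by [write_vibration_dataset()]
#'
#' @param path Path to a two-column `time_s`/`voltage` delimited file.
#' @param acquisition An [acquisition_config()] describing the record.
#' @param id Record identifier; defaults to the file name.
#' @return An `lrfa_record` tibble.
#' @export
read_vibration_record <- function(path, acquisition = acquisition_config(),
                                  id = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    time_s = readr::col_double(), voltage = readr::col_double()
  ))
  new_vibration_record(tbl$voltage, acquisition,
                       id = id %||% sub("\\.tsv$", "", basename(path)))
}

#' @importFrom rlang %||%
NULL
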