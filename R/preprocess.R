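#' Acquisition settings of a vibrometer record
#'
#' Describes how a record was digitized: sampling rate, record length, laser
#' pulse repetition rate, and the initial post-pulse interval that is purged
#' before spectral analysis (the early response is dominated by the impact
#' transient rather than the low-order natural frequencies of interest).
#' Defaults match a 2-s record sampled at 0.1 MHz with 10-Hz pulses and a
#' 2-ms purge.
#'
#' @param sampling_rate Samples per second (Hz).
#' @param record_duration Record length (s).
#' @param pulse_rate Pulse repetition rate (Hz).
#' @param purge_duration Leading interval removed from the averaged impulse
#'   response (s); must be shorter than one pulse period.
#' @return A list of class `lrfa_acquisition`.
#' @export
#' @examples
#' acq <- acquisition_config()
#' acq$sampling_rate * acq$record_duration # samples per record
acquisition_config <- function(sampling_rate = 1e5, record_duration = 2,
                               pulse_rate = 10, purge_duration = 0.002) {
  if (sampling_rate <= 0 || record_duration <= 0 || pulse_rate <= 0) {
    abort_config("sampling_rate, record_duration and pulse_rate must be positive.")
  }
  if (!is_whole(sampling_rate * record_duration)) {
    abort_config("`sampling_rate * record_duration` must be a whole sample count.")
  }
  if (purge_duration < 0 || purge_duration >= 1 / pulse_rate) {
    abort_config("`purge_duration` must lie in [0, 1/pulse_rate).")
  }
  structure(
    list(sampling_rate = sampling_rate, record_duration = record_duration,
         pulse_rate = pulse_rate, purge_duration = purge_duration),
    class = "lrfa_acquisition"
  )
}

#' Construct a vibration record
#'
#' Wraps a sampled voltage trace and its acquisition metadata into the
#' tibble-based record type the preprocessing functions operate on.
#'
#' @param voltage Numeric vector of sampled voltages; its length must equal
#'   `sampling_rate * record_duration`.
#' @param acquisition An [acquisition_config()].
#' @param id Record identifier.
#' @param t0 Time of the first sample (s).
#' @param torque_nm,tilt Optional ground-truth metadata carried along.
#' @return A tibble of class `lrfa_record` with columns `time_s`, `voltage`.
#' @export
new_vibration_record <- function(voltage, acquisition = acquisition_config(),
                                 id = "record", t0 = 0,
                                 torque_nm = NULL, tilt = NULL) {
  n_expected <- round(acquisition$sampling_rate * acquisition$record_duration)
  if (length(voltage) != n_expected) {
    abort_data(sprintf(
      "Record '%s' has %d samples; acquisition settings imply %d.",
      id, length(voltage), n_expected
    ))
  }
  out <- tibble::tibble(
    time_s = t0 + (seq_along(voltage) - 1) / acquisition$sampling_rate,
    voltage = as.numeric(voltage)
  )
  structure(out,
            class = c("lrfa_record", class(out)),
            acquisition = acquisition, record_id = id,
            torque_nm = torque_nm, tilt = tilt)
}

record_acquisition <- function(record, acquisition = NULL) {
  acq <- acquisition %||% attr(record, "acquisition")
  if (is.null(acq)) {
    abort_data("No acquisition settings found; pass `acquisition` explicitly.")
  }
  acq
}

#' Split a multi-pulse record into per-pulse segments
#'
#' Cuts the record into `pulse_rate * record_duration` equal segments of one
#' pulse period each, in temporal order. Pulse onsets are assumed to sit at
#' the segment starts (guaranteed for simulated records, where acquisition is
#' synchronized to the laser trigger). Concatenating the segments reproduces
#' the record exactly.
#'
#' @param record An `lrfa_record` (or a tibble with a `voltage` column).
#' @param acquisition Acquisition settings; defaults to the record's own.
#' @return A tibble with columns `pulse` (1-based segment index), `time_s`
#'   (time within the pulse period) and `voltage`.
#' @export
#' @examples
#' cfg <- sim_config(record_duration = 0.2, noise_sd = 0)
#' seg <- segment_pulses(simulate_record(1, "center", cfg, seed = 1))
#' dplyr::count(seg, pulse)
segment_pulses <- function(record, acquisition = NULL) {
  acq <- record_acquisition(record, acquisition)
  voltage <- record$voltage
  n <- length(voltage)
  per_pulse <- acq$sampling_rate / acq$pulse_rate
  if (!is_whole(per_pulse)) {
    abort_data("Samples per pulse period (sampling_rate / pulse_rate) is not a whole number.")
  }
  per_pulse <- as.integer(round(per_pulse))
  n_pulses <- n / per_pulse
  if (!is_whole(n_pulses) || n_pulses < 1) {
    abort_data(sprintf(
      "Record length %d is not a positive multiple of the %d-sample pulse period.",
      n, per_pulse
    ))
  }
  n_pulses <- as.integer(round(n_pulses))
  tibble::tibble(
    pulse = rep(seq_len(n_pulses), each = per_pulse),
    time_s = rep((seq_len(per_pulse) - 1) / acq$sampling_rate, times = n_pulses),
    voltage = voltage
  )
}

#' Average the per-pulse segments into one impulse response
#'
#' Element-wise arithmetic mean across pulses; averaging over the repeated
#' impulse responses suppresses uncorrelated noise by roughly the square
#' root of the pulse count.
#'
#' @param segments Output of [segment_pulses()] (long tibble with `pulse`,
#'   `time_s`, `voltage`).
#' @return A tibble with columns `time_s` and `voltage`, one pulse period
#'   long.
#' @export
average_pulses <- function(segments) {
  if (!all(c("pulse", "voltage") %in% names(segments)) || nrow(segments) == 0) {
    abort_data("`segments` must be a non-empty tibble from segment_pulses().")
  }
  lens <- table(segments$pulse)
  if (length(unique(as.integer(lens))) != 1L) {
    abort_data("Pulse segments have unequal lengths; cannot average.")
  }
  per_pulse <- as.integer(lens[1])
  n_pulses <- length(lens)
  mat <- matrix(segments$voltage, nrow = per_pulse, ncol = n_pulses)
  tibble::tibble(
    time_s = segments$time_s[seq_len(per_pulse)],
    voltage = rowMeans(mat)
  )
}

#' Purge the early post-pulse transient
#'
#' Removes the first `round(purge_duration * sampling_rate)` samples of the
#' averaged impulse response, leaving the remainder untouched, so that the
#' spectrum reflects the freely ringing low-order natural frequencies rather
#' than the broadband impact transient.
#'
#' @param response Tibble with `time_s` and `voltage` (from
#'   [average_pulses()]).
#' @param acquisition An [acquisition_config()]; its `purge_duration` and
#'   `sampling_rate` are used.
#' @return The shortened response tibble.
#' @export
purge_head <- function(response, acquisition = acquisition_config()) {
  n_purge <- as.integer(round(acquisition$purge_duration * acquisition$sampling_rate))
  if (n_purge >= nrow(response)) {
    abort_data("Purge interval is not shorter than the response itself.")
  }
  if (n_purge == 0L) {
    return(response)
  }
  response[-seq_len(n_purge), , drop = FALSE]
}

#' One-sided amplitude spectrum of an impulse response
#'
#' Computes the discrete Fourier transform with a rectangular window (no
#' taper) and returns the one-sided amplitude spectrum: bins from 0 Hz to
#' the Nyquist frequency at resolution `sampling_rate / n`. Intensities are
#' amplitudes, scaled so a unit-amplitude sinusoid at a bin frequency gives
#' a peak intensity of 1 (DC and Nyquist bins carry weight 1, interior bins
#' weight 2). Under this scaling Parseval's identity reads
#' `sum(x^2) = n * (a0^2 + aNyq^2 + sum(interior a^2) / 2)`.
#'
#' @param response Tibble with a `voltage` column (post-purge impulse
#'   response) or a bare numeric vector.
#' @param acquisition An [acquisition_config()]; only `sampling_rate` is
#'   used.
#' @return A tibble of class `lrfa_spectrum` with columns `frequency_hz`,
#'   `intensity` and attribute `resolution` (Hz).
#' @export
#' @examples
#' acq <- acquisition_config(sampling_rate = 1000, record_duration = 1,
#'                           pulse_rate = 1, purge_duration = 0)
#' x <- sin(2 * pi * 50 * (0:999) / 1000)
#' sp <- compute_spectrum(tibble::tibble(voltage = x), acq)
#' sp$frequency_hz[which.max(sp$intensity)]
compute_spectrum <- function(response, acquisition = acquisition_config()) {
  x <- if (is.numeric(response)) response else response$voltage
  n <- length(x)
  if (n == 0) {
    abort_data("Cannot compute a spectrum of an empty response.")
  }
  sr <- acquisition$sampling_rate
  mags <- Mod(stats::fft(x)) / n
  n_keep <- floor(n / 2) + 1L
  weights <- rep(2, n_keep)
  weights[1] <- 1
  if (n %% 2 == 0) weights[n_keep] <- 1
  intensity <- weights * mags[seq_len(n_keep)]
  resolution <- sr / n
  out <- tibble::tibble(
    frequency_hz = (seq_len(n_keep) - 1) * resolution,
    intensity = intensity
  )
  structure(out, class = c("lrfa_spectrum", class(out)),
            resolution = resolution)
}

#' Full preprocessing of one record: segment, average, purge, transform
#'
#' Convenience wrapper running [segment_pulses()], [average_pulses()],
#' [purge_head()] and [compute_spectrum()] in order.
#'
#' @inheritParams segment_pulses
#' @return An `lrfa_spectrum` tibble.
#' @export
preprocess_record <- function(record, acquisition = NULL) {
  acq <- record_acquisition(record, acquisition)
  record |>
    segment_pulses(acq) |>
    average_pulses() |>
    purge_head(acq) |>
    compute_spectrum(acq)
}

#' Write / read a spectrum as two-column delimited text
#'
#' @param spectrum An `lrfa_spectrum`.
#' @param path Output file.
#' @return `path` invisibly (write); an `lrfa_spectrum` (read).
#' @export
write_spectrum <- function(spectrum, path) {
  readr::write_tsv(tibble::as_tibble(spectrum), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    frequency_hz = readr::col_double(), intensity = readr::col_double()
  ))
  res <- if (nrow(tbl) > 1) tbl$frequency_hz[2] - tbl$frequency_hz[1] else NA_real_
  structure(tbl, class = c("lrfa_spectrum", class(tbl)), resolution = res)
}
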