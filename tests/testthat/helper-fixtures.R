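# Small-scale fixtures shared across tests. Short records (a few pulses)
# keep the unit tests fast; the acceptance tests use the full-size settings.

# 0.2-s polyaxial-style configuration: 2 pulses of 10,000 samples each.
small_cfg <- function(...) {
  sim_config("polyaxial", record_duration = 0.2, ...)
}

# Fully deterministic single-mode configuration (no tilt spread, no pulse
# wobble, no noise): the spectral peak must sit at the closed-form mode
# frequency.
clean_cfg <- function(...) {
  sim_config("polyaxial", record_duration = 0.2, n_modes = 1,
             tilt_jitter_sd = 0, pulse_jitter_sd = 0, noise_sd = 0, ...)
}

small_acq <- function() {
  acquisition_config(record_duration = 0.2)
}

# Deterministic synthetic feature table: one informative column (a noisy
# copy of the objective) among independent noise columns.
informative_table <- function(n = 60, n_noise = 10, seed = 42,
                              signal_sd = 0.1) {
  withr::with_seed(seed, {
    y <- rnorm(n)
    tbl <- tibble::tibble(measurement_id = sprintf("m%02d", seq_len(n)))
    tbl$signal <- y + rnorm(n, 0, signal_sd)
    for (j in seq_len(n_noise)) {
      tbl[[paste0("noise", j)]] <- rnorm(n)
    }
    tbl$peak_torque_nm <- y
    tbl
  })
}

# Independent brute-force spectral-moment oracles, written directly from
# the moment formulas (no shared code with the package).
oracle_dispersion <- function(x) {
  n <- length(x)
  sum((x - sum(x) / n)^2) / n
}

oracle_kurtosis <- function(x) {
  n <- length(x)
  xbar <- sum(x) / n
  s <- sqrt(sum((x - xbar)^2) / (n - 1))
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum((x - xbar)^4) / s^4 -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

oracle_skewness <- function(x) {
  n <- length(x)
  xbar <- sum(x) / n
  s <- sqrt(sum((x - xbar)^2) / (n - 1))
  n / ((n - 1) * (n - 2)) * sum(((x - xbar) / s)^3)
}

# O(N^2) discrete Fourier transform magnitude, one-sided amplitude scaling.
oracle_dft_amplitude <- function(x) {
  n <- length(x)
  ks <- 0:(floor(n / 2))
  vapply(ks, function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    w <- if (k == 0 || (n %% 2 == 0 && k == n / 2)) 1 else 2
    w * sqrt(re^2 + im^2) / n
  }, numeric(1))
}

spectrum_peak <- function(spectrum) {
  spectrum$frequency_hz[which.max(spectrum$intensity)]
}
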