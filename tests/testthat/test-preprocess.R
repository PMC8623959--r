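test_that("segmentation splits a record into whole pulse periods", {
  # 0.2 s at 100 kHz with 10-Hz pulses: 2 segments of 10,000 samples
  rec <- simulate_record(1, "center", small_cfg(), seed = 1)
  seg <- segment_pulses(rec)
  expect_equal(sort(unique(seg$pulse)), 1:2)
  expect_equal(sum(seg$pulse == 1), 10000)
  # concatenation reproduces the record
  expect_identical(seg$voltage, rec$voltage)
})

test_that("a one-pulse record segments to itself", {
  acq <- acquisition_config(sampling_rate = 1000, record_duration = 0.1,
                            pulse_rate = 10)
  rec <- new_vibration_record(rnorm(100), acq)
  seg <- segment_pulses(rec)
  expect_equal(unique(seg$pulse), 1L)
  expect_identical(seg$voltage, rec$voltage)
})

test_that("segment boundaries follow index arithmetic on a ramp", {
  n <- 200
  acq <- acquisition_config(sampling_rate = 1000, record_duration = 0.2,
                            pulse_rate = 10)
  rec <- new_vibration_record(seq_len(n) - 1, acq)
  seg <- segment_pulses(rec)
  # hand-sliced oracle: segment 2 starts at sample n/2
  expect_equal(seg$voltage[seg$pulse == 2][1], n / 2)
  expect_equal(seg$voltage[seg$pulse == 1], 0:(n / 2 - 1))
})

test_that("segmentation rejects records not divisible into pulses", {
  acq <- acquisition_config(sampling_rate = 1000, record_duration = 0.1,
                            pulse_rate = 10)
  rec <- new_vibration_record(rnorm(100), acq)
  # 1000 / 7 samples per pulse period is not a whole number
  bad_acq <- acquisition_config(sampling_rate = 1000, record_duration = 0.1,
                                pulse_rate = 7)
  expect_error(segment_pulses(rec, bad_acq), class = "lrfa_data_error")
})

test_that("averaging is the element-wise mean", {
  acq <- acquisition_config(sampling_rate = 100, record_duration = 0.1,
                            pulse_rate = 10)
  one <- segment_pulses(new_vibration_record(rnorm(10), acq))
  expect_equal(average_pulses(one)$voltage, one$voltage)

  s <- rnorm(10)
  seg <- tibble::tibble(pulse = rep(1:2, each = 10),
                        time_s = rep((0:9) / 100, 2),
                        voltage = c(s, -s))
  expect_equal(average_pulses(seg)$voltage, rep(0, 10))

  ragged <- seg[-1, ]
  expect_error(average_pulses(ragged), class = "lrfa_data_error")
})

test_that("averaging 20 noisy copies shrinks noise like 1/sqrt(20)", {
  withr::with_seed(314, {
    base <- sin(2 * pi * 50 * (0:999) / 1e4)
    sigma <- 0.3
    n_rep <- 20
    seg <- tibble::tibble(
      pulse = rep(seq_len(n_rep), each = 1000),
      time_s = rep((0:999) / 1e4, n_rep),
      voltage = rep(base, n_rep) + rnorm(1000 * n_rep, 0, sigma)
    )
    resid <- average_pulses(seg)$voltage - base
    se <- sigma / sqrt(n_rep)
    # the residual sd estimate itself has standard error ~ se / sqrt(2n)
    expect_lt(abs(sd(resid) - se), 3 * se / sqrt(2 * 1000))
  })
})

test_that("purging removes exactly the configured leading samples", {
  acq <- acquisition_config() # 2 ms at 100 kHz -> 200 samples
  resp <- tibble::tibble(time_s = (0:9999) / 1e5, voltage = rnorm(10000))
  purged <- purge_head(resp, acq)
  expect_equal(nrow(purged), 9800)
  expect_identical(purged$voltage, resp$voltage[-(1:200)])

  zero <- acquisition_config(purge_duration = 0)
  expect_identical(purge_head(resp, zero), resp)

  const <- tibble::tibble(time_s = resp$time_s, voltage = rep(1, 10000))
  expect_true(all(purge_head(const, acq)$voltage == 1))

  tiny <- tibble::tibble(time_s = (0:99) / 1e5, voltage = rnorm(100))
  expect_error(purge_head(tiny, acq), class = "lrfa_data_error")
})

test_that("the spectrum matches a brute-force DFT oracle", {
  withr::with_seed(7, {
    x <- rnorm(64)
    acq <- acquisition_config(sampling_rate = 64, record_duration = 1,
                              pulse_rate = 1, purge_duration = 0)
    sp <- compute_spectrum(x, acq)
    expect_equal(sp$intensity, oracle_dft_amplitude(x), tolerance = 1e-9)
    expect_equal(sp$frequency_hz, 0:32)
  })
})

test_that("pure tones and constants land in the right bins", {
  acq <- acquisition_config(sampling_rate = 1e5, record_duration = 0.01,
                            pulse_rate = 100, purge_duration = 0)
  t <- (0:999) / 1e5
  sp <- compute_spectrum(sin(2 * pi * 1000 * t), acq)
  expect_equal(spectrum_peak(sp), 1000)
  expect_equal(max(sp$intensity), 1, tolerance = 1e-6)

  spc <- compute_spectrum(rep(2, 1000), acq)
  expect_equal(spectrum_peak(spc), 0)
  expect_equal(spc$intensity[1], 2, tolerance = 1e-12)
  expect_lt(max(spc$intensity[-1]), 1e-10)

  expect_error(compute_spectrum(numeric(0), acq), class = "lrfa_data_error")
})

test_that("preprocessing is linear in the input amplitude", {
  cfg <- small_cfg()
  rec <- simulate_record(1, "center", cfg, seed = 9)
  acq <- attr(rec, "acquisition")
  scaled <- new_vibration_record(3.5 * rec$voltage, acq)
  sp1 <- preprocess_record(rec, acq)
  sp2 <- preprocess_record(scaled, acq)
  expect_equal(sp2$intensity, 3.5 * sp1$intensity, tolerance = 1e-9)
})

test_that("Parseval's identity holds under the documented scaling", {
  withr::with_seed(11, {
    for (n in c(64, 101)) { # even and odd lengths
      x <- rnorm(n)
      acq <- acquisition_config(sampling_rate = n, record_duration = 1,
                                pulse_rate = 1, purge_duration = 0)
      sp <- compute_spectrum(x, acq)
      a <- sp$intensity
      w <- rep(2, length(a)); w[1] <- 1
      if (n %% 2 == 0) w[length(a)] <- 1
      # sum(x^2) = n * sum(a^2 / w): DC/Nyquist enter once, others twice
      expect_equal(sum(x^2), n * sum(a^2 / w), tolerance = 1e-9)
    }
  })
})
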