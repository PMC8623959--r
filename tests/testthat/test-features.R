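make_spectrum <- function(frequency_hz, intensity) {
  structure(tibble::tibble(frequency_hz = frequency_hz, intensity = intensity),
            class = c("lrfa_spectrum", "tbl_df", "tbl", "data.frame"),
            resolution = frequency_hz[2] - frequency_hz[1])
}

test_that("band slicing keeps exactly the half-open interval", {
  sp <- make_spectrum(seq(0, 50000, by = 10), rep(1, 5001))
  whole <- band_slice(sp, 0, 50001)
  expect_equal(nrow(whole), 5001)
  sub <- band_slice(sp, 1000, 5000)
  expect_equal(sub$frequency_hz, seq(1000, 4990, by = 10))
  expect_error(band_slice(sp, 60000, 70000), class = "lrfa_data_error")
  expect_error(band_slice(sp, 60000, 70000), "60000-70000")
})

test_that("band presets produce the documented column counts", {
  expect_equal(nrow(band_scheme("monoaxial")), 8)
  expect_equal(nrow(band_scheme("polyaxial")), 6)
  sp <- make_spectrum(seq(0, 50000, by = 10), runif(5001) + 0.1)
  ft_mono <- build_feature_table(list(sp), 1, band_scheme("monoaxial"))
  expect_length(explanatory_columns(ft_mono), 64)
  ft_poly <- build_feature_table(list(sp), 1, band_scheme("polyaxial"))
  expect_length(explanatory_columns(ft_poly), 48)
  one_band <- band_scheme("custom",
                          bands = tibble::tibble(low_hz = 0, high_hz = 50001))
  expect_length(explanatory_columns(build_feature_table(list(sp), 1, one_band)), 8)
})

test_that("single-bin and flat bands hit their degenerate contracts", {
  single <- make_spectrum(c(100, 200), c(2, 0))[1, ]
  feats <- suppressWarnings(extract_band_features(single))
  expect_equal(feats$peak_frequency, 100)
  expect_equal(feats$peak_intensity, 2)
  expect_equal(feats$centroid_frequency, 100)
  expect_equal(feats$centroid_intensity, 2)
  expect_equal(feats$average_intensity, 2)
  expect_equal(feats$dispersion, 0)

  flat <- make_spectrum(seq(100, 140, 10), rep(1, 5))
  expect_warning(f2 <- extract_band_features(flat),
                 class = "lrfa_degenerate_moment")
  expect_equal(f2$dispersion, 0)
  expect_equal(f2$kurtosis, 0)
  expect_equal(f2$skewness, 0)
})

test_that("moment features match independent formula oracles", {
  x <- c(1, 2, 3, 4, 5, 6)
  sub <- make_spectrum(seq(100, 150, 10), x)
  feats <- extract_band_features(sub)
  expect_equal(feats$dispersion, oracle_dispersion(x), tolerance = 1e-12)
  expect_equal(feats$kurtosis, oracle_kurtosis(x), tolerance = 1e-12)
  expect_equal(feats$skewness, oracle_skewness(x), tolerance = 1e-12)

  withr::with_seed(5, {
    for (i in 1:20) {
      xi <- runif(sample(4:40, 1))
      si <- make_spectrum(seq_along(xi) * 10, xi)
      fi <- extract_band_features(si)
      expect_equal(fi$dispersion, oracle_dispersion(xi), tolerance = 1e-12)
      expect_equal(fi$kurtosis, oracle_kurtosis(xi), tolerance = 1e-12)
      expect_equal(fi$skewness, oracle_skewness(xi), tolerance = 1e-12)
    }
  })
})

test_that("peak ties break toward the lowest frequency", {
  sub <- make_spectrum(c(100, 110, 120, 130), c(1, 5, 5, 2))
  expect_equal(extract_band_features(sub)$peak_frequency, 110)
})

test_that("features scale correctly under intensity rescaling", {
  withr::with_seed(9, {
    x <- runif(30) + 0.05
    sub <- make_spectrum(seq(1000, 1290, 10), x)
    scaled <- make_spectrum(seq(1000, 1290, 10), 4 * x)
    f1 <- extract_band_features(sub)
    f4 <- extract_band_features(scaled)
    for (nm in c("peak_intensity", "centroid_intensity", "average_intensity")) {
      expect_equal(f4[[nm]], 4 * f1[[nm]], tolerance = 1e-12)
    }
    expect_equal(f4$dispersion, 16 * f1$dispersion, tolerance = 1e-12)
    for (nm in c("peak_frequency", "centroid_frequency", "kurtosis", "skewness")) {
      expect_equal(f4[[nm]], f1[[nm]], tolerance = 1e-9)
    }
  })
})

test_that("the centroid frequency is bounded by the band support", {
  withr::with_seed(13, {
    for (i in 1:10) {
      x <- runif(25)
      sub <- make_spectrum(seq(500, 740, 10), x)
      cf <- extract_band_features(sub)$centroid_frequency
      expect_gte(cf, 500)
      expect_lte(cf, 740)
    }
  })
})

test_that("a mirrored-ramp intensity profile has zero skewness", {
  # value multiset symmetric about its mean
  x <- c(1, 2, 3, 4, 4, 3, 2, 1)
  sub <- make_spectrum(seq(100, 170, 10), x)
  expect_lt(abs(extract_band_features(sub)$skewness), 1e-9)
})

test_that("feature tables keep ids, order and the objective column", {
  sp <- make_spectrum(seq(0, 50000, by = 10), runif(5001) + 0.1)
  ft <- build_feature_table(list(sp, sp), c(1.5, 2.5), band_scheme("polyaxial"),
                            ids = c("a", "b"))
  expect_equal(names(ft)[1], "measurement_id")
  expect_equal(names(ft)[ncol(ft)], "peak_torque_nm")
  expect_equal(ft$peak_torque_nm, c(1.5, 2.5))
  scheme <- band_scheme("polyaxial")
  expected <- paste0(rep(scheme$band_label, each = 8), ":", feature_names())
  expect_equal(explanatory_columns(ft), expected)

  # failures are attributed to measurement and band
  narrow <- make_spectrum(seq(0, 1000, by = 10), rep(1, 101))
  expect_error(
    build_feature_table(list(narrow), 1, band_scheme("polyaxial"), ids = "bad"),
    "bad.*1500-6500|1500-6500.*bad"
  )
})

test_that("feature tables round-trip through the text format", {
  sp <- make_spectrum(seq(0, 50000, by = 10), runif(5001) + 0.1)
  ft <- build_feature_table(list(sp), 1.5, band_scheme("polyaxial"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ft), tolerance = 1e-12,
               ignore_attr = TRUE)
})
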