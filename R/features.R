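#' Frequency-band schemes for feature extraction
#'
#' Returns the ordered set of analysis bands over which the eight spectral
#' features are extracted. Two presets are built in, chosen manually so that
#' the characteristic resonance peaks of each screw type fall in separate
#' bands:
#' * `"monoaxial"` — 30–150, 150–500, 500–1000, 1000–5000, 5000–10000,
#'   10000–15000, 15000–20000 and the whole-range 30–20000 Hz band
#'   (8 bands, 64 features);
#' * `"polyaxial"` — 0–1500, 1500–6500, 6500–11500, 11500–15000,
#'   15000–25000 and the whole-range 0–25000 Hz band (6 bands, 48 features).
#'
#' Bands are half-open intervals `[low, high)`; the whole-range band
#' deliberately overlaps the sub-bands.
#'
#' @param preset `"monoaxial"`, `"polyaxial"`, or `"custom"` together with
#'   `bands`.
#' @param bands For a custom scheme: a data frame with columns `low_hz` and
#'   `high_hz` (and optionally `band_label`).
#' @return A tibble of class `lrfa_band_scheme` with columns `band_label`,
#'   `low_hz`, `high_hz`, and attribute `preset_name`.
#' @export
#' @examples
#' band_scheme("polyaxial")
band_scheme <- function(preset = c("monoaxial", "polyaxial", "custom"),
                        bands = NULL) {
  preset <- match.arg(preset)
  if (preset == "monoaxial") {
    bands <- tibble::tibble(
      low_hz  = c(30, 150, 500, 1000, 5000, 10000, 15000, 30),
      high_hz = c(150, 500, 1000, 5000, 10000, 15000, 20000, 20000)
    )
  } else if (preset == "polyaxial") {
    bands <- tibble::tibble(
      low_hz  = c(0, 1500, 6500, 11500, 15000, 0),
      high_hz = c(1500, 6500, 11500, 15000, 25000, 25000)
    )
  } else if (is.null(bands)) {
    abort_config("A custom scheme needs a `bands` data frame.")
  }
  bands <- tibble::as_tibble(bands)
  if (!all(c("low_hz", "high_hz") %in% names(bands)) || nrow(bands) < 1) {
    abort_config("`bands` must have columns low_hz and high_hz and at least one row.")
  }
  if (any(bands$low_hz < 0) || any(bands$low_hz >= bands$high_hz)) {
    abort_config("Each band needs 0 <= low_hz < high_hz.")
  }
  if (!"band_label" %in% names(bands)) {
    bands$band_label <- sprintf("%g-%g", bands$low_hz, bands$high_hz)
  }
  bands <- bands[, c("band_label", "low_hz", "high_hz")]
  structure(bands, class = c("lrfa_band_scheme", class(bands)),
            preset_name = preset)
}

#' Names of the eight per-band spectral features, in output order
#' @return Character vector of length 8.
#' @export
feature_names <- function() {
  c("peak_frequency", "peak_intensity", "centroid_frequency",
    "centroid_intensity", "average_intensity", "dispersion",
    "kurtosis", "skewness")
}

#' Restrict a spectrum to one frequency band
#'
#' Keeps the bins with `low <= frequency < high`, preserving order.
#'
#' @param spectrum An `lrfa_spectrum` (tibble with `frequency_hz`,
#'   `intensity`).
#' @param low,high Band edges in Hz (half-open interval).
#' @param label Band name used in error messages.
#' @return The sub-spectrum tibble.
#' @export
band_slice <- function(spectrum, low, high, label = sprintf("%g-%g", low, high)) {
  keep <- spectrum$frequency_hz >= low & spectrum$frequency_hz < high
  if (!any(keep)) {
    abort_data(sprintf("Band %s Hz contains no spectrum bins.", label))
  }
  spectrum[keep, , drop = FALSE]
}

# Bias-adjusted excess kurtosis:
# K = n(n+1)/((n-1)(n-2)(n-3)) * sum(((x - xbar)/s)^4) - 3(n-1)^2/((n-2)(n-3))
# with s the sample (n-1) standard deviation. Degenerate for n < 4 or s = 0.
adjusted_kurtosis <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  if (n < 4 || s == 0) {
    return(NA_real_)
  }
  n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(((x - mean(x)) / s)^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
}

# Bias-adjusted skewness: S = n/((n-1)(n-2)) * sum(((x - xbar)/s)^3).
adjusted_skewness <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  if (n < 3 || s == 0) {
    return(NA_real_)
  }
  n / ((n - 1) * (n - 2)) * sum(((x - mean(x)) / s)^3)
}

#' Extract the eight spectral features of one band
#'
#' From the intensities \eqn{x_i} of the \eqn{n} bins in a band, computes:
#' peak frequency and peak intensity (maximum-intensity bin, ties broken
#' toward the lowest frequency); centroid frequency
#' \eqn{\sum f_i x_i / \sum x_i} and the intensity linearly interpolated at
#' it (centroid intensity); average intensity \eqn{\bar x}; dispersion
#' \eqn{V = \frac{1}{n}\sum (x_i - \bar x)^2} (population form);
#' bias-adjusted excess kurtosis \eqn{K}; and bias-adjusted skewness
#' \eqn{S}. \eqn{K} and \eqn{S} standardize by the sample (n−1) standard
#' deviation \eqn{s}; when they are undefined (fewer than 4 bins or
#' \eqn{s = 0}, i.e. a flat band with no shape information) they are emitted
#' as 0 with a warning of class `lrfa_degenerate_moment` so downstream
#' matrices stay complete.
#'
#' @param sub A sub-spectrum from [band_slice()].
#' @param centroid_intensity_method `"interpolate"` (default) evaluates the
#'   intensity at the centroid frequency by linear interpolation between the
#'   neighbouring bins; `"nearest"` takes the nearest bin's intensity.
#' @return A named list of the eight feature values, in [feature_names()]
#'   order.
#' @export
#' @examples
#' sp <- tibble::tibble(frequency_hz = c(100, 110, 120),
#'                      intensity = c(1, 3, 1))
#' extract_band_features(sp)$centroid_frequency
extract_band_features <- function(sub,
                                  centroid_intensity_method = c("interpolate", "nearest")) {
  centroid_intensity_method <- match.arg(centroid_intensity_method)
  f <- sub$frequency_hz
  x <- sub$intensity
  n <- length(x)
  if (n < 1) {
    abort_data("Band contains no bins.")
  }
  i_peak <- which.max(x) # which.max returns the first (lowest-frequency) tie
  total <- sum(x)
  centroid_f <- if (total > 0) sum(f * x) / total else mean(f)
  centroid_i <- if (n == 1) {
    x[1]
  } else if (centroid_intensity_method == "interpolate") {
    stats::approx(f, x, xout = centroid_f, rule = 2)$y
  } else {
    x[which.min(abs(f - centroid_f))]
  }
  xbar <- mean(x)
  v <- mean((x - xbar)^2)
  k <- adjusted_kurtosis(x)
  s <- adjusted_skewness(x)
  if (is.na(k) || is.na(s)) {
    rlang::warn(
      sprintf("Degenerate kurtosis/skewness in band %g-%g Hz (n = %d, flat = %s); emitting 0.",
              min(f), max(f), n, identical(stats::sd(x), 0)),
      class = "lrfa_degenerate_moment"
    )
    if (is.na(k)) k <- 0
    if (is.na(s)) s <- 0
  }
  list(
    peak_frequency = f[i_peak],
    peak_intensity = x[i_peak],
    centroid_frequency = centroid_f,
    centroid_intensity = centroid_i,
    average_intensity = xbar,
    dispersion = v,
    kurtosis = k,
    skewness = s
  )
}

#' Build the explanatory-variable table from spectra
#'
#' Extracts the eight features in every band of `scheme` for each spectrum,
#' yielding `8 * nrow(scheme)` explanatory columns named
#' `"<band_label>:<feature_name>"`, preceded by `measurement_id` and
#' followed by the objective column `peak_torque_nm`.
#'
#' @param spectra A list of `lrfa_spectrum` objects, or a tibble with a
#'   `spectrum` list-column plus `torque_nm` (and optionally `record_id`).
#' @param torques Numeric vector of peak torques (Nm), one per spectrum
#'   (ignored when `spectra` is a tibble carrying `torque_nm`).
#' @param scheme A [band_scheme()].
#' @param ids Optional measurement identifiers.
#' @param centroid_intensity_method Passed to [extract_band_features()].
#' @return A tibble of class `lrfa_feature_table`.
#' @export
build_feature_table <- function(spectra, torques = NULL,
                                scheme = band_scheme("polyaxial"),
                                ids = NULL,
                                centroid_intensity_method = "interpolate") {
  if (is.data.frame(spectra)) {
    ids <- ids %||% spectra[["record_id"]]
    torques <- torques %||% spectra[["torque_nm"]]
    spectra <- spectra[["spectrum"]] %||% spectra[["record"]]
  }
  if (length(spectra) < 1) {
    abort_data("Need at least one measurement.")
  }
  if (is.null(torques) || length(torques) != length(spectra) ||
      anyNA(torques)) {
    abort_data("`torques` must match the spectra with no missing values.")
  }
  ids <- ids %||% sprintf("m%03d", seq_along(spectra))
  degenerate <- 0L
  rows <- purrr::map(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    feats <- purrr::pmap(
      list(scheme$band_label, scheme$low_hz, scheme$high_hz),
      function(lab, lo, hi) {
        vals <- tryCatch(
          withCallingHandlers(
            extract_band_features(band_slice(sp, lo, hi, lab),
                                  centroid_intensity_method),
            lrfa_degenerate_moment = function(w) {
              degenerate <<- degenerate + 1L
              rlang::cnd_muffle(w)
            }
          ),
          lrfa_data_error = function(e) {
            abort_data(sprintf("Measurement '%s', band %s: %s",
                               ids[i], lab, conditionMessage(e)))
          }
        )
        rlang::set_names(vals, paste0(lab, ":", feature_names()))
      }
    )
    tibble::as_tibble(purrr::flatten(feats))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(
    tibble::tibble(measurement_id = ids),
    out,
    tibble::tibble(peak_torque_nm = torques)
  )
  if (degenerate > 0) {
    rlang::warn(sprintf(
      "%d band(s) had degenerate kurtosis/skewness (emitted as 0).", degenerate
    ), class = "lrfa_degenerate_summary")
  }
  structure(out, class = c("lrfa_feature_table", class(out)),
            scheme = scheme)
}

#' Explanatory-variable column names of a feature table
#' @param table An `lrfa_feature_table` (or compatible tibble).
#' @return Character vector of explanatory column names.
#' @export
explanatory_columns <- function(table) {
  setdiff(names(table), c("measurement_id", "peak_torque_nm"))
}

#' Write / read a feature table as delimited text
#'
#' Columns: `measurement_id`, the explanatory variables in deterministic
#' band-then-feature order, then `peak_torque_nm`.
#'
#' @param table An `lrfa_feature_table`.
#' @param path Output file.
#' @return `path` invisibly (write); a feature-table tibble (read).
#' @export
write_feature_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    measurement_id = readr::col_character(),
    .default = readr::col_double()
  ))
  structure(tbl, class = c("lrfa_feature_table", class(tbl)))
}
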