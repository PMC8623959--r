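#' End-to-end synthetic demonstration of the diagnosis pipeline
#'
#' Runs the full analysis chain on simulated polyaxial-screw data:
#' simulate a measurement campaign, preprocess every record into an
#' amplitude spectrum, extract the band features, rank them by
#' bootstrap-Lasso, build torque-stratified folds, train the SVR on folds 1
#' and 2 with the top-ranked variables, and validate on fold 3. The
#' conventional log-fit peak-frequency baseline is fitted on the same
#' training rows and inverted to predict the validation torques, so the two
#' approaches are compared on an identical split.
#'
#' A single `seed` deterministically derives the per-stage seeds
#' (simulation, resampling, SVR tuning), so the whole experiment is
#' reproducible from one integer.
#'
#' @param seed Master seed.
#' @param n Number of simulated measurements.
#' @param torque_range Torque interval (Nm) of the campaign.
#' @param sim_cfg A [sim_config()]; its `rng_seed` is overridden by the
#'   derived stage seed.
#' @param scheme A [band_scheme()].
#' @param lasso_cfg A [lasso_config()]; its `rng_seed` is overridden.
#' @param svr_cfg An [svr_config()]; its `rng_seed` is overridden.
#' @param top_k Number of top-ranked variables used by the SVR.
#' @param validation_fold Which fold to hold out (default 3).
#'
#' @return A list of class `lrfa_demo`: `measurements` (tibble with torque,
#'   tilt, fold, peak frequency, predictions), `feature_table`, `selection`,
#'   `model`, `evaluation` (held-out fold), `baseline` (log fit on training
#'   rows), `baseline_evaluation` (inverted baseline on the held-out fold),
#'   `baseline_fit_all` (log fit over the whole campaign), and `seeds`.
#' @export
#' @examples
#' \donttest{
#' demo <- run_full_demo(seed = 1, n = 12,
#'                       sim_cfg = sim_config(record_duration = 0.5),
#'                       lasso_cfg = lasso_config(n_bootstrap = 50),
#'                       svr_cfg = svr_config(grid_step_exponent = 8))
#' glance(demo$evaluation)
#' }
run_full_demo <- function(seed = 1,
                          n = 57,
                          torque_range = c(0.06, 3),
                          sim_cfg = sim_config("polyaxial"),
                          scheme = band_scheme("polyaxial"),
                          lasso_cfg = lasso_config(),
                          svr_cfg = svr_config(),
                          top_k = lasso_cfg$top_k,
                          validation_fold = 3) {
  seeds <- demo_seeds(seed)

  dataset <- simulate_dataset(n, torque_range, cfg = sim_cfg,
                              seed = seeds[["simulate"]])
  spectra <- purrr::map(dataset$record, preprocess_record)
  feature_table <- build_feature_table(spectra, dataset$torque_nm,
                                       scheme = scheme,
                                       ids = dataset$record_id)

  norm <- normalize_columns(feature_table)
  lasso_cfg$rng_seed <- seeds[["select"]]
  selection <- bootstrap_lasso(norm$data, lasso_cfg)
  variables <- take_top_k(selection, min(top_k, length(selection$ranked_variables)))

  folds <- assign_folds(feature_table$peak_torque_nm)
  train_rows <- folds != validation_fold
  svr_cfg$rng_seed <- seeds[["train"]]
  model <- train_svr(feature_table[train_rows, ], variables, svr_cfg)
  predicted <- suppressWarnings(predict(model, feature_table[!train_rows, ]))
  evaluation <- evaluate_predictions(
    feature_table$peak_torque_nm[!train_rows], predicted
  )

  # conventional single-variable diagnosis on the same split
  peak_freq <- vapply(spectra, function(sp) sp$frequency_hz[which.max(sp$intensity)],
                      numeric(1))
  baseline <- fit_log_baseline(dataset$torque_nm[train_rows], peak_freq[train_rows])
  baseline_pred <- predict(baseline, peak_freq[!train_rows])
  baseline_evaluation <- evaluate_predictions(
    dataset$torque_nm[!train_rows], baseline_pred
  )
  baseline_fit_all <- fit_log_baseline(dataset$torque_nm, peak_freq)

  measurements <- tibble::tibble(
    record_id = dataset$record_id,
    torque_nm = dataset$torque_nm,
    tilt = dataset$tilt,
    fold = folds,
    peak_frequency_hz = peak_freq
  )
  measurements$svr_predicted_nm <- NA_real_
  measurements$svr_predicted_nm[!train_rows] <- predicted
  measurements$baseline_predicted_nm <- NA_real_
  measurements$baseline_predicted_nm[!train_rows] <- baseline_pred

  structure(
    list(measurements = measurements,
         feature_table = feature_table,
         selection = selection,
         variables = variables,
         model = model,
         evaluation = evaluation,
         baseline = baseline,
         baseline_evaluation = baseline_evaluation,
         baseline_fit_all = baseline_fit_all,
         validation_fold = validation_fold,
         seeds = seeds),
    class = "lrfa_demo"
  )
}

# One master seed -> named per-stage seeds (all < 2^31).
demo_seeds <- function(seed) {
  s <- derive_seeds(seed, 3)
  c(simulate = s[1], select = s[2], train = s[3])
}

#' @export
print.lrfa_demo <- function(x, ...) {
  cat(sprintf("Synthetic L-RFA demonstration (%d measurements, fold %d held out)\n",
              nrow(x$measurements), x$validation_fold))
  cat("SVR:      "); print(x$evaluation)
  cat("Baseline: "); print(x$baseline_evaluation)
  cat(sprintf("Log fit over all measurements: R^2 = %.3f\n", x$baseline_fit_all$r2))
  invisible(x)
}

#' @rdname glance.lrfa_selection
#' @export
glance.lrfa_demo <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$evaluation),
    tibble::tibble(
      baseline_r2 = x$baseline_evaluation$metrics$r2,
      baseline_fit_all_r2 = x$baseline_fit_all$r2,
      chosen_lambda = x$selection$chosen_lambda,
      mean_variables_per_trial = x$selection$mean_variables_per_trial
    )
  )
}
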