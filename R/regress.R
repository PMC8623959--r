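#' Configuration of the SVR torque predictor
#'
#' Hyperparameters of the epsilon-insensitive support vector regression with
#' a Gaussian (RBF) kernel, tuned by exhaustive grid search over
#' power-of-two grids: epsilon over `2^-20 .. 2^9`, cost C over
#' `2^-10 .. 2^10` and kernel width gamma over `2^-15 .. 2^9`, stepping the
#' exponent by `grid_step_exponent`. Each candidate triple is scored by the
#' mean determination coefficient over an internal seeded k-fold split of
#' the training rows.
#'
#' @param grid_step_exponent Integer step between consecutive exponents
#'   (default 1; larger values coarsen the grid for quick runs).
#' @param epsilon_grid,cost_grid,gamma_grid Explicit grids overriding the
#'   power-of-two defaults.
#' @param cv_folds_for_tuning Internal folds used to score candidates
#'   (default 3).
#' @param objective_scale `"log"` (default) regresses the z-scored natural
#'   logarithm of peak torque and exponentiates predictions back to Nm;
#'   `"linear"` regresses z-scored torque directly. The log scale flattens
#'   the objective's 1.5+ orders of magnitude, matches the logarithmic
#'   frequency-torque law, and makes the epsilon-insensitive loss act on
#'   relative error — the scale on which accuracy is judged.
#' @param rng_seed Seed for the internal fold split.
#' @return A list of class `lrfa_svr_config`.
#' @export
svr_config <- function(grid_step_exponent = 1,
                       epsilon_grid = NULL,
                       cost_grid = NULL,
                       gamma_grid = NULL,
                       cv_folds_for_tuning = 3,
                       objective_scale = c("log", "linear"),
                       rng_seed = 1L) {
  if (grid_step_exponent < 1) abort_config("`grid_step_exponent` must be >= 1.")
  objective_scale <- match.arg(objective_scale)
  cfg <- list(
    epsilon_grid = epsilon_grid %||% 2^seq(-20, 9, by = grid_step_exponent),
    cost_grid = cost_grid %||% 2^seq(-10, 10, by = grid_step_exponent),
    gamma_grid = gamma_grid %||% 2^seq(-15, 9, by = grid_step_exponent),
    grid_step_exponent = grid_step_exponent,
    cv_folds_for_tuning = cv_folds_for_tuning,
    objective_scale = objective_scale,
    rng_seed = rng_seed
  )
  if (any(cfg$epsilon_grid <= 0) || any(cfg$cost_grid <= 0) ||
      any(cfg$gamma_grid <= 0)) {
    abort_config("All hyperparameter grid values must be positive.")
  }
  structure(cfg, class = "lrfa_svr_config")
}

#' Torque-stratified three-fold assignment
#'
#' Builds validation folds so that no fold requires extrapolation: the
#' measurements with the minimum and the maximum torque always go to fold 1
#' (the fold used only for training), and the remaining measurements,
#' sorted by torque, are dealt out in consecutive triplets — the j-th,
#' (j+1)-th and (j+2)-th sorted measurements going one to each fold — so
#' each fold spans the torque range evenly. Ties in torque are broken by
#' input order.
#'
#' @param torques Numeric vector of peak torques (Nm), length >= 5.
#' @param n_folds Number of folds (default 3).
#' @return Integer vector of fold indices (1..n_folds) in input order.
#' @export
#' @examples
#' assign_folds(c(0.1, 0.5, 1, 2, 3))
assign_folds <- function(torques, n_folds = 3) {
  n <- length(torques)
  if (n < 5) abort_data("Need at least 5 measurements to build folds.")
  ord <- order(torques) # stable: ties keep input order
  folds <- integer(n)
  folds[ord[1]] <- 1L
  folds[ord[n]] <- 1L
  middle <- ord[seq(2, n - 1)]
  folds[middle] <- rep_len(seq_len(n_folds), length(middle))
  folds
}

r_squared <- function(truth, predicted) {
  sst <- sum((truth - mean(truth))^2)
  if (sst == 0) {
    return(NA_real_)
  }
  1 - sum((truth - predicted)^2) / sst
}

#' Train the SVR torque predictor
#'
#' Normalizes the selected explanatory columns and the objective to zero
#' mean and unit variance (statistics from the training rows only; the
#' objective is optionally log-transformed first, see
#' [svr_config()]'s `objective_scale`), runs an exhaustive grid search over
#' the configured power-of-two (epsilon, C, gamma) grids — scoring each
#' triple by mean determination coefficient over an internal seeded k-fold
#' split — and refits the best triple on all training rows.
#'
#' @param table An `lrfa_feature_table` of training measurements.
#' @param variables Ordered character vector of explanatory columns to use
#'   (typically from [take_top_k()]).
#' @param cfg An [svr_config()].
#' @return An object of class `lrfa_svr` with the fitted model,
#'   normalization statistics, selected variables, chosen hyperparameters,
#'   `training_r2` and the training torque range. Supports [predict()],
#'   [tidy()] and [glance()].
#' @export
train_svr <- function(table, variables, cfg = svr_config()) {
  missing <- setdiff(variables, names(table))
  if (length(missing) > 0) {
    abort_data(paste0("Missing columns: ", paste(missing, collapse = ", ")))
  }
  n <- nrow(table)
  if (n < cfg$cv_folds_for_tuning) {
    abort_data("Fewer training rows than internal tuning folds.")
  }
  y_raw <- table$peak_torque_nm
  if (stats::sd(y_raw) == 0) {
    abort_data("The objective `peak_torque_nm` has zero variance.")
  }
  if (cfg$objective_scale == "log" && any(y_raw <= 0)) {
    abort_data("Log-scale objective requires positive torques; use objective_scale = \"linear\".")
  }
  y_work <- if (cfg$objective_scale == "log") log(y_raw) else y_raw

  stats_tbl <- tibble::tibble(
    column = c(variables, "peak_torque_nm"),
    mean = c(vapply(variables, function(cl) mean(table[[cl]]), numeric(1)), mean(y_work)),
    sd = c(vapply(variables, function(cl) stats::sd(table[[cl]]), numeric(1)), stats::sd(y_work))
  )
  # a constant explanatory column normalizes to 0 everywhere: keep it but
  # guard the division
  stats_tbl$sd[stats_tbl$sd == 0] <- 1

  xn <- sapply(variables, function(cl) apply_norm(table[[cl]], stats_tbl, cl))
  xn <- matrix(xn, nrow = n, dimnames = list(NULL, variables))
  yn <- apply_norm(y_work, stats_tbl, "peak_torque_nm")

  grid <- expand.grid(epsilon = cfg$epsilon_grid, cost = cfg$cost_grid,
                      gamma = cfg$gamma_grid, KEEP.OUT.ATTRS = FALSE)
  k <- cfg$cv_folds_for_tuning
  fold_id <- with_seed(cfg$rng_seed, sample(rep_len(seq_len(k), n)))

  if (nrow(grid) == 1L) {
    best <- grid[1, ]
    best_score <- NA_real_
  } else {
    scores <- numeric(nrow(grid))
    splits <- lapply(seq_len(k), function(f) {
      list(train = which(fold_id != f), test = which(fold_id == f))
    })
    for (g in seq_len(nrow(grid))) {
      r2s <- vapply(splits, function(sp) {
        if (length(sp$test) < 2 || length(sp$train) < 2) {
          return(NA_real_)
        }
        # a too-wide epsilon tube leaves no support vectors ("empty" model);
        # such candidates are simply invalid
        tryCatch({
          fit <- e1071::svm(xn[sp$train, , drop = FALSE], yn[sp$train],
                            type = "eps-regression", kernel = "radial",
                            epsilon = grid$epsilon[g], cost = grid$cost[g],
                            gamma = grid$gamma[g], scale = FALSE)
          pred <- stats::predict(fit, xn[sp$test, , drop = FALSE])
          r_squared(yn[sp$test], pred)
        }, error = function(e) NA_real_)
      }, numeric(1))
      scores[g] <- if (all(is.na(r2s))) -Inf else mean(r2s, na.rm = TRUE)
    }
    best_idx <- which.max(scores) # first maximum: deterministic tie-break
    best <- grid[best_idx, ]
    best_score <- scores[best_idx]
  }

  fit <- e1071::svm(xn, yn, type = "eps-regression", kernel = "radial",
                    epsilon = best$epsilon, cost = best$cost,
                    gamma = best$gamma, scale = FALSE)
  train_pred <- invert_norm(stats::predict(fit, xn), stats_tbl, "peak_torque_nm")
  if (cfg$objective_scale == "log") train_pred <- exp(train_pred)

  structure(
    list(
      fit = fit,
      objective_scale = cfg$objective_scale,
      selected_variables = variables,
      normalization_stats = stats_tbl,
      hyperparameters = list(epsilon = best$epsilon, cost = best$cost,
                             gamma = best$gamma),
      tuning_score = best_score,
      training_r2 = r_squared(y_raw, train_pred),
      torque_range = range(y_raw),
      feature_ranges = apply(xn, 2, range),
      config = cfg
    ),
    class = "lrfa_svr"
  )
}

#' Predict peak torque for new measurements
#'
#' Applies the stored normalization to the selected columns, evaluates the
#' kernel regression, and inverse-transforms the result back to Nm.
#' Extrapolated queries — rows whose features leave the training range, or
#' whose predicted torque leaves the training torque range — are flagged
#' (attribute `extrapolated`) and reported with a warning: accuracy outside
#' the training range degrades sharply and such outputs should not be
#' trusted. They are still returned, never clipped or refused.
#'
#' @param object An `lrfa_svr` model.
#' @param newdata A feature table containing all selected variables.
#' @param ... Unused.
#' @return Numeric vector of predicted torques (Nm), strictly finite, with
#'   a logical `extrapolated` attribute.
#' @export
predict.lrfa_svr <- function(object, newdata, ...) {
  missing <- setdiff(object$selected_variables, names(newdata))
  if (length(missing) > 0) {
    abort_data(paste0("Missing columns: ", paste(missing, collapse = ", ")))
  }
  vars <- object$selected_variables
  xn <- sapply(vars, function(cl) apply_norm(newdata[[cl]], object$normalization_stats, cl))
  xn <- matrix(xn, nrow = nrow(newdata), dimnames = list(NULL, vars))
  pred <- invert_norm(stats::predict(object$fit, xn),
                      object$normalization_stats, "peak_torque_nm")
  if (identical(object$objective_scale, "log")) pred <- exp(pred)
  pred <- as.numeric(pred)
  stopifnot(all(is.finite(pred)))
  out_features <- rowSums(
    sweep(xn, 2, object$feature_ranges[1, ], `<`) |
      sweep(xn, 2, object$feature_ranges[2, ], `>`)
  ) > 0
  extrap <- out_features |
    pred < object$torque_range[1] | pred > object$torque_range[2]
  if (any(extrap)) {
    rlang::warn(sprintf(
      "%d prediction(s) extrapolate beyond the training data (torque range [%.3g, %.3g] Nm).",
      sum(extrap), object$torque_range[1], object$torque_range[2]
    ), class = "lrfa_extrapolation")
  }
  attr(pred, "extrapolated") <- extrap
  pred
}

#' @export
print.lrfa_svr <- function(x, ...) {
  cat("RBF-kernel support vector regression (torque predictor)\n")
  cat(sprintf("  variables: %d   epsilon = %.4g, C = %.4g, gamma = %.4g\n",
              length(x$selected_variables), x$hyperparameters$epsilon,
              x$hyperparameters$cost, x$hyperparameters$gamma))
  cat(sprintf("  training R^2 = %.3f on torques in [%.3g, %.3g] Nm\n",
              x$training_r2, x$torque_range[1], x$torque_range[2]))
  invisible(x)
}

#' @rdname tidy.lrfa_selection
#' @export
tidy.lrfa_svr <- function(x, ...) {
  dplyr::left_join(
    tibble::tibble(variable = x$selected_variables,
                   rank = seq_along(x$selected_variables)),
    x$normalization_stats, by = c(variable = "column")
  )
}

#' @rdname glance.lrfa_selection
#' @export
glance.lrfa_svr <- function(x, ...) {
  tibble::tibble(
    epsilon = x$hyperparameters$epsilon,
    cost = x$hyperparameters$cost,
    gamma = x$hyperparameters$gamma,
    n_variables = length(x$selected_variables),
    training_r2 = x$training_r2,
    tuning_r2 = x$tuning_score
  )
}

#' Evaluate torque predictions
#'
#' Computes the determination coefficient `R^2 = 1 - SS_res/SS_tot`, the
#' Pearson correlation, the mean squared error on the raw Nm scale (and on
#' the variance-normalized scale, since reported MSEs are scale-ambiguous),
#' and the fraction of predictions within ±20% of the true torque — the
#' band treated as clinically useful accuracy.
#'
#' @param truth True peak torques (Nm).
#' @param predicted Predicted peak torques (Nm), same length (>= 2).
#' @return An object of class `lrfa_evaluation`: list with `metrics` (one
#'   row tibble) and `points` (per-measurement tibble, including the
#'   within-band flag). Supports [tidy()], [glance()] and `autoplot()`.
#' @export
#' @examples
#' ev <- evaluate_predictions(c(1, 2), c(1.1, 2.5))
#' glance(ev)$n_within
evaluate_predictions <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) < 2) {
    abort_data("`truth` and `predicted` must have equal length >= 2.")
  }
  if (stats::sd(truth) == 0) {
    abort_data("R^2 is undefined for zero-variance truth.")
  }
  within <- abs(predicted - truth) <= 0.2 * truth
  metrics <- tibble::tibble(
    r2 = r_squared(truth, predicted),
    pearson_r = stats::cor(truth, predicted),
    mse = mean((truth - predicted)^2),
    mse_normalized = mean((truth - predicted)^2) / mean((truth - mean(truth))^2),
    frac_within_20pct = mean(within),
    n_within = sum(within),
    n_total = length(truth)
  )
  structure(
    list(metrics = metrics,
         points = tibble::tibble(true = truth, predicted = predicted,
                                 within_20pct = within,
                                 abs_error = abs(predicted - truth))),
    class = "lrfa_evaluation"
  )
}

#' @export
print.lrfa_evaluation <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "Torque prediction: %d/%d within +/-20%% (%.0f%%), R^2 = %.3f, r = %.3f, MSE = %.4g Nm^2\n",
    m$n_within, m$n_total, 100 * m$frac_within_20pct, m$r2, m$pearson_r, m$mse
  ))
  invisible(x)
}

#' @rdname tidy.lrfa_selection
#' @export
tidy.lrfa_evaluation <- function(x, ...) x$points

#' @rdname glance.lrfa_selection
#' @export
glance.lrfa_evaluation <- function(x, ...) x$metrics

#' Conventional logarithmic peak-frequency baseline
#'
#' The single-variable diagnostic that preceded the machine-learning
#' scheme: a least-squares fit of the dominant peak frequency on the
#' logarithm of peak torque, `f = a * ln(torque) + b`. Inverting the fit
#' predicts torque from a measured peak frequency.
#'
#' @param torques Peak torques (Nm), all > 0, length >= 3.
#' @param peak_frequencies Dominant peak frequencies (Hz).
#' @return A list of class `lrfa_log_baseline` with `a`, `b`, `r2`.
#' @export
#' @examples
#' fit <- fit_log_baseline(c(0.1, 0.5, 1, 2), 2000 * log(c(0.1, 0.5, 1, 2)) + 6000)
#' c(fit$a, fit$b, fit$r2)
fit_log_baseline <- function(torques, peak_frequencies) {
  if (any(torques <= 0)) abort_data("All torques must be positive.")
  if (length(torques) < 3 || length(torques) != length(peak_frequencies)) {
    abort_data("Need >= 3 paired (torque, frequency) observations.")
  }
  fit <- stats::lm(peak_frequencies ~ log(torques))
  a <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  sst <- sum((peak_frequencies - mean(peak_frequencies))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(stats::residuals(fit)^2) / sst
  if (sst == 0) a <- 0
  structure(list(a = a, b = b, r2 = r2), class = "lrfa_log_baseline")
}

#' Predict torque by inverting the logarithmic baseline
#'
#' @param object An `lrfa_log_baseline`.
#' @param peak_frequencies Peak frequencies (Hz) to convert.
#' @param ... Unused.
#' @return Predicted torques in Nm.
#' @export
predict.lrfa_log_baseline <- function(object, peak_frequencies, ...) {
  if (object$a == 0) {
    abort_data("Baseline slope is zero; torque cannot be inferred from frequency.")
  }
  exp((peak_frequencies - object$b) / object$a)
}

#' @rdname glance.lrfa_selection
#' @export
glance.lrfa_log_baseline <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, r2 = x$r2)
}

#' Leave-one-out cross-validation of the SVR predictor
#'
#' For each measurement, trains on all other rows (full grid search each
#' time) and predicts the held-out one; useful for characterizing where the
#' predictor works — in particular, its weakness at the extreme torques,
#' which are necessarily extrapolated when held out.
#'
#' @inheritParams train_svr
#' @return A list of class `lrfa_loocv`: `evaluation` (an
#'   `lrfa_evaluation` over all held-out predictions) and `points` (tibble
#'   ordered by torque with per-point held-out predictions and errors).
#' @export
loocv <- function(table, variables, cfg = svr_config()) {
  n <- nrow(table)
  if (n < 3) abort_data("Need at least 3 rows for leave-one-out validation.")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    model <- train_svr(table[-i, , drop = FALSE], variables, cfg)
    preds[i] <- suppressWarnings(predict(model, table[i, , drop = FALSE]))
  }
  truth <- table$peak_torque_nm
  ord <- order(truth)
  structure(
    list(
      evaluation = evaluate_predictions(truth, preds),
      points = tibble::tibble(
        measurement_id = table$measurement_id %||% as.character(seq_len(n)),
        true = truth, predicted = preds, abs_error = abs(preds - truth)
      )[ord, ]
    ),
    class = "lrfa_loocv"
  )
}
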