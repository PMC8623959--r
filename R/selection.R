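#' Configuration of bootstrap-Lasso variable ranking
#'
#' @param n_bootstrap Number of bootstrap resamples (default 2000).
#' @param lambda_grid Candidate L1 regularization strengths (> 0). The
#'   default is 20 logarithmically spaced values on `[1e-3, 1]`, which
#'   brackets the strengths typically chosen on normalized data.
#' @param max_variables Upper bound on the selection footprint when choosing
#'   the regularization strength (default 40).
#' @param constraint How the footprint is measured: `"mean"` constrains the
#'   mean number of variables selected per resample; `"unique"` constrains
#'   the number of distinct variables selected across all resamples.
#' @param top_k Default number of top-ranked variables handed to the
#'   regression stage.
#' @param score How a regularization strength is scored when choosing one:
#'   `"oob"` (default) uses the mean out-of-bag determination coefficient —
#'   resamples drawn with replacement leave out roughly a third of the rows,
#'   which act as a validation set — while `"insample"` uses the best-case
#'   in-resample coefficient. In-sample fit improves monotonically as the
#'   penalty weakens, so in-sample scoring degenerates to the weakest
#'   penalty on the grid and a saturated, non-discriminating ranking;
#'   out-of-bag scoring selects an intermediate strength with sparse
#'   per-trial models and informative selection counts. Both scores are
#'   reported per strength in the result's `lambda_summary`.
#' @param rng_seed Integer seed for the resampling.
#' @return A list of class `lrfa_lasso_config`.
#' @export
lasso_config <- function(n_bootstrap = 2000,
                         lambda_grid = 10^seq(-3, 0, length.out = 20),
                         max_variables = 40,
                         constraint = c("mean", "unique"),
                         top_k = 30,
                         score = c("oob", "insample"),
                         rng_seed = 1L) {
  constraint <- match.arg(constraint)
  score <- match.arg(score)
  if (n_bootstrap < 1) abort_config("`n_bootstrap` must be >= 1.")
  if (length(lambda_grid) < 1 || any(lambda_grid <= 0)) {
    abort_config("`lambda_grid` must be a non-empty set of positive values.")
  }
  if (top_k > max_variables) abort_config("`top_k` must be <= `max_variables`.")
  structure(
    list(n_bootstrap = as.integer(n_bootstrap),
         lambda_grid = sort(unique(lambda_grid), decreasing = TRUE),
         max_variables = max_variables, constraint = constraint,
         top_k = as.integer(top_k), score = score, rng_seed = rng_seed),
    class = "lrfa_lasso_config"
  )
}

#' Z-score normalize a feature table
#'
#' Transforms every explanatory column and the objective (`peak_torque_nm`)
#' to zero mean and unit sample standard deviation, flattening the wildly
#' different orders of magnitude of frequency-valued and intensity-valued
#' features so the L1 penalty and the RBF kernel treat them comparably.
#' Constant columns (undefined after normalization) are dropped with a
#' warning. The returned statistics allow exact inverse transformation of
#' predictions back to Nm.
#'
#' @param table An `lrfa_feature_table`.
#' @return A list with elements `data` (the normalized tibble, identifiers
#'   preserved) and `stats` (tibble with `column`, `mean`, `sd`).
#' @export
#' @examples
#' tbl <- tibble::tibble(measurement_id = c("a", "b", "c"),
#'                       x = c(1, 2, 3), peak_torque_nm = c(1, 2, 4))
#' norm <- normalize_columns(tbl)
#' colMeans(norm$data[, c("x", "peak_torque_nm")])
normalize_columns <- function(table) {
  num_cols <- c(explanatory_columns(table), "peak_torque_nm")
  stats <- tibble::tibble(
    column = num_cols,
    mean = vapply(num_cols, function(cl) mean(table[[cl]]), numeric(1)),
    sd = vapply(num_cols, function(cl) stats::sd(table[[cl]]), numeric(1))
  )
  constant <- stats$column[stats$sd == 0 | is.na(stats$sd)]
  if ("peak_torque_nm" %in% constant) {
    abort_data("The objective `peak_torque_nm` is constant; nothing to regress.")
  }
  if (length(constant) > 0) {
    rlang::warn(sprintf("Dropping %d constant column(s): %s",
                        length(constant),
                        paste(utils::head(constant, 5), collapse = ", ")),
                class = "lrfa_constant_columns")
    table <- table[, setdiff(names(table), constant)]
    stats <- stats[!stats$column %in% constant, ]
  }
  data <- table
  for (i in seq_len(nrow(stats))) {
    cl <- stats$column[i]
    data[[cl]] <- (data[[cl]] - stats$mean[i]) / stats$sd[i]
  }
  list(data = data, stats = stats)
}

# Apply / invert stored normalization statistics for one column.
apply_norm <- function(x, stats, column) {
  i <- match(column, stats$column)
  (x - stats$mean[i]) / stats$sd[i]
}

invert_norm <- function(z, stats, column) {
  i <- match(column, stats$column)
  z * stats$sd[i] + stats$mean[i]
}

#' Rank explanatory variables by bootstrap-Lasso selection frequency
#'
#' For each candidate regularization strength, fits an L1-penalized linear
#' regression of the (normalized) objective on the explanatory variables on
#' `n_bootstrap` resamples drawn with replacement, recording which variables
#' receive nonzero coefficients and the fit's in-resample and out-of-bag
#' determination coefficients. The chosen strength maximizes the configured
#' score (out-of-bag mean by default, see [lasso_config()]) among strengths
#' whose selection footprint does not exceed `max_variables`; variables are
#' then ranked by how often they were selected at that strength (ties
#' broken by column order).
#'
#' @param data A normalized feature table (the `data` element of
#'   [normalize_columns()]), with `measurement_id`, explanatory columns and
#'   `peak_torque_nm`.
#' @param cfg A [lasso_config()].
#' @param resample_indices Optional list of `n_bootstrap` integer vectors of
#'   row indices, overriding the internal resampling (used to pin the
#'   resample sequence independently of row order).
#' @return A list of class `lrfa_selection` with `selection_counts` (named
#'   integer vector), `chosen_lambda`, `best_r2`,
#'   `mean_variables_per_trial`, `ranked_variables`, `lambda_summary`
#'   (per-strength tibble) and `n_bootstrap`. Supports [tidy()] and
#'   [glance()].
#' @export
bootstrap_lasso <- function(data, cfg = lasso_config(),
                            resample_indices = NULL) {
  vars <- explanatory_columns(data)
  n <- nrow(data)
  if (n < 5) abort_data("Need at least 5 rows for bootstrap-Lasso.")
  if (length(vars) < 2) abort_data("Need at least 2 explanatory columns.")
  x <- as.matrix(data[, vars])
  y <- data$peak_torque_nm
  lambdas <- cfg$lambda_grid # decreasing
  B <- cfg$n_bootstrap
  if (!is.null(resample_indices)) {
    if (length(resample_indices) != B) {
      abort_config("`resample_indices` must have `n_bootstrap` elements.")
    }
  }

  n_lam <- length(lambdas)
  counts <- matrix(0L, nrow = n_lam, ncol = length(vars),
                   dimnames = list(NULL, vars))
  r2 <- matrix(NA_real_, nrow = B, ncol = n_lam)
  r2_oob <- matrix(NA_real_, nrow = B, ncol = n_lam)
  n_sel <- matrix(0L, nrow = B, ncol = n_lam)
  n_nonconverged <- 0L

  with_seed(cfg$rng_seed, {
    for (b in seq_len(B)) {
      idx <- resample_indices[[b]] %||% sample.int(n, n, replace = TRUE)
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      sds <- apply(xb, 2, stats::sd)
      fit <- tryCatch(
        glmnet::glmnet(xb, yb, lambda = lambdas, standardize = FALSE,
                       thresh = 1e-6, maxit = 1e5),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        n_nonconverged <- n_nonconverged + 1L
        next
      }
      beta <- as.matrix(fit$beta) # vars x fitted lambdas
      # glmnet may stop early on a degenerate resample; align by lambda value
      lam_pos <- match(round(fit$lambda, 12), round(lambdas, 12))
      pred <- stats::predict(fit, newx = xb)
      sst <- sum((yb - mean(yb))^2)
      for (j in seq_along(lam_pos)) {
        pos <- lam_pos[j]
        if (is.na(pos)) next
        nz <- beta[, j] != 0
        counts[pos, nz] <- counts[pos, nz] + 1L
        n_sel[b, pos] <- sum(nz)
        r2[b, pos] <- if (sst > 0) 1 - sum((yb - pred[, j])^2) / sst else NA_real_
        if (cfg$score == "oob") {
          oob <- setdiff(seq_len(n), unique(idx))
          if (length(oob) >= 2) {
            po <- stats::predict(fit, newx = x[oob, , drop = FALSE])[, j]
            ssto <- sum((y[oob] - mean(y[oob]))^2)
            r2_oob[b, pos] <- if (ssto > 0) 1 - sum((y[oob] - po)^2) / ssto else NA_real_
          }
        }
      }
    }
  })

  lambda_summary <- tibble::tibble(
    lambda = lambdas,
    best_r2 = apply(r2, 2, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)),
    mean_r2 = colMeans(r2, na.rm = TRUE),
    oob_r2 = if (cfg$score == "oob") colMeans(r2_oob, na.rm = TRUE) else NA_real_,
    mean_variables_per_trial = colMeans(n_sel),
    unique_variables = apply(counts, 1, function(ct) sum(ct > 0))
  )

  footprint <- switch(cfg$constraint,
    mean = lambda_summary$mean_variables_per_trial,
    unique = as.numeric(lambda_summary$unique_variables)
  )
  score_col <- if (cfg$score == "oob") lambda_summary$oob_r2 else lambda_summary$best_r2
  feasible <- which(footprint <= cfg$max_variables & !is.na(score_col))
  if (all(lambda_summary$unique_variables == 0)) {
    abort_data("Every regularization strength produced empty models; extend `lambda_grid` toward smaller values.")
  }
  if (length(feasible) == 0) {
    # fall back to the sparsest strength if nothing satisfies the footprint
    feasible <- which.max(lambda_summary$lambda)
  }
  # maximize the score; ties go to the larger (sparser) lambda,
  # i.e. the earlier index since lambdas are decreasing
  chosen <- feasible[which.max(score_col[feasible])]

  sel_counts <- counts[chosen, ]
  ranked <- vars[order(-sel_counts, seq_along(vars))]
  if (n_nonconverged > 0) {
    rlang::warn(sprintf("%d resample(s) failed to fit and were skipped.",
                        n_nonconverged), class = "lrfa_lasso_nonconverged")
  }

  structure(
    list(
      selection_counts = sel_counts,
      chosen_lambda = lambdas[chosen],
      best_r2 = lambda_summary$best_r2[chosen],
      mean_variables_per_trial = lambda_summary$mean_variables_per_trial[chosen],
      ranked_variables = ranked,
      lambda_summary = lambda_summary,
      n_bootstrap = B,
      config = cfg
    ),
    class = "lrfa_selection"
  )
}

#' Take the top-k ranked variables from a selection result
#'
#' @param result An `lrfa_selection`.
#' @param k Number of variables (defaults to the configuration's `top_k`).
#' @return Character vector: the first `k` of the ranking.
#' @export
take_top_k <- function(result, k = result$config$top_k) {
  if (k > length(result$ranked_variables)) {
    abort_data(sprintf("k = %d exceeds the %d ranked variables.",
                       k, length(result$ranked_variables)))
  }
  result$ranked_variables[seq_len(k)]
}

#' @export
print.lrfa_selection <- function(x, ...) {
  cat("Bootstrap-Lasso variable selection\n")
  cat(sprintf("  resamples: %d   chosen lambda: %.4g\n", x$n_bootstrap, x$chosen_lambda))
  cat(sprintf("  best R^2: %.3f   mean variables per trial: %.1f\n",
              x$best_r2, x$mean_variables_per_trial))
  cat("  top variables:\n")
  top <- utils::head(x$ranked_variables, 5)
  for (v in top) cat(sprintf("    %-40s %d\n", v, x$selection_counts[[v]]))
  invisible(x)
}

#' Tidy a bootstrap-Lasso selection result
#'
#' One row per explanatory variable with its band, feature name, selection
#' count and rank — the layout of a selection-frequency table.
#'
#' @param x An `lrfa_selection`.
#' @param ... Unused.
#' @return A tibble sorted by rank.
#' @export
tidy.lrfa_selection <- function(x, ...) {
  vars <- names(x$selection_counts)
  split <- strsplit(vars, ":", fixed = TRUE)
  tibble::tibble(
    variable = vars,
    band = vapply(split, function(p) p[1], character(1)),
    feature = vapply(split, function(p) if (length(p) > 1) p[2] else NA_character_, character(1)),
    n_selected = as.integer(x$selection_counts),
    rank = match(vars, x$ranked_variables)
  ) |> dplyr::arrange(.data$rank)
}

#' Glance at a bootstrap-Lasso selection result
#' @inheritParams tidy.lrfa_selection
#' @return A one-row tibble with the chosen strength and summary statistics.
#' @export
glance.lrfa_selection <- function(x, ...) {
  tibble::tibble(
    chosen_lambda = x$chosen_lambda,
    best_r2 = x$best_r2,
    mean_variables_per_trial = x$mean_variables_per_trial,
    n_bootstrap = x$n_bootstrap
  )
}

#' Write a selection result to delimited text
#'
#' Writes the per-variable table (variable, band, feature, count, rank) and
#' a small YAML sidecar with the strength grid, chosen strength and seed.
#'
#' @param result An `lrfa_selection`.
#' @param path Output file for the table; the sidecar gets the suffix
#'   `.meta.yaml`.
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(result, path) {
  readr::write_tsv(tidy(result), path)
  yaml::write_yaml(
    list(lambda_grid = result$config$lambda_grid,
         chosen_lambda = result$chosen_lambda,
         n_bootstrap = result$n_bootstrap,
         rng_seed = result$config$rng_seed),
    paste0(path, ".meta.yaml")
  )
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
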