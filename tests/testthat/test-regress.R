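# Small deterministic feature table with a smooth, learnable relation
# between one feature and the torque objective.
linear_table <- function(n = 30) {
  x <- seq_len(n)
  tibble::tibble(measurement_id = sprintf("m%02d", x),
                 x = as.numeric(x),
                 peak_torque_nm = as.numeric(x))
}

single_triple <- function(...) {
  svr_config(epsilon_grid = 2^-6, cost_grid = 2^4, gamma_grid = 2^-2, ...)
}

test_that("fold assignment pins the extremes and deals sorted triplets", {
  f <- assign_folds(c(0.1, 0.5, 1, 2, 3))
  expect_equal(f[1], 1L) # minimum
  expect_equal(f[5], 1L) # maximum
  expect_equal(f[2:4], c(1L, 2L, 3L)) # sorted middle dealt 1,2,3

  expect_error(assign_folds(c(1, 2, 3, 4)), class = "lrfa_data_error")
})

test_that("fold assignment matches an enumeration oracle at n = 56", {
  withr::with_seed(31, {
    torques <- runif(56, 0.06, 3)
    f <- assign_folds(torques)
    # oracle: apply the rule by hand
    ord <- order(torques)
    expected <- integer(56)
    expected[ord[1]] <- 1L
    expected[ord[56]] <- 1L
    expected[ord[2:55]] <- rep_len(1:3, 54)
    expect_identical(f, expected)
    # fold sizes: fold 1 has the 2 extremes plus its share of triplets
    expect_equal(as.integer(table(f)), c(20L, 18L, 18L))
    expect_true(all(table(f) > 0))
  })
})

test_that("tied torques get a stable order-based assignment", {
  f <- assign_folds(rep(1, 6))
  # order() is stable: first row is the "minimum", last the "maximum"
  expect_equal(f, c(1L, 1L, 2L, 3L, 1L, 1L))
})

test_that("a noiseless linear relation is learned nearly exactly", {
  tbl <- linear_table(30)
  model <- train_svr(tbl, "x", svr_config(
    epsilon_grid = 2^seq(-8, -2, 2), cost_grid = 2^seq(0, 10, 2),
    gamma_grid = 2^seq(-6, 0, 2), rng_seed = 1
  ))
  expect_gte(model$training_r2, 0.99)
  pred <- predict(model, tbl)
  expect_gte(lrfa:::r_squared(tbl$peak_torque_nm, as.numeric(pred)), 0.99)
})

test_that("a single-triple grid passes hyperparameters through", {
  model <- train_svr(linear_table(10), "x", single_triple())
  expect_equal(model$hyperparameters$epsilon, 2^-6)
  expect_equal(model$hyperparameters$cost, 2^4)
  expect_equal(model$hyperparameters$gamma, 2^-2)
})

test_that("prediction enforces columns, determinism and finiteness", {
  tbl <- linear_table(12)
  model <- train_svr(tbl, "x", single_triple())
  expect_error(predict(model, tbl[, c("measurement_id", "peak_torque_nm")]),
               "Missing columns")

  dup <- tbl[c(3, 3), ]
  p <- suppressWarnings(predict(model, dup))
  expect_equal(p[1], p[2])

  far <- tibble::tibble(x = 1e4, peak_torque_nm = NA_real_)
  expect_warning(pf <- predict(model, far), class = "lrfa_extrapolation")
  expect_true(is.finite(as.numeric(pf)))
  expect_true(attr(pf, "extrapolated"))
})

test_that("degenerate objectives are rejected", {
  tbl <- linear_table(10)
  tbl$peak_torque_nm <- 1
  expect_error(train_svr(tbl, "x", single_triple()), class = "lrfa_data_error")
  tbl$peak_torque_nm <- c(-1, 2:10)
  expect_error(train_svr(tbl, "x", single_triple()), class = "lrfa_data_error")
  expect_silent(train_svr(tbl, "x",
                          single_triple(objective_scale = "linear")))
})

test_that("evaluation metrics follow their definitions", {
  perfect <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  m <- perfect$metrics
  expect_equal(m$r2, 1)
  expect_equal(m$pearson_r, 1)
  expect_equal(m$mse, 0)
  expect_equal(m$frac_within_20pct, 1)

  hand <- evaluate_predictions(c(1, 2), c(1.1, 2.5))
  expect_equal(hand$metrics$n_within, 1L)
  expect_equal(hand$metrics$n_total, 2L)

  # 16 of 18 inside the band
  truth <- as.numeric(1:18)
  pred <- truth * 1.1
  pred[c(4, 9)] <- truth[c(4, 9)] * 1.5
  ev <- evaluate_predictions(truth, pred)
  expect_equal(ev$metrics$n_within, 16L)
  expect_equal(ev$metrics$frac_within_20pct, 16 / 18)

  expect_error(evaluate_predictions(c(1, 1), c(1, 2)), class = "lrfa_data_error")
  expect_error(evaluate_predictions(1, c(1, 2)), class = "lrfa_data_error")
})

test_that("r and the accuracy band are scale-free but MSE is not", {
  withr::with_seed(41, {
    truth <- runif(20, 0.1, 3)
    pred <- truth * exp(rnorm(20, 0, 0.2))
    e1 <- evaluate_predictions(truth, pred)$metrics
    e2 <- evaluate_predictions(5 * truth, 5 * pred)$metrics
    expect_equal(e2$pearson_r, e1$pearson_r, tolerance = 1e-12)
    expect_equal(e2$frac_within_20pct, e1$frac_within_20pct)
    expect_equal(e2$mse, 25 * e1$mse, tolerance = 1e-9)
  })
})

test_that("the logarithmic baseline recovers exact coefficients", {
  tq <- c(0.1, 0.3, 1, 2, 3)
  f <- 2000 * log(tq) + 6000
  fit <- fit_log_baseline(tq, f)
  expect_equal(fit$a, 2000, tolerance = 1e-9)
  expect_equal(fit$b, 6000, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(predict(fit, f), tq, tolerance = 1e-9)

  const <- fit_log_baseline(tq, rep(5000, 5))
  expect_equal(const$a, 0)
  expect_equal(const$r2, 0)
  expect_error(predict(const, 5000), class = "lrfa_data_error")

  expect_error(fit_log_baseline(c(-1, 1, 2), c(1, 2, 3)),
               class = "lrfa_data_error")
})

test_that("head-tilt variation degrades the log-fit determination coefficient", {
  base <- small_cfg(tilt_shift_horizontal = 0, tilt_shift_vertical = 0,
                    tilt_jitter_sd = 0, pulse_jitter_sd = 0, noise_sd = 0)
  jittery <- small_cfg()
  peak_curve <- function(cfg, seed0) {
    ds <- simulate_dataset(20, c(0.06, 3), cfg = cfg, seed = seed0)
    vapply(ds$record, function(r) spectrum_peak(preprocess_record(r)), numeric(1))
  }
  ds_t <- simulate_dataset(20, c(0.06, 3), cfg = base, seed = 77)
  r2_clean <- fit_log_baseline(ds_t$torque_nm, peak_curve(base, 77))$r2
  r2_jitter <- fit_log_baseline(ds_t$torque_nm, peak_curve(jittery, 77))$r2
  expect_lt(r2_jitter, r2_clean - 0.05)
})

test_that("leave-one-out validation reports one row per measurement", {
  tbl <- linear_table(6)
  res <- suppressWarnings(loocv(tbl, "x", single_triple()))
  expect_equal(nrow(res$points), 6)
  expect_equal(res$points$true, sort(res$points$true)) # ordered by torque
  expect_s3_class(res$evaluation, "lrfa_evaluation")
})

test_that("tidy and glance summarize trained models", {
  tbl <- linear_table(10)
  model <- train_svr(tbl, "x", single_triple())
  td <- tidy(model)
  expect_equal(td$variable, "x")
  gl <- glance(model)
  expect_equal(gl$epsilon, 2^-6)
  expect_true(is.finite(gl$training_r2))
})
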