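# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so callers never perturb (or depend on) global state.
#' A `NULL` seed evaluates `code` under the ambient RNG.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive n reproducible child seeds from a single master seed, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "lrfa_config_error", ...)
}

abort_data <- function(msg, ...) {
  rlang::abort(msg, class = "lrfa_data_error", ...)
}

# Near-integer check tolerant of floating-point products like 1e5 * 2.
is_whole <- function(x, tol = 1e-8) {
  abs(x - round(x)) < tol
}
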