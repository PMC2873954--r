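# Internal helpers shared across modules.

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so package functions do not perturb the global random stream.
with_seed_preserved <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "cghdiv_config_error")
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)),
          class = "cghdiv_config_error")
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  assert_number(x, name, lower = lower)
  if (x != round(x)) {
    abort(sprintf("`%s` must be a whole number.", name),
          class = "cghdiv_config_error")
  }
  invisible(as.integer(x))
}

# Column presence check with a format-error class naming the offender.
require_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s", what,
                  paste(missing, collapse = ", ")),
          class = "cghdiv_format_error")
  }
  invisible(df)
}

# Truncated-normal sampler on [lo, hi] by inverse-CDF; exact, no rejection.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p_lo <- pnorm((lo - mean) / sd)
  p_hi <- pnorm((hi - mean) / sd)
  mean + sd * qnorm(runif(n, p_lo, p_hi))
}

# z-score a vector; a zero-variance vector maps to zeros (degenerate input
# rather than NaN so planted models with constant covariates stay defined).
zscore <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}
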