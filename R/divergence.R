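#' Per-feature summary statistics of the normalized log2 ratios
#'
#' Computes, over the usable cells of each feature, the number of arrays
#' used, the mean M and the unbiased sample variance. Features with fewer
#' than two usable arrays are kept in the output with `NA` statistics (they
#' are reported, never silently dropped), but are excluded from all
#' downstream inference.
#'
#' @param ratios A `cgh_ratios` tibble from [normalize_loess_conserved()],
#'   or any tibble with `feature_id`, `M` and optionally `usable`.
#' @return A tibble `feature_id`, `n_used`, `mean_M`, `s2`.
#' @export
fit_feature_stats <- function(ratios) {
  require_columns(ratios, c("feature_id", "M"), "ratios")
  if (nrow(ratios) == 0L) {
    abort("empty ratio table.", class = "cghdiv_input_error")
  }
  if (!"usable" %in% names(ratios)) ratios$usable <- !is.na(ratios$M)
  ratios |>
    group_by(.data$feature_id) |>
    summarise(
      n_used = sum(.data$usable & !is.na(.data$M)),
      mean_M = ifelse(.data$n_used >= 2,
                      mean(.data$M[.data$usable], na.rm = TRUE), NA_real_),
      s2 = ifelse(.data$n_used >= 2,
                  var(.data$M[.data$usable], na.rm = TRUE), NA_real_),
      .groups = "drop"
    )
}

# Invert the trigamma function by Newton iteration: solve trigamma(x) = y.
trigamma_inverse <- function(y, tol = 1e-8, max_iter = 100L) {
  if (y <= 0) return(Inf)
  # large y -> small x; trigamma(x) ~ 1/x + 1/(2x^2)
  x <- 0.5 + 1 / y
  for (i in seq_len(max_iter)) {
    f <- trigamma(x) - y
    step <- f / psigamma(x, 2L)
    x_new <- x - step
    if (x_new <= 0) x_new <- x / 2
    if (abs(x_new - x) < tol * max(1, x)) return(x_new)
    x <- x_new
  }
  warn("trigamma inversion did not converge; using last iterate")
  x
}

# Estimate the scaled-F hyperparameters (d0, s0_2) of the variance prior by
# matching the first two moments of log s2. With s2 ~ s0^2 * F(d, d0),
# e = log s2 - digamma(d/2) + log(d/2) has
# E[e]  = log s0^2 - digamma(d0/2) + log(d0/2)
# Var[e] = trigamma(d/2) + trigamma(d0/2).
estimate_variance_prior <- function(s2, df, tol = 1e-8, max_iter = 100L) {
  ok <- is.finite(s2) & s2 > 0 & df >= 1
  s2 <- s2[ok]; df <- df[ok]
  n <- length(s2)
  if (n < 2L) {
    abort("need at least 2 positive sample variances to estimate the prior.",
          class = "cghdiv_input_error")
  }
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  e_bar <- mean(e)
  v_raw <- sum((e - e_bar)^2) / (n - 1L)
  v <- v_raw - mean(trigamma(df / 2))
  if (v_raw < 1e-12) {
    # literally constant variances: outside the sampling model; the pooled
    # value can only be that constant
    d0 <- Inf
    s0_2 <- exp(mean(log(s2)))
  } else if (!is.finite(v) || v <= 0) {
    # dispersion of log s2 consistent with pure chi-square sampling noise:
    # completely pooled prior with the chi-square log-moment correction
    d0 <- Inf
    s0_2 <- exp(e_bar)
  } else {
    half_d0 <- trigamma_inverse(v, tol = tol, max_iter = max_iter)
    d0 <- 2 * half_d0
    s0_2 <- exp(e_bar + digamma(half_d0) - log(half_d0))
  }
  list(d0 = d0, s0_2 = s0_2, n_used = n)
}

#' Empirical Bayes shrinkage of per-feature variances and moderated t-tests
#'
#' Estimates prior degrees of freedom `d0` and prior variance `s0_2` by
#' matching the first two moments of `log(s2)` to a scaled-F model (closed
#' form up to a trigamma inversion solved by Newton iteration, tolerance
#' 1e-8, at most 100 iterations), then shrinks each feature's variance
#' towards the pooled estimate,
#' \deqn{s^2_{post} = (d_0 s_0^2 + d s^2) / (d_0 + d), \quad d = n - 1,}
#' and forms the moderated statistic
#' `t = mean_M / sqrt(s2_post / n)` on `d0 + d` degrees of freedom, with
#' two-sided p-values and Benjamini-Hochberg q-values ([bh_fdr()]). If the
#' moment matching cannot produce a usable prior, the function falls back to
#' `s2_post = s2` with a warning.
#'
#' @param stats Tibble from [fit_feature_stats()].
#' @param d0,s0_2 Optional forced hyperparameters (e.g. `d0 = Inf` pools
#'   completely); both must be given together to skip estimation.
#' @return A `cgh_moderated` tibble: `feature_id`, `n_used`, `mean_M`, `s2`,
#'   `s2_post`, `t_mod`, `p`, `q`, with attributes `d0` and `s0_2`.
#' @export
shrink_variances <- function(stats, d0 = NULL, s0_2 = NULL) {
  require_columns(stats, c("feature_id", "n_used", "mean_M", "s2"), "stats")
  use <- stats$n_used >= 2 & is.finite(stats$mean_M)
  df <- stats$n_used - 1

  if (is.null(d0) || is.null(s0_2)) {
    prior <- tryCatch(
      estimate_variance_prior(stats$s2[use], df[use]),
      error = function(e) {
        warn(paste("variance prior estimation failed; using unshrunk",
                   "variances:", conditionMessage(e)))
        NULL
      })
    if (is.null(prior)) {
      d0 <- 0
      s0_2 <- 0
    } else {
      d0 <- prior$d0
      s0_2 <- prior$s0_2
    }
  }

  s2_post <- rep(NA_real_, nrow(stats))
  if (is.infinite(d0)) {
    s2_post[use] <- s0_2
  } else {
    s2_post[use] <- (d0 * s0_2 + df[use] * stats$s2[use]) / (d0 + df[use])
  }
  t_mod <- stats$mean_M / sqrt(s2_post / stats$n_used)
  df_total <- ifelse(use, d0 + df, NA_real_)
  p <- 2 * pt(-abs(t_mod), df = df_total)
  q <- rep(NA_real_, length(p))
  q[use] <- bh_fdr(p[use])

  out <- stats |>
    mutate(s2_post = s2_post, t_mod = t_mod, p = p, q = q)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  class(out) <- c("cgh_moderated", class(out))
  out
}

#' @export
tidy.cgh_moderated <- function(x, ...) {
  as_tibble(x)[, c("feature_id", "n_used", "mean_M", "s2", "s2_post",
                   "t_mod", "p", "q")]
}

#' @export
glance.cgh_moderated <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_tested = sum(is.finite(x$p)),
    d0 = attr(x, "d0"),
    s0_2 = attr(x, "s0_2")
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity; tied p-values
#' receive identical q-values. Input values must lie in \[0, 1\].
#'
#' @param p Numeric vector of p-values.
#' @return Vector of BH-adjusted q-values, same length and order as `p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p) {
  if (!is.numeric(p)) {
    abort("`p` must be numeric.", class = "cghdiv_input_error")
  }
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    abort("p-values must lie in [0, 1].", class = "cghdiv_input_error")
  }
  m <- sum(!is.na(p))
  q <- rep(NA_real_, length(p))
  if (m == 0L) return(q)
  idx <- which(!is.na(p))
  o <- order(p[idx])
  p_sorted <- p[idx][o]
  q_sorted <- pmin(1, rev(cummin(rev(m * p_sorted / seq_len(m)))))
  q[idx[o]] <- q_sorted
  q
}

#' Directional divergence calls at nested q-value thresholds
#'
#' A feature is called diverged at level `alpha` iff its q-value is below
#' `alpha` **and** its mean M is negative (hybridization reduced in the
#' heterologous species); by construction the calls are nested across
#' thresholds. Non-directional significance flags are also emitted, since
#' summary tables can be built either way.
#'
#' @param mod A `cgh_moderated` tibble from [shrink_variances()].
#' @param thresholds q-value thresholds, default `c(0.1, 0.05, 0.01)`.
#' @return A `cgh_calls` tibble: the input plus `direction` and, per
#'   threshold, `significant_q*` and `diverged_q*` columns (e.g.
#'   `diverged_q10` for alpha 0.1).
#' @export
call_diverged <- function(mod, thresholds = c(0.1, 0.05, 0.01)) {
  require_columns(mod, c("feature_id", "mean_M", "q"), "mod")
  if (any(thresholds <= 0 | thresholds >= 1)) {
    abort("thresholds must lie in (0, 1).", class = "cghdiv_input_error")
  }
  out <- mod |> mutate(direction = sign(.data$mean_M))
  for (a in thresholds) {
    tag <- threshold_tag(a)
    out[[paste0("significant_", tag)]] <- !is.na(out$q) & out$q < a
    out[[paste0("diverged_", tag)]] <- !is.na(out$q) & out$q < a &
      out$mean_M < 0
  }
  attr(out, "thresholds") <- thresholds
  class(out) <- unique(c("cgh_calls", class(out)))
  out
}

threshold_tag <- function(alpha) {
  # 0.1 -> "q10", 0.05 -> "q05", 0.01 -> "q01"
  paste0("q", sub("^0\\.", "", format(alpha, nsmall = 2, trim = TRUE)))
}
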