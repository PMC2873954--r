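#' Moving-window detection curve of divergence calls against %ID
#'
#' Sorts features by percent identity and, for every window of `window`
#' consecutive features, reports the fraction called diverged at each
#' threshold, against the window's mean %ID. A lowess smooth of each curve
#' is attached. Features without a %ID (no BLAST hit) are excluded.
#'
#' @param calls A `cgh_calls` tibble joined with a `pct_id` column, i.e. it
#'   must contain `pct_id` and one or more `diverged_q*` columns.
#' @param window Odd window width in features (default 51).
#' @param lowess_span Smoother span for the lowess summary (default 0.3).
#' @return A `cgh_detection_curve` tibble: `center_pct_id`, `alpha`
#'   (character tag such as "q10"), `fraction`, `smooth`.
#' @export
detection_curve <- function(calls, window = 51, lowess_span = 0.3) {
  require_columns(calls, "pct_id", "calls")
  window <- assert_count(window, "window", lower = 1)
  if (window %% 2L == 0L) {
    abort("`window` must be odd.", class = "cghdiv_input_error")
  }
  div_cols <- grep("^diverged_q", names(calls), value = TRUE)
  if (!length(div_cols)) {
    abort("no `diverged_q*` columns found; run call_diverged() first.",
          class = "cghdiv_input_error")
  }
  dat <- calls |>
    filter(is.finite(.data$pct_id)) |>
    arrange(.data$pct_id)
  n <- nrow(dat)
  if (n < window) {
    abort(sprintf("need at least %d features with %%ID, got %d", window, n),
          class = "cghdiv_input_error")
  }
  roll_mean <- function(x) {
    cs <- cumsum(c(0, x))
    (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  }
  centers <- roll_mean(dat$pct_id)
  curves <- map(div_cols, function(col) {
    frac <- roll_mean(as.numeric(dat[[col]]))
    smooth <- if (length(centers) < 2L) {
      frac
    } else {
      sm <- lowess(centers, frac, f = lowess_span)
      approx(sm$x, sm$y, xout = centers, ties = "ordered")$y
    }
    tibble(center_pct_id = centers,
           alpha = sub("^diverged_", "", col),
           fraction = frac,
           smooth = pmin(1, pmax(0, smooth)))
  }) |> list_rbind()
  class(curves) <- c("cgh_detection_curve", class(curves))
  attr(curves, "window") <- window
  curves
}

#' Logistic detection-limit fit (ID-50)
#'
#' Fits a binomial-logit regression of the per-feature diverged indicator on
#' %ID by maximum likelihood (IRLS, convergence tolerance 1e-10) and reports
#' the ID-50: the %ID at which a feature has a 50% chance of being called
#' diverged — the method's detection limit, by analogy with power analysis.
#' If the fitted probability never crosses 0.5 on \[60, 100\], the ID-50 is
#' reported as out of range with the side recorded. Complete separation
#' triggers a warning and a boundary estimate. Alternatively
#' (`method = "windowed"`) the fit uses the moving-window proportions of
#' [detection_curve()] as binomial counts.
#'
#' @param calls A `cgh_calls` tibble with `pct_id`.
#' @param alpha Divergence threshold whose calls are modeled (default 0.1).
#' @param method `"binary"` (per-feature 0/1 response, the default) or
#'   `"windowed"`.
#' @param window Window size when `method = "windowed"`.
#' @return A `cgh_id50` object: list with `coefficients` (intercept, slope),
#'   `id50`, `out_of_range`, `side`, `n`, `model`.
#' @export
fit_id50 <- function(calls, alpha = 0.1, method = c("binary", "windowed"),
                     window = 51) {
  method <- match.arg(method)
  require_columns(calls, "pct_id", "calls")
  col <- paste0("diverged_", threshold_tag(alpha))
  require_columns(calls, col, "calls")
  dat <- calls |>
    filter(is.finite(.data$pct_id)) |>
    transmute(pct_id = .data$pct_id, diverged = as.numeric(.data[[col]]))
  if (length(unique(dat$diverged)) < 2L && method == "binary") {
    warn("all features share one outcome; logistic fit is degenerate")
  }

  # complete separation: %ID perfectly splits the two outcomes, so the MLE
  # slope is unbounded and the crossing only bracketed by the gap
  if (method == "binary" && all(c(0, 1) %in% dat$diverged)) {
    hi_div <- max(dat$pct_id[dat$diverged == 1])
    lo_con <- min(dat$pct_id[dat$diverged == 0])
    if (hi_div < lo_con || max(dat$pct_id[dat$diverged == 0]) <
          min(dat$pct_id[dat$diverged == 1])) {
      warn(paste("complete separation in the logistic ID-50 fit;",
                 "the estimate is a boundary value bracketed by the gap"))
    }
  }

  fit <- withCallingHandlers(
    {
      if (method == "binary") {
        glm(diverged ~ pct_id, family = binomial(), data = dat,
            control = glm.control(epsilon = 1e-10, maxit = 100))
      } else {
        dc <- detection_curve(mutate(calls, !!col := calls[[col]]),
                              window = window)
        dcw <- filter(dc, .data$alpha == threshold_tag(!!alpha))
        glm(fraction ~ center_pct_id, family = binomial(), data = dcw,
            weights = rep(window, nrow(dcw)),
            control = glm.control(epsilon = 1e-10, maxit = 100))
      }
    },
    warning = function(w) {
      # probabilities saturating to 0/1 at the %ID extremes are expected for
      # steep curves; non-integer window counts are by construction
      if (grepl("fitted probabilities numerically 0 or 1|non-integer",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })

  b <- unname(coef(fit))
  id50 <- if (abs(b[2]) < .Machine$double.eps) NA_real_ else -b[1] / b[2]
  out_of_range <- !is.finite(id50) || id50 < 60 || id50 > 100
  side <- NA_character_
  if (out_of_range) {
    # with a negative slope, detection decreases with %ID; if probability is
    # still > 0.5 at 100 %ID the crossing lies above the observable range
    p100 <- plogis(b[1] + b[2] * 100)
    p60 <- plogis(b[1] + b[2] * 60)
    side <- if (max(p100, p60) < 0.5) "none" else if (p100 > 0.5) "high" else "low"
  }
  structure(
    list(coefficients = c(intercept = b[1], slope = b[2]),
         id50 = if (out_of_range) NA_real_ else id50,
         id50_raw = id50,
         out_of_range = out_of_range, side = side,
         alpha = alpha, method = method, n = nrow(dat), model = fit),
    class = "cgh_id50")
}

#' @export
print.cgh_id50 <- function(x, ...) {
  cat(sprintf("<cgh_id50> logistic detection limit at alpha = %g (%s fit)\n",
              x$alpha, x$method))
  if (x$out_of_range) {
    cat(sprintf("  ID-50 out of range (side: %s); raw crossing %.2f\n",
                x$side, x$id50_raw))
  } else {
    cat(sprintf("  ID-50 = %.2f %%ID  (slope %.4f per %%ID, n = %d)\n",
                x$id50, x$coefficients[["slope"]], x$n))
  }
  invisible(x)
}

#' @export
tidy.cgh_id50 <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
         statistic = sm[, 3], p_value = sm[, 4])
}

#' @export
glance.cgh_id50 <- function(x, ...) {
  tibble(id50 = x$id50, out_of_range = x$out_of_range, side = x$side,
         alpha = x$alpha, n = x$n, method = x$method)
}

#' Linear regression of mean log2 ratio on %ID
#'
#' Ordinary least squares of the per-feature mean hybridization ratio on
#' percent identity, the calibration line at the heart of ratio-based
#' divergence estimation. Reports slope, intercept, R-squared, slope
#' standard error and p-value.
#'
#' @param data Tibble with `mean_M` and `pct_id` (NoHit features, whose
#'   %ID is undefined, are dropped).
#' @return A `cgh_linreg` object wrapping the `lm` fit.
#' @export
linreg_ratio_id <- function(data) {
  require_columns(data, c("mean_M", "pct_id"), "data")
  dat <- data |>
    filter(is.finite(.data$mean_M), is.finite(.data$pct_id))
  if (nrow(dat) < 3L) {
    abort("need at least 3 features with mean_M and %ID.",
          class = "cghdiv_input_error")
  }
  if (sd(dat$pct_id) == 0) {
    abort("%ID has zero variance; regression undefined.",
          class = "cghdiv_input_error")
  }
  fit <- lm(mean_M ~ pct_id, data = dat)
  sm <- summary(fit)
  structure(
    list(model = fit,
         intercept = unname(coef(fit)[1]),
         slope = unname(coef(fit)[2]),
         slope_se = sm$coefficients["pct_id", "Std. Error"],
         p_value = sm$coefficients["pct_id", "Pr(>|t|)"],
         r_squared = sm$r.squared,
         sigma = sm$sigma,
         n = nrow(dat),
         data = dat),
    class = "cgh_linreg")
}

#' @export
print.cgh_linreg <- function(x, ...) {
  cat(sprintf(
    "<cgh_linreg> mean_M ~ %%ID: slope %.4f (SE %.4f), R^2 = %.4f, n = %d\n",
    x$slope, x$slope_se, x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.cgh_linreg <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
         statistic = sm[, 3], p_value = sm[, 4])
}

#' @export
glance.cgh_linreg <- function(x, ...) {
  tibble(r_squared = x$r_squared, slope = x$slope, slope_se = x$slope_se,
         p_value = x$p_value, sigma = x$sigma, n = x$n)
}

#' Hybridization-kinetics regression
#'
#' Fits `mean_M ~ pct_id * (gc + length + align)`: main effects of %ID, GC
#' content, probe length and percent alignment length plus the interaction
#' of each covariate with %ID — the model used to ask which physical probe
#' characteristics modulate hybridization beyond sequence identity. With
#' `standardize = TRUE`, response and all explanatory variables are z-scored
#' first so estimates are comparable effect sizes.
#'
#' @param data Tibble with `mean_M`, `pct_id`, `gc_percent`,
#'   `probe_length_bp`, `pct_align`; rows with missing values are dropped.
#' @param standardize Standardize all variables to mean 0, SD 1 first?
#' @return A `cgh_kinetics` object; `tidy()` gives the term table
#'   (estimate, std_error, t_value, p_value).
#' @export
kinetics_regression <- function(data, standardize = FALSE) {
  require_columns(data, c("mean_M", "pct_id", "gc_percent",
                          "probe_length_bp", "pct_align"), "data")
  dat <- data |>
    transmute(M = .data$mean_M, id = .data$pct_id, gc = .data$gc_percent,
              length = .data$probe_length_bp, align = .data$pct_align) |>
    filter(complete.cases(across(everything())))
  if (nrow(dat) < 10L) {
    abort("too few complete rows for the kinetics regression.",
          class = "cghdiv_input_error")
  }
  id_scale <- c(mean(dat$id), sd(dat$id))
  if (standardize) {
    dat <- mutate(dat, across(everything(), zscore))
  }
  fit <- lm(M ~ id * (gc + length + align), data = dat)
  aliased <- summary(fit)$aliased
  if (any(aliased)) {
    abort(sprintf("rank-deficient kinetics model; collinear term(s): %s",
                  paste(names(aliased)[aliased], collapse = ", ")),
          class = "cghdiv_input_error")
  }
  sm <- summary(fit)$coefficients
  table <- tibble(term = rownames(sm), estimate = sm[, 1],
                  std_error = sm[, 2], t_value = sm[, 3], p_value = sm[, 4])
  out <- structure(
    list(table = table, model = fit, standardized = standardize,
         r_squared = summary(fit)$r.squared, n = nrow(dat)),
    class = "cgh_kinetics")
  attr(out, "id_scale") <- id_scale
  out
}

#' @export
print.cgh_kinetics <- function(x, ...) {
  cat(sprintf("<cgh_kinetics> mean_M ~ %%ID * (GC + length + %%align)%s, n = %d, R^2 = %.4f\n",
              if (x$standardized) " [standardized]" else "", x$n, x$r_squared))
  print(x$table, n = nrow(x$table))
  invisible(x)
}

#' @export
tidy.cgh_kinetics <- function(x, ...) x$table

#' @export
glance.cgh_kinetics <- function(x, ...) {
  tibble(r_squared = x$r_squared, n = x$n, standardized = x$standardized)
}

#' Standardized covariate effect sizes as functions of %ID
#'
#' For a standardized kinetics fit, the effect of covariate `c` at identity
#' `id` is `beta_c + beta_{id:c} * z(id)`; this evaluates those effect-size
#' curves over a grid of %ID values.
#'
#' @param fit A standardized `cgh_kinetics` fit.
#' @param pct_id_grid %ID values at which to evaluate (default 75..100).
#' @return Tibble `pct_id`, `term`, `effect_size`.
#' @export
standardized_effects <- function(fit, pct_id_grid = seq(75, 100, by = 1)) {
  stopifnot(inherits(fit, "cgh_kinetics"))
  if (!fit$standardized) {
    abort("fit must be standardized (kinetics_regression(standardize = TRUE)).",
          class = "cghdiv_input_error")
  }
  b <- coef(fit$model)
  # grid given in %ID units must be placed on the standardized axis used in
  # the fit; the caller's data scale is reconstructed from attributes
  sc <- attr(fit, "id_scale")
  z_grid <- if (is.null(sc)) zscore(pct_id_grid) else (pct_id_grid - sc[1]) / sc[2]
  map_dfr(c("gc", "length", "align"), function(cv) {
    tibble(pct_id = pct_id_grid, term = cv,
           effect_size = unname(b[cv] + b[paste0("id:", cv)] * z_grid))
  })
}
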