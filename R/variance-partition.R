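# Consistency factor of the median-absolute-residual scale estimator: the
# 0.75 standard-normal quantile, so that median(|r|)/KINETIC_SCALE_CONSTANT
# is consistent for the SD of normal residuals.
KINETIC_SCALE_CONSTANT <- 0.6745

#' Robust SD from the median absolute residual
#'
#' `median(|x|) / 0.6745`: for centered normal residuals this is a
#' consistent, outlier-resistant estimator of the standard deviation
#' (0.6745 being the 0.75 standard-normal quantile).
#'
#' @param x Numeric residuals.
#' @return Robust scale estimate.
#' @export
robust_scale <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  median(abs(x)) / KINETIC_SCALE_CONSTANT
}

#' Partition hybridization-ratio variance into technical and kinetic parts
#'
#' In sliding windows of features ordered by %ID, contrasts two sources of
#' scatter: *technical error*, the mean per-feature standard error of the
#' fitted mean ratio among replicate arrays, and *hybridization-kinetics
#' variation*, the robust SD ([robust_scale()]) of the residuals from the
#' ratio-vs-%ID regression line within the window. Conserved orthologs are
#' typically dominated by technical error, diverged ones by kinetics.
#'
#' @param data Tibble with `pct_id`, `n_used` and either `s2_post`
#'   (preferred; the moderated variance) or `s2`.
#' @param linreg Optional [linreg_ratio_id()] fit to take residuals from; by
#'   default it is fitted to `data` itself (requires `mean_M`).
#' @param window Odd sliding-window width in features (default 301, wider
#'   than the detection window so the median-based scale is stable).
#' @return A `cgh_variance_partition` tibble: `center_pct_id`,
#'   `technical_sd`, `kinetic_sd`, `window_lo`, `window_hi`.
#' @export
variance_partition <- function(data, linreg = NULL, window = 301) {
  require_columns(data, c("pct_id", "n_used"), "data")
  window <- assert_count(window, "window", lower = 3)
  if (window %% 2L == 0L) {
    abort("`window` must be odd.", class = "cghdiv_input_error")
  }
  if (is.null(linreg)) linreg <- linreg_ratio_id(data)
  s2_col <- if ("s2_post" %in% names(data)) "s2_post" else "s2"
  require_columns(data, s2_col, "data")

  dat <- data |>
    mutate(se_mean = sqrt(.data[[s2_col]] / .data$n_used),
           resid = .data$mean_M -
             (linreg$intercept + linreg$slope * .data$pct_id)) |>
    filter(is.finite(.data$pct_id), is.finite(.data$se_mean),
           is.finite(.data$resid)) |>
    arrange(.data$pct_id)
  n <- nrow(dat)
  if (n < window) {
    abort(sprintf("need at least %d usable features, got %d", window, n),
          class = "cghdiv_input_error")
  }
  half <- (window - 1L) %/% 2L
  centers <- (half + 1L):(n - half)
  roll_mean <- function(x) {
    cs <- cumsum(c(0, x))
    (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  }
  abs_resid <- abs(dat$resid)
  kinetic <- vapply(centers, function(i) {
    median(abs_resid[(i - half):(i + half)])
  }, numeric(1)) / KINETIC_SCALE_CONSTANT
  out <- tibble(
    center_pct_id = roll_mean(dat$pct_id),
    technical_sd = roll_mean(dat$se_mean),
    kinetic_sd = kinetic,
    window_lo = dat$pct_id[centers - half],
    window_hi = dat$pct_id[centers + half]
  )
  class(out) <- c("cgh_variance_partition", class(out))
  attr(out, "window") <- window
  out
}

#' Crossover %ID between kinetic and technical variation
#'
#' The %ID below which hybridization-kinetics variation exceeds technical
#' error: found as the highest-%ID sign change of `kinetic_sd -
#' technical_sd` along the partition curves, located by linear
#' interpolation. Returns the crossover and the local window width (the
#' natural resolution of the estimate).
#'
#' @param vp A `cgh_variance_partition` tibble.
#' @return A list with `crossover_pct_id` (NA if the curves never cross) and
#'   `bin_width`.
#' @export
partition_crossover <- function(vp) {
  stopifnot(inherits(vp, "cgh_variance_partition"))
  d <- vp$kinetic_sd - vp$technical_sd
  x <- vp$center_pct_id
  sign_change <- which(d[-length(d)] * d[-1] < 0 |
                         (d[-length(d)] == 0 & d[-1] != 0))
  if (!length(sign_change)) {
    return(list(crossover_pct_id = NA_real_,
                bin_width = mean(vp$window_hi - vp$window_lo)))
  }
  i <- max(sign_change)  # highest-%ID crossing
  x0 <- x[i]; x1 <- x[i + 1]
  d0 <- d[i]; d1 <- d[i + 1]
  cross <- x0 + (0 - d0) * (x1 - x0) / (d1 - d0)
  list(crossover_pct_id = cross,
       bin_width = mean(vp$window_hi[c(i, i + 1)] - vp$window_lo[c(i, i + 1)]))
}
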