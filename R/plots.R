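# ggplot2 views of the main result types. Each autoplot() returns a plot
# the caller can restyle; nothing is drawn as a side effect.

#' @export
autoplot.cgh_detection_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$center_pct_id)) +
    geom_point(aes(y = .data$fraction, colour = .data$alpha),
               size = 0.4, alpha = 0.3) +
    geom_line(aes(y = .data$smooth, colour = .data$alpha,
                  linetype = .data$alpha), linewidth = 0.8) +
    scale_y_continuous(labels = function(x) 100 * x) +
    labs(x = "% identity to platform species",
         y = "% features called diverged",
         colour = "FDR level", linetype = "FDR level") +
    theme_minimal()
}

#' @export
autoplot.cgh_variance_partition <- function(object, ...) {
  long <- object |>
    pivot_longer(c("technical_sd", "kinetic_sd"),
                 names_to = "source", values_to = "sd") |>
    mutate(source = ifelse(.data$source == "technical_sd",
                           "technical error", "hybridization kinetics"))
  ggplot(long, aes(x = .data$center_pct_id, y = .data$sd,
                   colour = .data$source)) +
    geom_line(linewidth = 0.8) +
    labs(x = "% identity to platform species", y = "SD (log2 ratio)",
         colour = NULL) +
    theme_minimal()
}

#' @export
autoplot.cgh_replication <- function(object, ...) {
  ggplot(object$se_curve,
         aes(x = .data$bin_center, y = .data$mean_se,
             colour = factor(.data$k), group = .data$k)) +
    geom_line(linewidth = 0.8) +
    geom_point(size = 1.5) +
    labs(x = "% identity to platform species",
         y = "mean SE of fitted ratio", colour = "arrays") +
    theme_minimal()
}

#' Scatter of mean log2 ratio against %ID with the calibration line
#'
#' @param data Tibble with `mean_M` and `pct_id`.
#' @param linreg Optional [linreg_ratio_id()] fit (fitted on the fly
#'   otherwise).
#' @return A ggplot.
#' @export
plot_ratio_vs_id <- function(data, linreg = NULL) {
  if (is.null(linreg)) linreg <- linreg_ratio_id(data)
  dat <- filter(data, is.finite(.data$mean_M), is.finite(.data$pct_id))
  ggplot(dat, aes(x = .data$pct_id, y = .data$mean_M)) +
    geom_point(size = 0.3, alpha = 0.2) +
    geom_abline(intercept = linreg$intercept, slope = linreg$slope,
                colour = "red") +
    labs(x = "% identity to platform species",
         y = "mean log2 hybridization ratio (M)") +
    theme_minimal()
}
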