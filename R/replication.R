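#' Replication power analysis over array subsets
#'
#' Repeats the complete divergence analysis (per-feature statistics,
#' variance shrinkage, FDR calls, logistic ID-50, ratio-vs-%ID regression)
#' on every k-array combination of the available arrays for each `k` in
#' `k_list`, and summarizes how detection power grows with technical
#' replication: the mean fraction of analyzed features called diverged at
#' `alpha`, the mean ID-50, the mean R-squared, and the mean per-feature
#' standard error of the fitted mean ratio within %ID bins. When the number
#' of combinations exceeds `max_combinations` a deterministic random sample
#' of that size is analyzed instead.
#'
#' @param ratios A `cgh_ratios` tibble covering all arrays.
#' @param annotations Tibble with `feature_id` and `true_pct_id` (or
#'   `pct_id`) giving each feature's percent identity.
#' @param k_list Replication levels to evaluate (default `c(2, 4, 6, 8)`).
#' @param alpha Divergence call threshold summarized (default 0.1).
#' @param min_arrays Multi-array survival rule applied within each subset.
#' @param max_combinations Cap on combinations per k (default 70, the
#'   number of 4-of-8 subsets, so an 8-array design is always exhaustive).
#' @param bin_breaks %ID bin edges for the SE summary (default every
#'   5 %ID from 60 to 100).
#' @param subsample_seed Seed used only when combinations must be sampled.
#' @return A `cgh_replication` object: list with `summary` (tibble per k:
#'   `k`, `n_combinations`, `n_analyzed`, `pct_diverged`, `id50`,
#'   `r_squared`) and `se_curve` (tibble `k`, `bin_center`, `mean_se`).
#' @export
replication_power_analysis <- function(ratios, annotations,
                                       k_list = c(2, 4, 6, 8),
                                       alpha = 0.1,
                                       min_arrays = 2,
                                       max_combinations = 70,
                                       bin_breaks = seq(60, 100, by = 5),
                                       subsample_seed = 1L) {
  require_columns(ratios, c("feature_id", "array_id", "M", "usable"), "ratios")
  id_col <- if ("pct_id" %in% names(annotations)) "pct_id" else "true_pct_id"
  require_columns(annotations, c("feature_id", id_col), "annotations")
  pct_id_tbl <- annotations |>
    transmute(feature_id = .data$feature_id, pct_id = .data[[id_col]])

  arrays <- sort(unique(ratios$array_id))
  n_arrays <- length(arrays)
  k_list <- sort(unique(as.integer(k_list)))
  if (any(k_list > n_arrays)) {
    abort(sprintf("k = %d exceeds the %d available arrays",
                  max(k_list), n_arrays),
          class = "cghdiv_input_error")
  }
  tag <- paste0("diverged_", threshold_tag(alpha))

  # wide matrix once; per-subset statistics are then plain row operations
  M_wide <- ratios |>
    mutate(M = ifelse(.data$usable, .data$M, NA_real_)) |>
    select("feature_id", "array_id", "M") |>
    pivot_wider(names_from = "array_id", values_from = "M")
  M_mat <- as.matrix(M_wide[, arrays, drop = FALSE])
  rownames(M_mat) <- M_wide$feature_id

  analyze_subset <- function(cols) {
    sub <- M_mat[, cols, drop = FALSE]
    n_used <- rowSums(!is.na(sub))
    mean_M <- rowMeans(sub, na.rm = TRUE)
    s2 <- (rowSums(sub^2, na.rm = TRUE) - n_used * mean_M^2) /
      pmax(1, n_used - 1)
    s2 <- pmax(0, s2)  # guard tiny negative values from cancellation
    stats <- tibble(feature_id = rownames(sub), n_used = n_used,
                    mean_M = ifelse(n_used >= 2, mean_M, NA_real_),
                    s2 = ifelse(n_used >= 2, s2, NA_real_))
    mod <- shrink_variances(stats)
    calls <- call_diverged(mod, thresholds = alpha) |>
      left_join(pct_id_tbl, by = "feature_id")
    analyzed <- calls |> filter(.data$n_used >= min_arrays)
    id50 <- tryCatch(fit_id50(analyzed, alpha = alpha)$id50_raw,
                     error = function(e) NA_real_)
    lr <- tryCatch(linreg_ratio_id(analyzed), error = function(e) NULL)
    se <- analyzed |>
      filter(is.finite(.data$pct_id)) |>
      mutate(se_mean = sqrt(.data$s2_post / .data$n_used),
             bin = cut(.data$pct_id, breaks = bin_breaks,
                       include.lowest = TRUE)) |>
      filter(!is.na(.data$bin), is.finite(.data$se_mean)) |>
      group_by(.data$bin) |>
      summarise(mean_se = mean(.data$se_mean), .groups = "drop")
    list(n_analyzed = nrow(analyzed),
         pct_diverged = 100 * mean(analyzed[[tag]]),
         id50 = id50,
         r_squared = if (is.null(lr)) NA_real_ else lr$r_squared,
         se = se)
  }

  summaries <- vector("list", length(k_list))
  se_curves <- vector("list", length(k_list))
  for (j in seq_along(k_list)) {
    k <- k_list[j]
    combos <- combn(arrays, k, simplify = FALSE)
    if (length(combos) > max_combinations) {
      combos <- with_seed_preserved(subsample_seed, {
        combos[sample.int(length(combos), max_combinations)]
      })
    }
    res <- map(combos, analyze_subset)
    summaries[[j]] <- tibble(
      k = k,
      n_combinations = length(combos),
      n_analyzed = mean(map_dbl(res, "n_analyzed")),
      pct_diverged = mean(map_dbl(res, "pct_diverged")),
      id50 = mean(map_dbl(res, "id50"), na.rm = TRUE),
      r_squared = mean(map_dbl(res, "r_squared"), na.rm = TRUE)
    )
    se_curves[[j]] <- map(res, "se") |>
      list_rbind() |>
      group_by(.data$bin) |>
      summarise(mean_se = mean(.data$mean_se), .groups = "drop") |>
      mutate(k = k)
  }

  mids <- (head(bin_breaks, -1) + tail(bin_breaks, -1)) / 2
  labs <- levels(cut(bin_breaks[1], breaks = bin_breaks,
                     include.lowest = TRUE))
  se_curve <- list_rbind(se_curves) |>
    mutate(bin_center = mids[match(as.character(.data$bin), labs)]) |>
    select("k", "bin_center", bin_label = "bin", "mean_se")

  structure(list(summary = list_rbind(summaries), se_curve = se_curve,
                 alpha = alpha, arrays = arrays),
            class = "cgh_replication")
}

#' @export
print.cgh_replication <- function(x, ...) {
  cat(sprintf("<cgh_replication> power analysis at alpha = %g over %d arrays\n",
              x$alpha, length(x$arrays)))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.cgh_replication <- function(x, ...) x$summary
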