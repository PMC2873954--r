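#' Read a GPR-like two-channel scan file
#'
#' Parses the tab-separated scan dialect written by [write_dataset()]:
#' comment lines prefixed `#` carry `array_id` and `dye_swapped`, followed
#' by a header row and one row per feature with columns `feature_id`,
#' `F635`, `B635`, `F532`, `B532`, `flag`. Unknown columns are ignored.
#'
#' @param path Path to the scan TSV.
#' @return A `cgh_scan` tibble with attributes `array_id` and `dye_swapped`.
#' @export
read_array_scan <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("scan file '%s' does not exist", path),
          class = "cghdiv_io_error")
  }
  head_lines <- readLines(path, n = 20L)
  comments <- grep("^#", head_lines, value = TRUE)
  grab <- function(key, default) {
    hit <- grep(sprintf("^#\\s*%s\\s*:", key), comments, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub(sprintf("^#\\s*%s\\s*:", key), "", hit[1]))
  }
  array_id <- grab("array_id", sub("\\.tsv$", "", basename(path)))
  dye_swapped <- tolower(grab("dye_swapped", "false")) %in%
    c("true", "1", "yes")

  # numeric fields are parsed via base strtod (exactly rounded) so that
  # written datasets round-trip bit-exactly
  scan <- read_tsv(path, comment = "#", show_col_types = FALSE,
                   progress = FALSE,
                   col_types = cols(.default = col_character()))
  require_columns(scan, c("feature_id", "F635", "B635", "F532", "B532", "flag"),
                  sprintf("scan file '%s'", basename(path)))
  scan <- scan |>
    select("feature_id", "F635", "B635", "F532", "B532", "flag") |>
    mutate(across(c("F635", "B635", "F532", "B532"), as.numeric),
           flag = as.integer(.data$flag))
  if (anyDuplicated(scan$feature_id)) {
    abort(sprintf("scan '%s' has duplicated feature ids", array_id),
          class = "cghdiv_format_error")
  }
  attr(scan, "array_id") <- array_id
  attr(scan, "dye_swapped") <- dye_swapped
  class(scan) <- c("cgh_scan", class(scan))
  scan
}

#' Quality filter on signal over background
#'
#' An observation is usable iff, in both channels, the foreground intensity
#' is at least the background plus `k_sd` standard deviations of that
#' channel's background (SD taken across the array's features), and the
#' feature's flag is non-negative. The boundary is inclusive. If nothing
#' survives, a warning is raised and an all-FALSE result returned.
#'
#' @param scan A `cgh_scan`.
#' @param k_sd Number of background SDs a signal must clear (default 2).
#' @return A tibble `feature_id`, `usable`.
#' @export
quality_filter <- function(scan, k_sd = 2) {
  require_columns(scan, c("feature_id", "F635", "B635", "F532", "B532", "flag"),
                  "scan")
  assert_number(k_sd, "k_sd", lower = 0)
  sd635 <- sd(scan$B635)
  sd532 <- sd(scan$B532)
  usable <- scan$F635 >= scan$B635 + k_sd * sd635 &
    scan$F532 >= scan$B532 + k_sd * sd532 &
    scan$flag >= 0L
  if (!any(usable)) {
    warn(sprintf("quality filter removed every observation on array '%s'",
                 attr(scan, "array_id") %||% "?"))
  }
  tibble(feature_id = scan$feature_id, usable = usable)
}

#' "Minimum" background correction
#'
#' Per channel, corrected intensity is foreground minus background; any
#' result at or below zero is replaced by half the smallest positive
#' corrected value on that array and channel, so all corrected intensities
#' are strictly positive (the "minimum" strategy of two-color preprocessing).
#'
#' @param scan A `cgh_scan`.
#' @return The scan with corrected-intensity columns `C635` and `C532`.
#' @export
background_correct_minimum <- function(scan) {
  require_columns(scan, c("F635", "B635", "F532", "B532"), "scan")
  fix <- function(x, channel) {
    pos <- x[x > 0]
    if (!length(pos)) {
      abort(sprintf(
        "no positive background-corrected intensity in channel %s of array '%s'",
        channel, attr(scan, "array_id") %||% "?"),
        class = "cghdiv_preprocess_error")
    }
    x[x <= 0] <- min(pos) / 2
    x
  }
  scan$C635 <- fix(scan$F635 - scan$B635, "635")
  scan$C532 <- fix(scan$F532 - scan$B532, "532")
  scan
}

#' Conserved-set loess normalization to an oriented ratio table
#'
#' Runs the full preprocessing chain on a set of scans: quality filtering
#' ([quality_filter()]), minimum background correction
#' ([background_correct_minimum()]), computation of per-feature M
#' (`log2(C635/C532)`) and A (average log2 intensity), a within-array loess
#' fit of M on A **using only usable conserved features** (the anchor set
#' with %ID >= 95, so diverged features cannot distort the curve) subtracted
#' from all features, a final median-centering on the anchor set (conserved
#' orthologs hybridize equally by definition, so their median M is pinned at
#' zero), and negation of dye-swapped arrays so that every column is
#' oriented as `log2(heterologous / platform)`. Features usable on at least
#' `min_arrays` arrays are flagged `analyzed`.
#'
#' @param scans Named list of `cgh_scan` tibbles.
#' @param annotations Tibble with `feature_id` and logical `conserved`.
#' @param span Loess span (default 0.4).
#' @param degree Local polynomial degree of the loess fit (default 2:
#'   locally quadratic; degree-1 local lines cannot track the curvature of
#'   realistic intensity trends over spans this wide and leave a visible
#'   residual trend).
#' @param k_sd Quality-filter threshold passed to [quality_filter()].
#' @param min_arrays Multi-array survival rule: minimum usable arrays for a
#'   feature to be analyzed (default 2).
#' @param min_conserved Minimum usable conserved features per array required
#'   to fit the normalization curve.
#' @return A `cgh_ratios` tibble in long form: `feature_id`, `array_id`,
#'   `dye_swapped`, `A`, `M` (NA where masked), `usable`, `analyzed`.
#' @export
normalize_loess_conserved <- function(scans, annotations, span = 0.4,
                                      degree = 2, k_sd = 2, min_arrays = 2,
                                      min_conserved = 50) {
  require_columns(annotations, c("feature_id", "conserved"), "annotations")
  assert_number(span, "span", lower = 0.05, upper = 1)
  min_arrays <- assert_count(min_arrays, "min_arrays", lower = 1)
  conserved_ids <- annotations$feature_id[annotations$conserved]

  per_array <- imap(scans, function(scan, aid) {
    aid <- attr(scan, "array_id") %||% aid
    swapped <- isTRUE(attr(scan, "dye_swapped"))
    usable <- quality_filter(scan, k_sd = k_sd)$usable
    scan <- background_correct_minimum(scan)
    M_raw <- log2(scan$C635 / scan$C532)
    A <- 0.5 * log2(scan$C635 * scan$C532)

    anchor <- usable & scan$feature_id %in% conserved_ids
    if (sum(anchor) < min_conserved) {
      abort(sprintf(
        "array '%s': only %d usable conserved features (need >= %d) for loess",
        aid, sum(anchor), min_conserved),
        class = "cghdiv_normalization_error")
    }
    fit <- loess(M_raw[anchor] ~ A[anchor], span = span, degree = degree,
                 family = "symmetric",
                 control = loess.control(surface = "direct", iterations = 4))
    trend_hat <- predict(fit, newdata = A)
    M_norm <- M_raw - trend_hat
    # anchor the conserved set at exactly zero: the loess targets a robust
    # mean, so a final median-centering on the anchors pins the location
    M_norm <- M_norm - median(M_norm[anchor])
    M_oriented <- if (swapped) -M_norm else M_norm
    tibble(feature_id = scan$feature_id,
           array_id = aid,
           dye_swapped = swapped,
           A = A,
           M = ifelse(usable, M_oriented, NA_real_),
           usable = usable)
  })

  ratios <- list_rbind(unname(per_array))
  survival <- ratios |>
    group_by(.data$feature_id) |>
    summarise(n_usable = sum(.data$usable), .groups = "drop") |>
    mutate(analyzed = .data$n_usable >= min_arrays)
  ratios <- ratios |>
    left_join(select(survival, "feature_id", "analyzed"), by = "feature_id")
  class(ratios) <- c("cgh_ratios", class(ratios))
  attr(ratios, "min_arrays") <- min_arrays
  ratios
}

#' Write / read a normalized ratio table
#'
#' The on-disk shape is wide: `feature_id`, one `M` column per array, an
#' `analyzed` flag; masked cells are `NA`.
#'
#' @param ratios A `cgh_ratios` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ratio_matrix <- function(ratios, path) {
  wide <- ratios |>
    select("feature_id", "array_id", "M", "analyzed") |>
    pivot_wider(names_from = "array_id", values_from = "M")
  write_tsv(relocate(wide, "analyzed", .after = last_col()), path)
  invisible(path)
}
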