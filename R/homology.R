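#' Parse BLAST tabular output (12-column outfmt 6)
#'
#' Reads the standard 12-column tab-separated BLAST dialect: query id,
#' subject id, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, e-value, bit score. Rows with the
#' wrong column count or non-numeric fields raise a format error naming the
#' offending line numbers. An empty file yields an empty tibble.
#'
#' @param path Path to the BLAST tabular file.
#' @return Tibble with columns `qseqid`, `sseqid`, `pident`, `length`,
#'   `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`, `evalue`,
#'   `bitscore`, plus `line` (source line number, used for deterministic
#'   tie-breaking).
#' @export
parse_blast_tabular <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("BLAST file '%s' does not exist", path),
          class = "cghdiv_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (!length(lines)) {
    out <- as_tibble(setNames(
      c(list(character(), character()), rep(list(numeric()), 10)), cols))
    out$line <- integer()
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield != 12L)
  if (length(bad)) {
    abort(sprintf("malformed BLAST rows (expected 12 columns) at line(s): %s",
                  paste(head(bad, 10), collapse = ", ")),
          class = "cghdiv_format_error")
  }
  mat <- do.call(rbind, parts)
  out <- tibble(qseqid = mat[, 1], sseqid = mat[, 2])
  num <- suppressWarnings(
    matrix(as.numeric(mat[, 3:12]), ncol = 10))
  bad_num <- which(apply(is.na(num), 1, any))
  if (length(bad_num)) {
    abort(sprintf("non-numeric BLAST fields at line(s): %s",
                  paste(head(bad_num, 10), collapse = ", ")),
          class = "cghdiv_format_error")
  }
  for (i in seq_along(cols[-(1:2)])) out[[cols[i + 2L]]] <- num[, i]
  out$line <- seq_len(nrow(out))
  out
}

#' Top-hit %ID and percent alignment length per feature
#'
#' For each query, keeps the best hit passing the e-value threshold: the
#' smallest e-value, ties broken by larger bit score, then first occurrence
#' in the file. Reports the hit's percent identity and the percent
#' alignment length, `100 * alignment_length / probe_length` (allowed above
#' 100: insertions in the heterologous sequence can inflate the alignment).
#' Queries with no passing hit are reported with status `NoHit`.
#'
#' @param hits Tibble from [parse_blast_tabular()].
#' @param probe_lengths Tibble with `feature_id` and `probe_length_bp`
#'   covering every query.
#' @param evalue_max Maximum e-value of an acceptable hit (default 1e-14).
#' @return Tibble `feature_id`, `pct_id`, `pct_align`, `no_hit` — one row
#'   per distinct query id, in first-appearance order.
#' @export
top_hits <- function(hits, probe_lengths, evalue_max = 1e-14) {
  require_columns(hits, c("qseqid", "pident", "length", "evalue", "bitscore"),
                  "hits")
  require_columns(probe_lengths, c("feature_id", "probe_length_bp"),
                  "probe_lengths")
  assert_number(evalue_max, "evalue_max", lower = 0)
  queries <- unique(hits$qseqid)
  missing <- setdiff(queries, probe_lengths$feature_id)
  if (length(missing)) {
    abort(sprintf("no probe length for query id(s): %s",
                  paste(head(missing, 10), collapse = ", ")),
          class = "cghdiv_input_error")
  }
  if (!"line" %in% names(hits)) hits$line <- seq_len(nrow(hits))

  best <- hits |>
    filter(.data$evalue <= evalue_max) |>
    arrange(.data$evalue, desc(.data$bitscore), .data$line) |>
    distinct(.data$qseqid, .keep_all = TRUE)

  tibble(feature_id = queries) |>
    left_join(best, by = c(feature_id = "qseqid")) |>
    left_join(select(probe_lengths, "feature_id", "probe_length_bp"),
              by = "feature_id") |>
    transmute(
      feature_id = .data$feature_id,
      pct_id = .data$pident,
      pct_align = 100 * .data$length / .data$probe_length_bp,
      no_hit = is.na(.data$pident)
    )
}
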