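#' Write a synthetic dataset to disk
#'
#' Writes one GPR-like TSV per array (header lines prefixed `#` carry the
#' array id and dye orientation), the feature annotation TSV (with `NoHit`
#' sentinels for missing orthologs), the truth TSV and a JSON manifest
#' recording the seed and configuration. All numeric values are written at
#' full round-trip precision, so re-reading reproduces them bit-exactly and
#' regenerating with the same seed yields identical files.
#'
#' @param scans Named list of `cgh_scan` tibbles from [simulate_scans()].
#' @param annotations,truth Tibbles from [generate_feature_annotations()].
#' @param dir_path Output directory (created if absent).
#' @param cfg Optional [generator_config()] recorded in the manifest.
#' @return The manifest, invisibly.
#' @export
write_dataset <- function(scans, annotations, truth, dir_path, cfg = NULL) {
  ok <- dir.exists(dir_path) || dir.create(dir_path, recursive = TRUE)
  if (!ok || file.access(dir_path, 2) != 0) {
    abort(sprintf("cannot write to directory '%s'", dir_path),
          class = "cghdiv_io_error")
  }
  for (scan in scans) {
    if (!identical(scan$feature_id, annotations$feature_id)) {
      abort("scan feature ids do not match annotations.",
            class = "cghdiv_io_error")
    }
  }

  # 17 significant digits guarantee numeric round-trip through text
  fmt_full <- function(x) {
    if (!is.double(x)) return(x)
    out <- formatC(x, digits = 17, format = "g")
    out[is.na(x)] <- NA_character_
    out
  }

  scan_files <- map_chr(scans, function(scan) {
    aid <- attr(scan, "array_id")
    path <- file.path(dir_path, paste0("scan_", aid, ".tsv"))
    header <- c(sprintf("# array_id: %s", aid),
                sprintf("# dye_swapped: %s",
                        tolower(as.character(attr(scan, "dye_swapped")))))
    writeLines(header, path)
    write_tsv(mutate(as_tibble(scan), across(where(is.double), fmt_full)),
              path, append = TRUE, col_names = TRUE)
    basename(path)
  })

  ann_out <- annotations |>
    mutate(
      conserved = as.integer(.data$conserved),
      true_pct_id = ifelse(.data$no_hit, "NoHit",
                           fmt_full(.data$true_pct_id)),
      pct_align = ifelse(.data$no_hit, "NoHit", fmt_full(.data$pct_align)),
      across(where(is.double), fmt_full)
    ) |>
    select("feature_id", "gene_id", "probe_length_bp", "gc_percent",
           "conserved", "true_pct_id", "pct_align", "go_terms")
  write_tsv(ann_out, file.path(dir_path, "annotations.tsv"))
  write_tsv(mutate(truth, across(where(is.double), fmt_full)),
            file.path(dir_path, "truth.tsv"))

  manifest <- list(
    format = "cghdiv-synthetic-v1",
    n_features = nrow(annotations),
    n_arrays = length(scans),
    scan_files = unname(scan_files),
    annotation_file = "annotations.tsv",
    truth_file = "truth.tsv"
  )
  if (!is.null(cfg)) {
    manifest$seed <- cfg$seed
    manifest$config <- c(
      cfg[map_lgl(cfg, is.numeric)],
      list(sd_kinetic = paste(deparse(cfg$sd_kinetic), collapse = " "),
           sd_technical = paste(deparse(cfg$sd_technical), collapse = " "))
    )
  }
  jsonlite::write_json(manifest, file.path(dir_path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir_path Directory containing `manifest.json`.
#' @return A list with `scans`, `annotations`, `truth` and `manifest`.
#' @export
read_dataset <- function(dir_path) {
  mpath <- file.path(dir_path, "manifest.json")
  if (!file.exists(mpath)) {
    abort(sprintf("no manifest.json in '%s'", dir_path),
          class = "cghdiv_io_error")
  }
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  scans <- map(file.path(dir_path, manifest$scan_files), read_array_scan)
  names(scans) <- map_chr(scans, attr, "array_id")
  ann <- read_tsv(file.path(dir_path, manifest$annotation_file),
                  show_col_types = FALSE,
                  col_types = cols(.default = col_character()))
  ann <- ann |>
    mutate(
      no_hit = .data$true_pct_id == "NoHit",
      true_pct_id = suppressWarnings(as.numeric(.data$true_pct_id)),
      pct_align = suppressWarnings(as.numeric(.data$pct_align)),
      probe_length_bp = as.integer(.data$probe_length_bp),
      gc_percent = as.numeric(.data$gc_percent),
      conserved = .data$conserved == "1",
      go_terms = ifelse(is.na(.data$go_terms), "", .data$go_terms)
    )
  truth <- read_tsv(file.path(dir_path, manifest$truth_file),
                    show_col_types = FALSE,
                    col_types = cols(.default = col_character()))
  for (col in names(truth)) {
    if (col %in% c("feature_id", "gene_id", "go_terms")) next
    truth[[col]] <- if (all(truth[[col]] %in% c("TRUE", "FALSE", NA))) {
      truth[[col]] == "TRUE"
    } else if (col == "probe_length_bp") {
      as.integer(truth[[col]])
    } else {
      as.numeric(truth[[col]])
    }
  }
  if ("go_terms" %in% names(truth)) {
    truth$go_terms <- ifelse(is.na(truth$go_terms), "", truth$go_terms)
  }
  list(scans = scans, annotations = ann, truth = truth, manifest = manifest)
}
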