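#' Propagate GO annotations to ancestor terms
#'
#' Applies the true-path rule: a gene annotated to a term is annotated to
#' every ancestor of that term in the DAG. The edge list must be acyclic
#' (checked by Kahn's algorithm; a cycle raises an error listing the terms
#' involved). The operation is idempotent and uses set semantics, so a
#' diamond (two paths to the root) annotates the root once.
#'
#' @param annotations Tibble with `gene_id`, `term_id` (direct annotations).
#' @param dag_edges Tibble with `child`, `parent` term columns.
#' @return A `cgh_go` object: list with `annotations` (propagated tibble
#'   `gene_id`, `term_id`), `edges`, and `ancestors` (named list).
#' @export
propagate_annotations <- function(annotations, dag_edges) {
  require_columns(annotations, c("gene_id", "term_id"), "annotations")
  require_columns(dag_edges, c("child", "parent"), "dag_edges")
  terms <- unique(c(dag_edges$child, dag_edges$parent, annotations$term_id))

  # Kahn's algorithm over child -> parent edges to certify acyclicity
  parents_of <- split(dag_edges$parent, dag_edges$child)
  out_deg <- setNames(integer(length(terms)), terms)
  out_deg[names(parents_of)] <- lengths(parents_of)
  children_of <- split(dag_edges$child, dag_edges$parent)
  queue <- names(out_deg)[out_deg == 0L]
  seen <- 0L
  deg <- out_deg
  while (length(queue)) {
    t0 <- queue[[1]]; queue <- queue[-1]
    seen <- seen + 1L
    for (ch in children_of[[t0]] %||% character()) {
      deg[ch] <- deg[ch] - 1L
      if (deg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(terms)) {
    cyc <- names(deg)[deg > 0L]
    abort(sprintf("GO edge list contains a cycle involving: %s",
                  paste(head(cyc, 10), collapse = ", ")),
          class = "cghdiv_input_error")
  }

  # ancestor closure per term, memoized
  anc_env <- new.env(parent = emptyenv())
  ancestors <- function(term) {
    if (!is.null(anc_env[[term]])) return(anc_env[[term]])
    ps <- parents_of[[term]]
    res <- if (is.null(ps)) character() else {
      unique(c(ps, unlist(lapply(ps, ancestors), use.names = FALSE)))
    }
    anc_env[[term]] <- res
    res
  }
  anc_list <- setNames(lapply(terms, ancestors), terms)

  direct <- distinct(annotations, .data$gene_id, .data$term_id)
  extra <- direct |>
    mutate(all_terms = lapply(.data$term_id,
                              function(t) c(t, anc_list[[t]]))) |>
    select("gene_id", "all_terms") |>
    tidyr::unnest_longer("all_terms", values_to = "term_id")
  propagated <- distinct(extra, .data$gene_id, .data$term_id) |>
    arrange(.data$gene_id, .data$term_id)

  structure(list(annotations = propagated, edges = as_tibble(dag_edges),
                 ancestors = anc_list),
            class = "cgh_go")
}

#' @export
print.cgh_go <- function(x, ...) {
  cat(sprintf("<cgh_go> %d propagated annotations, %d terms, %d genes\n",
              nrow(x$annotations), length(unique(x$annotations$term_id)),
              length(unique(x$annotations$gene_id))))
  invisible(x)
}

#' Hypergeometric over/under-representation of GO terms
#'
#' For every term with at least one annotated universe gene, computes the
#' inclusive upper-tail probability `P[X >= k]` (over-representation) and
#' lower-tail probability `P[X <= k]` (under-representation) of the number
#' of set genes annotated to the term, under hypergeometric sampling from
#' the universe. Following common practice for this analysis the universe
#' is restricted to genes carrying at least one annotation, and p-values
#' are reported uncorrected (a BH option is available).
#'
#' @param set_genes Character vector, the gene set of interest; must be a
#'   subset of `universe_genes`.
#' @param universe_genes Character vector of analyzed genes.
#' @param go A `cgh_go` object (or a tibble `gene_id`, `term_id` of already
#'   propagated annotations).
#' @param p_cutoff Significance threshold for the direction flags
#'   (default 0.01).
#' @param adjust `"none"` (default) or `"BH"` applied per tail.
#' @return Tibble: `term_id`, `set_hits`, `set_size`, `universe_hits`,
#'   `universe_size`, `p_over`, `p_under`, `over_represented`,
#'   `under_represented`.
#' @export
hypergeom_test <- function(set_genes, universe_genes, go,
                           p_cutoff = 0.01, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  ann <- if (inherits(go, "cgh_go")) go$annotations else as_tibble(go)
  require_columns(ann, c("gene_id", "term_id"), "annotations")
  if (!length(set_genes) || !length(universe_genes)) {
    abort("set and universe must be non-empty.", class = "cghdiv_input_error")
  }
  offenders <- setdiff(set_genes, universe_genes)
  if (length(offenders)) {
    abort(sprintf("set genes not in universe: %s",
                  paste(head(offenders, 10), collapse = ", ")),
          class = "cghdiv_input_error")
  }
  annotated <- unique(ann$gene_id)
  universe <- intersect(unique(universe_genes), annotated)
  set <- intersect(unique(set_genes), universe)
  N <- length(universe)
  n <- length(set)
  if (N == 0L) {
    abort("no universe gene carries an annotation.",
          class = "cghdiv_input_error")
  }

  ann_u <- ann |> filter(.data$gene_id %in% universe)
  per_term <- ann_u |>
    group_by(.data$term_id) |>
    summarise(universe_hits = n_distinct(.data$gene_id),
              set_hits = n_distinct(intersect(.data$gene_id, set)),
              .groups = "drop")

  out <- per_term |>
    mutate(
      set_size = n,
      universe_size = N,
      # inclusive tails: P[X >= k] and P[X <= k]
      p_over = phyper(.data$set_hits - 1, .data$universe_hits,
                      N - .data$universe_hits, n, lower.tail = FALSE),
      p_under = phyper(.data$set_hits, .data$universe_hits,
                       N - .data$universe_hits, n)
    )
  if (adjust == "BH") {
    out <- out |>
      mutate(p_over = bh_fdr(.data$p_over), p_under = bh_fdr(.data$p_under))
  }
  out |>
    mutate(over_represented = .data$p_over < p_cutoff,
           under_represented = .data$p_under < p_cutoff) |>
    select("term_id", "set_hits", "set_size", "universe_hits",
           "universe_size", "p_over", "p_under", "over_represented",
           "under_represented") |>
    arrange(.data$p_over)
}

#' Highly diverged gene sets and their cross-species intersection
#'
#' A feature belongs to a species' highly diverged set iff its mean log2
#' ratio shows **greater than** `fold`-fold reduction, i.e.
#' `mean_M < -log2(fold)` (strict; a ratio of exactly 1/fold is excluded).
#' Features are collapsed to genes (a gene qualifies if any of its features
#' does), the intersection across all supplied species is formed, and a
#' per-gene report of each species' %ID (`NoHit` where the ortholog had no
#' BLAST hit) is emitted.
#'
#' @param species_calls Named list of per-species tibbles, each with
#'   `feature_id`, `gene_id`, `mean_M`, and `pct_id` (NA for no-hit).
#' @param fold Fold-reduction threshold, > 1 (default 4).
#' @return A list with `sets` (named list of per-species gene id vectors),
#'   `intersection` (gene ids diverged in every species), and `table` (one
#'   row per intersection gene; minimum qualifying-feature %ID per species,
#'   formatted, `NoHit` when absent).
#' @export
highly_diverged_sets <- function(species_calls, fold = 4) {
  assert_number(fold, "fold")
  if (fold <= 1) {
    abort("`fold` must be > 1.", class = "cghdiv_input_error")
  }
  if (is.null(names(species_calls)) || any(!nzchar(names(species_calls)))) {
    abort("`species_calls` must be a named list.",
          class = "cghdiv_input_error")
  }
  cutoff <- -log2(fold)
  qualifying <- map(species_calls, function(tb) {
    require_columns(tb, c("feature_id", "gene_id", "mean_M"), "species table")
    if (!"pct_id" %in% names(tb)) tb$pct_id <- NA_real_
    tb |> filter(is.finite(.data$mean_M), .data$mean_M < cutoff)
  })
  sets <- map(qualifying, function(tb) unique(tb$gene_id))
  intersection <- Reduce(intersect, sets)

  table <- map(names(species_calls), function(sp) {
    qualifying[[sp]] |>
      filter(.data$gene_id %in% intersection) |>
      group_by(.data$gene_id) |>
      summarise(
        pct_id = if (all(is.na(.data$pct_id))) "NoHit" else
          format(round(min(.data$pct_id, na.rm = TRUE), 2), nsmall = 2),
        .groups = "drop") |>
      mutate(species = sp)
  }) |>
    list_rbind() |>
    pivot_wider(names_from = "species", values_from = "pct_id",
                names_prefix = "pct_id_") |>
    arrange(.data$gene_id)

  list(sets = sets, intersection = sort(intersection), table = table)
}
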