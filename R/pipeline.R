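#' Pipeline configuration
#'
#' Bundles every setting of an end-to-end divergence analysis: per-species
#' inputs (either a simulate block — species profile plus array count — or a
#' directory of scan files written by [write_dataset()]), the analysis
#' thresholds, window sizes and the master seed. Exactly one of
#' `profile`/`dir` must be given per species.
#'
#' @param species Named list; each element is a list with either `profile`
#'   (a [species_profile()]) and optional `n_arrays`, or `dir` (a dataset
#'   directory).
#' @param generator A [generator_config()] shared by all simulated species;
#'   its `seed` is overridden by `seed`.
#' @param seed Master seed for the run.
#' @param k_sd Quality-filter threshold ([quality_filter()]).
#' @param q_levels Divergence-call q-value thresholds.
#' @param fold Fold-reduction threshold for highly diverged sets.
#' @param go_p GO significance threshold.
#' @param loess_span Normalization loess span.
#' @param min_arrays Multi-array survival rule.
#' @param detection_window Moving-window width for [detection_curve()].
#' @param partition_window Sliding-window width for [variance_partition()].
#' @param replication_k Array-subset sizes for the power analysis, run for
#'   every species with at least `max(replication_k)` arrays; `NULL`
#'   disables it.
#' @return A validated `cgh_pipeline_config`.
#' @export
pipeline_config <- function(species,
                            generator = generator_config(),
                            seed = 1L,
                            k_sd = 2,
                            q_levels = c(0.1, 0.05, 0.01),
                            fold = 4,
                            go_p = 0.01,
                            loess_span = 0.4,
                            min_arrays = 2,
                            detection_window = 51,
                            partition_window = 301,
                            replication_k = c(2, 4, 6, 8)) {
  if (!is.list(species) || !length(species) || is.null(names(species)) ||
      any(!nzchar(names(species)))) {
    abort("`species` must be a non-empty named list.",
          class = "cghdiv_config_error")
  }
  for (nm in names(species)) {
    sp <- species[[nm]]
    has_profile <- !is.null(sp$profile)
    has_dir <- !is.null(sp$dir)
    if (has_profile == has_dir) {
      abort(sprintf(
        "species '%s' must have exactly one of `profile` (simulate) or `dir` (files)",
        nm), class = "cghdiv_config_error")
    }
    if (has_profile && !inherits(sp$profile, "cgh_species_profile")) {
      abort(sprintf("species '%s': `profile` must be a species_profile()", nm),
            class = "cghdiv_config_error")
    }
  }
  stopifnot(inherits(generator, "cgh_generator_config"))
  seed <- assert_count(seed, "seed")
  assert_number(k_sd, "k_sd", lower = 0)
  if (any(q_levels <= 0 | q_levels >= 1)) {
    abort("`q_levels` must lie in (0, 1).", class = "cghdiv_config_error")
  }
  assert_number(fold, "fold", lower = 1 + 1e-9)
  assert_number(go_p, "go_p", 0, 1)
  assert_number(loess_span, "loess_span", 0.05, 1)
  min_arrays <- assert_count(min_arrays, "min_arrays", lower = 1)
  detection_window <- assert_count(detection_window, "detection_window", 3)
  partition_window <- assert_count(partition_window, "partition_window", 3)
  generator$seed <- seed
  structure(
    list(species = species, generator = generator, seed = seed, k_sd = k_sd,
         q_levels = sort(q_levels, decreasing = TRUE), fold = fold,
         go_p = go_p, loess_span = loess_span, min_arrays = min_arrays,
         detection_window = detection_window,
         partition_window = partition_window,
         replication_k = replication_k),
    class = "cgh_pipeline_config")
}

#' Default three-species simulated study
#'
#' The default configuration emulates the structure of a platform-species
#' versus three heterologous species study: two closely diverged species
#' with two dye-swapped arrays each, and one distantly diverged species
#' with eight arrays (the replication-analysis species).
#'
#' @param seed Master seed.
#' @param n_features Features per array.
#' @param conserved_n Conserved anchor-set size.
#' @return A `cgh_pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L, n_features = 18000L,
                                    conserved_n = 1000L) {
  pipeline_config(
    species = list(
      species_A = list(profile = profile_closely_diverged("species_A"),
                       n_arrays = 2L),
      species_B = list(profile = profile_closely_diverged("species_B"),
                       n_arrays = 2L),
      species_C = list(profile = profile_distantly_diverged("species_C"),
                       n_arrays = 8L)
    ),
    generator = generator_config(n_features = n_features,
                                 conserved_n = conserved_n),
    seed = seed
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "cghdiv_pipeline_error", parent = e)
  })
}

#' Run the full divergence pipeline
#'
#' Executes simulate/read, preprocessing and normalization, moderated
#' divergence testing, ratio-vs-%ID calibration, variance partitioning,
#' optional replication power analysis, GO representation tests and the
#' cross-species four-fold intersection, and (optionally) writes all module
#' outputs plus a `summary.json` to `out_dir`. The run is a pure function
#' of the configuration: the same config (including seed) produces
#' byte-identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param quiet Suppress per-stage progress messages?
#' @return A `cgh_report` list: `species` (per-species result bundles),
#'   `intersection`, `summary`, `config`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "cgh_pipeline_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))
  t0 <- Sys.time()

  sim_names <- names(cfg$species)[map_lgl(cfg$species,
                                          function(s) !is.null(s$profile))]
  study_go <- NULL
  datasets <- list()
  if (length(sim_names)) {
    say("simulating %d species (seed %d)", length(sim_names), cfg$seed)
    profiles <- map(cfg$species[sim_names], "profile")
    n_arr <- map_dbl(cfg$species[sim_names], function(s) {
      s$n_arrays %||% cfg$generator$n_arrays
    })
    study <- stage("simulate",
                   simulate_study(cfg$generator, profiles,
                                  n_arrays_by_species = n_arr))
    names(study$species) <- sim_names
    datasets <- study$species
    study_go <- study$go
  }
  for (nm in setdiff(names(cfg$species), sim_names)) {
    say("reading species '%s' from %s", nm, cfg$species[[nm]]$dir)
    ds <- stage("read", read_dataset(cfg$species[[nm]]$dir))
    datasets[[nm]] <- list(annotations = ds$annotations, truth = ds$truth,
                           scans = ds$scans)
  }
  datasets <- datasets[names(cfg$species)]

  go <- if (!is.null(study_go)) {
    stage("go-propagation",
          propagate_annotations(study_go$annotations, study_go$edges))
  } else NULL

  results <- list()
  for (nm in names(datasets)) {
    say("analyzing species '%s'", nm)
    ds <- datasets[[nm]]
    ratios <- stage("normalize",
                    normalize_loess_conserved(ds$scans, ds$annotations,
                                              span = cfg$loess_span,
                                              k_sd = cfg$k_sd,
                                              min_arrays = cfg$min_arrays))
    mod <- stage("detect",
                 shrink_variances(fit_feature_stats(ratios)))
    calls <- call_diverged(mod, thresholds = cfg$q_levels)
    feat <- calls |>
      left_join(ds$annotations |>
                  select("feature_id", "gene_id", pct_id = "true_pct_id",
                         "no_hit", "gc_percent", "probe_length_bp",
                         "pct_align", "conserved"),
                by = "feature_id")
    analyzed <- feat |> filter(.data$n_used >= cfg$min_arrays)

    calib <- stage("calibrate", {
      dc <- tryCatch(detection_curve(analyzed, window = cfg$detection_window),
                     error = function(e) NULL)
      id50 <- tryCatch(fit_id50(analyzed, alpha = max(cfg$q_levels)),
                       error = function(e) NULL)
      lr <- tryCatch(linreg_ratio_id(analyzed), error = function(e) NULL)
      kin <- tryCatch(kinetics_regression(analyzed), error = function(e) NULL)
      vp <- tryCatch(variance_partition(analyzed, linreg = lr,
                                        window = cfg$partition_window),
                     error = function(e) NULL)
      list(detection = dc, id50 = id50, linreg = lr, kinetics = kin,
           partition = vp,
           crossover = if (is.null(vp)) NULL else partition_crossover(vp))
    })

    repl <- NULL
    if (!is.null(cfg$replication_k) &&
        length(unique(ratios$array_id)) >= max(cfg$replication_k)) {
      say("replication power analysis for '%s'", nm)
      repl <- stage("replication",
                    replication_power_analysis(
                      ratios,
                      transmute(ds$annotations,
                                feature_id = .data$feature_id,
                                pct_id = .data$true_pct_id),
                      k_list = cfg$replication_k,
                      alpha = max(cfg$q_levels),
                      min_arrays = cfg$min_arrays))
    }

    enrich <- NULL
    if (!is.null(go)) {
      enrich <- stage("enrich", {
        universe <- unique(analyzed$gene_id)
        div_col <- paste0("diverged_", threshold_tag(max(cfg$q_levels)))
        diverged_genes <- unique(analyzed$gene_id[analyzed[[div_col]]])
        fourfold <- analyzed |>
          filter(is.finite(.data$mean_M), .data$mean_M < -log2(cfg$fold))
        fourfold_genes <- unique(fourfold$gene_id)
        list(
          diverged = if (length(diverged_genes))
            hypergeom_test(diverged_genes, universe, go,
                           p_cutoff = cfg$go_p) else NULL,
          fourfold = if (length(fourfold_genes))
            hypergeom_test(fourfold_genes, universe, go,
                           p_cutoff = cfg$go_p) else NULL,
          fourfold_genes = fourfold_genes,
          n_fourfold_features = nrow(fourfold)
        )
      })
    }

    results[[nm]] <- list(ratios = ratios, calls = feat,
                          analyzed = analyzed, calibration = calib,
                          replication = repl, enrichment = enrich)
  }

  say("cross-species intersection")
  intersection <- stage("intersection", {
    tables <- map(results, function(r) {
      r$analyzed |>
        select("feature_id", "gene_id", "mean_M", "pct_id")
    })
    highly_diverged_sets(tables, fold = cfg$fold)
  })

  summary <- build_summary(cfg, results, intersection)
  report <- structure(
    list(species = results, intersection = intersection, go = go,
         summary = summary, config = cfg,
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "cgh_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

build_summary <- function(cfg, results, intersection) {
  species <- imap(results, function(r, nm) {
    an <- r$analyzed
    divergence <- map(cfg$q_levels, function(a) {
      tag <- threshold_tag(a)
      list(alpha = a,
           pct_significant = 100 * mean(an[[paste0("significant_", tag)]]),
           pct_diverged = 100 * mean(an[[paste0("diverged_", tag)]]))
    })
    names(divergence) <- map_chr(cfg$q_levels, threshold_tag)
    calib <- r$calibration
    list(
      n_features = nrow(r$calls),
      n_analyzed = nrow(an),
      divergence = divergence,
      id50 = if (is.null(calib$id50)) NULL else calib$id50$id50,
      r_squared = if (is.null(calib$linreg)) NULL else calib$linreg$r_squared,
      slope = if (is.null(calib$linreg)) NULL else calib$linreg$slope,
      variance_crossover_pct_id =
        if (is.null(calib$crossover)) NULL else
          calib$crossover$crossover_pct_id,
      n_fourfold_features =
        if (is.null(r$enrichment)) NULL else r$enrichment$n_fourfold_features,
      n_fourfold_genes = if (is.null(r$enrichment)) NULL else
        length(r$enrichment$fourfold_genes),
      go_terms_over = if (is.null(r$enrichment$fourfold)) NULL else
        sum(r$enrichment$fourfold$over_represented),
      go_terms_under = if (is.null(r$enrichment$diverged)) NULL else
        sum(r$enrichment$diverged$under_represented),
      replication = if (is.null(r$replication)) NULL else
        as.list(r$replication$summary)
    )
  })
  list(seed = cfg$seed,
       q_levels = cfg$q_levels,
       fold = cfg$fold,
       species = species,
       intersection_n_genes = length(intersection$intersection))
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$species)) {
    d <- file.path(out_dir, nm)
    dir.create(d, showWarnings = FALSE)
    r <- report$species[[nm]]
    write_ratio_matrix(r$ratios, file.path(d, "ratio_matrix.tsv"))
    write_tsv(
      as_tibble(r$calls) |>
        select(any_of(c("feature_id", "gene_id", "n_used", "mean_M", "s2",
                        "s2_post", "t_mod", "p", "q", "pct_id", "no_hit")),
               starts_with("significant_"), starts_with("diverged_")),
      file.path(d, "divergence_calls.tsv"))
    calib <- r$calibration
    if (!is.null(calib$detection)) {
      write_tsv(as_tibble(calib$detection),
                file.path(d, "detection_curve.tsv"))
    }
    if (!is.null(calib$partition)) {
      write_tsv(as_tibble(calib$partition),
                file.path(d, "variance_partition.tsv"))
    }
    cal_json <- list(
      id50 = if (is.null(calib$id50)) NULL else
        glance(calib$id50) |> as.list(),
      linreg = if (is.null(calib$linreg)) NULL else
        glance(calib$linreg) |> as.list(),
      kinetics = if (is.null(calib$kinetics)) NULL else
        list(terms = calib$kinetics$table,
             r_squared = calib$kinetics$r_squared)
    )
    jsonlite::write_json(cal_json, file.path(d, "calibration.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(r$replication)) {
      write_tsv(r$replication$summary, file.path(d, "replication.tsv"))
      write_tsv(r$replication$se_curve,
                file.path(d, "replication_se_curve.tsv"))
    }
    if (!is.null(r$enrichment)) {
      if (!is.null(r$enrichment$diverged)) {
        write_tsv(r$enrichment$diverged,
                  file.path(d, "go_diverged_set.tsv"))
      }
      if (!is.null(r$enrichment$fourfold)) {
        write_tsv(r$enrichment$fourfold,
                  file.path(d, "go_fourfold_set.tsv"))
      }
    }
  }
  write_tsv(report$intersection$table,
            file.path(out_dir, "intersection.tsv"))
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.cgh_report <- function(x, ...) {
  cat(sprintf("<cgh_report> %d species, seed %d (%.1f s)\n",
              length(x$species), x$config$seed, x$elapsed_s))
  for (nm in names(x$summary$species)) {
    s <- x$summary$species[[nm]]
    top <- s$divergence[[1]]
    cat(sprintf(
      "  %-10s analyzed %d/%d | diverged %.1f%% (q<%g) | ID-50 %s | R^2 %s\n",
      nm, s$n_analyzed, s$n_features, top$pct_diverged, top$alpha,
      if (is.null(s$id50)) "NA" else sprintf("%.1f", s$id50),
      if (is.null(s$r_squared)) "NA" else sprintf("%.3f", s$r_squared)))
  }
  cat(sprintf("  shared >%g-fold reduced genes: %d\n", x$config$fold,
              x$summary$intersection_n_genes))
  invisible(x)
}
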