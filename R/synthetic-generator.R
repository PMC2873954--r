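#' Configuration for the synthetic aCGH generator
#'
#' Collects every knob of the synthetic two-color aCGH study: array geometry,
#' the planted mean model linking log2 hybridization ratio (M) to percent
#' identity and probe covariates, the two noise processes (per-feature
#' hybridization-kinetics deviation and per-observation technical noise),
#' dye structure, intensity-dependent curvature, backgrounds, and the
#' fraction of observations forced below the quality filter.
#'
#' The planted mean for feature f is
#' \deqn{\mu_f = \beta_0 + \beta_{id}(ID_f - 100) +
#'   \left[\beta_{gc} z(GC_f) + \beta_{len} z(L_f) +
#'   \beta_{align} z(PA_f)\right] w_f + \beta_{id:gc} z(GC_f)(ID_f - 100)}
#' where `z()` standardizes a covariate across features and
#' `w_f = (100 - ID_f)/20` scales covariate effects with divergence: probe
#' characteristics modulate hybridization of a *mismatched* duplex, so their
#' influence vanishes for an identical sequence and the planted mean at
#' 100 %ID is exactly `beta0`. With `beta_id > 0`, divergence (lower %ID)
#' depresses M, i.e. reduced heterologous hybridization, and the defaults
#' `beta_gc > 0`, `beta_id_gc < 0` reproduce the sign pattern seen in real
#' kinetics fits (a positive GC main effect with a negative %ID-by-GC
#' interaction). Each feature also
#' carries a kinetics deviation drawn once with SD `sd_kinetic(%ID)` (a
#' property of the sequence pair, constant across arrays), while technical
#' noise with SD `sd_technical(%ID)` is drawn per observation.
#'
#' @param seed Integer RNG seed; identical configs generate identical data.
#' @param n_features Number of array features.
#' @param n_arrays Number of replicate arrays; must be even so that dye
#'   orientations come in swapped pairs.
#' @param beta0,beta_id Intercept and slope (per %ID, log2 units) of the
#'   planted mean M on `%ID - 100`.
#' @param beta_gc,beta_length,beta_align Coefficients on standardized GC
#'   content, probe length and percent alignment length.
#' @param beta_id_gc Coefficient of the `z(GC) * (%ID - 100)` interaction.
#' @param sd_kinetic Function of %ID giving the per-feature kinetics SD
#'   (log2 units); must be non-negative and non-increasing in %ID.
#' @param sd_technical Function of %ID giving the per-observation technical
#'   SD (log2 units); must be non-negative.
#' @param dye_bias Additive channel offset (log2 units) favoring the red
#'   channel, cancelled by dye swaps.
#' @param intensity_trend_amplitude Amplitude (log2 units) of the smooth
#'   cubic intensity-dependent trend removed by loess normalization.
#' @param background_mean,background_sd Mean and SD of additive background
#'   fluorescence per channel.
#' @param frac_lowquality Proportion of feature-by-array observations forced
#'   below the "2 SD above background" quality filter.
#' @param conserved_n Size of the conserved anchor set (features flagged for
#'   loess normalization; all have true %ID >= 95).
#' @param nohit_floor_id %ID assigned to missing-ortholog features when
#'   simulating hybridization (their annotation still carries the `NoHit`
#'   sentinel).
#' @param n_shared_deep In multi-species simulations
#'   ([simulate_study()]), number of genes forced to deep divergence
#'   (72-78 %ID or no hit) in every species, providing planted truth for
#'   cross-species intersection analyses.
#' @param deep_extra_drop Additional log2-ratio reduction applied to the
#'   features of shared deep-divergence genes, emulating outright deletion
#'   or ortholog absence, where the heterologous signal falls to background
#'   rather than tracking the %ID calibration.
#'
#' @return An object of class `cgh_generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_features = 18000L,
                             n_arrays = 8L,
                             beta0 = 0,
                             beta_id = 0.08,
                             beta_gc = 0.10,
                             beta_length = 0,
                             beta_align = 0.05,
                             beta_id_gc = -0.01,
                             sd_kinetic = function(id) 0.02 + 0.02 * (100 - id),
                             sd_technical = function(id) 0.25 + 0.01 * (100 - id),
                             dye_bias = 0.1,
                             intensity_trend_amplitude = 0.3,
                             background_mean = 120,
                             background_sd = 25,
                             frac_lowquality = 0.15,
                             conserved_n = 1000L,
                             nohit_floor_id = 60,
                             n_shared_deep = 40L,
                             deep_extra_drop = 2) {
  seed <- assert_count(seed, "seed")
  n_features <- assert_count(n_features, "n_features", lower = 1)
  n_arrays <- assert_count(n_arrays, "n_arrays", lower = 2)
  if (n_arrays %% 2L != 0L) {
    abort("`n_arrays` must be even (dye-swap pairs).",
          class = "cghdiv_config_error")
  }
  for (nm in c("beta0", "beta_id", "beta_gc", "beta_length", "beta_align",
               "beta_id_gc", "dye_bias", "intensity_trend_amplitude")) {
    assert_number(get(nm), nm)
  }
  assert_number(background_mean, "background_mean", lower = 0)
  assert_number(background_sd, "background_sd", lower = 0)
  assert_number(frac_lowquality, "frac_lowquality", 0, 1 - 1e-12)
  conserved_n <- assert_count(conserved_n, "conserved_n", lower = 0)
  if (conserved_n > n_features) {
    abort("`conserved_n` must be <= `n_features`.",
          class = "cghdiv_config_error")
  }
  assert_number(nohit_floor_id, "nohit_floor_id", 0, 100)
  n_shared_deep <- assert_count(n_shared_deep, "n_shared_deep", lower = 0)
  assert_number(deep_extra_drop, "deep_extra_drop", lower = 0)
  for (fn_nm in c("sd_kinetic", "sd_technical")) {
    f <- get(fn_nm)
    if (!is.function(f)) {
      abort(sprintf("`%s` must be a function of %%ID.", fn_nm),
            class = "cghdiv_config_error")
    }
    probe <- f(c(60, 80, 95, 100))
    if (any(!is.finite(probe)) || any(probe < 0)) {
      abort(sprintf("`%s` must return finite non-negative SDs on [60, 100].",
                    fn_nm),
            class = "cghdiv_config_error")
    }
  }
  structure(
    list(seed = seed, n_features = n_features, n_arrays = n_arrays,
         beta0 = beta0, beta_id = beta_id, beta_gc = beta_gc,
         beta_length = beta_length, beta_align = beta_align,
         beta_id_gc = beta_id_gc, sd_kinetic = sd_kinetic,
         sd_technical = sd_technical, dye_bias = dye_bias,
         intensity_trend_amplitude = intensity_trend_amplitude,
         background_mean = background_mean, background_sd = background_sd,
         frac_lowquality = frac_lowquality, conserved_n = conserved_n,
         nohit_floor_id = nohit_floor_id, n_shared_deep = n_shared_deep,
         deep_extra_drop = deep_extra_drop),
    class = "cgh_generator_config"
  )
}

#' @export
print.cgh_generator_config <- function(x, ...) {
  cat(sprintf(
    "<cgh_generator_config> %d features x %d arrays (seed %d)\n",
    x$n_features, x$n_arrays, x$seed))
  cat(sprintf("  beta0 %.3g, beta_id %.3g, beta_gc %.3g, beta_len %.3g, beta_align %.3g, beta_id:gc %.3g\n",
              x$beta0, x$beta_id, x$beta_gc, x$beta_length, x$beta_align,
              x$beta_id_gc))
  invisible(x)
}

# Smooth cubic intensity trend; `amplitude` is roughly the value one
# A-halfspan from the center. Any smooth loess-removable shape would do.
intensity_trend <- function(A, amplitude, center = 11.5, halfspan = 3) {
  cc <- (A - center) / halfspan
  amplitude * (0.5 * cc + 0.5 * cc^3)
}

# Workhorse behind generate_feature_annotations() / simulate_study().
# `shared` carries a gene/GO/covariate universe reused across species;
# `deep_gene_ids` forces those genes' features to deep divergence.
generate_features_impl <- function(cfg, profile, shared = NULL,
                                   deep_gene_ids = NULL) {
  n <- cfg$n_features
  if (is.null(shared)) {
    shared <- with_seed_preserved(cfg$seed, make_shared_universe(n))
  }
  stopifnot(length(shared$gene_id) == n)

  with_seed_preserved(cfg$seed + 1000L, {
    no_hit <- runif(n) < profile$frac_missing_ortholog
    pct_id <- sample_pct_id(profile, n)
    pct_id[no_hit] <- NA_real_

    if (!is.null(deep_gene_ids) && length(deep_gene_ids)) {
      deep <- shared$gene_id %in% deep_gene_ids
      deep_nohit <- deep & (runif(n) < 0.3)
      no_hit <- no_hit | deep_nohit
      pct_id[deep] <- runif(sum(deep), 72, 78)
      pct_id[deep_nohit] <- NA_real_
    }

    # %ID used when simulating hybridization; NoHit features sit at the floor.
    pct_id_sim <- ifelse(no_hit, cfg$nohit_floor_id, pct_id)

    # Alignment coverage rises with %ID but insertions can push it past 100.
    pct_align <- pmax(5, 25 + 0.78 * pct_id + rnorm(n, 0, 6))
    pct_align[no_hit] <- NA_real_

    candidates <- which(!no_hit & pct_id >= 95)
    if (length(candidates) < cfg$conserved_n) {
      abort(sprintf(
        "only %d features with %%ID >= 95 available for a conserved set of %d",
        length(candidates), cfg$conserved_n),
        class = "cghdiv_config_error")
    }
    conserved <- rep(FALSE, n)
    conserved[sample(candidates, cfg$conserved_n)] <- TRUE

    z_gc <- zscore(shared$gc_percent)
    z_len <- zscore(shared$probe_length_bp)
    z_align <- zscore(pct_align)
    z_align[is.na(z_align)] <- 0
    div <- pct_id_sim - 100
    # covariates modulate hybridization of the *mismatched* part of the
    # duplex, so their effects scale with divergence and vanish at 100 %ID
    w <- -div / 20

    mu <- cfg$beta0 + cfg$beta_id * div +
      (cfg$beta_gc * z_gc + cfg$beta_length * z_len +
         cfg$beta_align * z_align) * w +
      cfg$beta_id_gc * z_gc * div
    if (!is.null(deep_gene_ids) && length(deep_gene_ids)) {
      # deletion-like loss of signal on top of the %ID calibration
      mu[deep] <- mu[deep] - cfg$deep_extra_drop
    }

    kinetic_dev <- rnorm(n, 0, cfg$sd_kinetic(pct_id_sim))

    truth <- tibble(
      feature_id = shared$feature_id,
      gene_id = shared$gene_id,
      true_pct_id = pct_id_sim,
      no_hit = no_hit,
      true_pct_align = pct_align,
      gc_percent = shared$gc_percent,
      probe_length_bp = shared$probe_length_bp,
      conserved = conserved,
      mu = mu,
      kinetic_dev = kinetic_dev,
      go_terms = shared$go_terms
    )
    annotations <- tibble(
      feature_id = shared$feature_id,
      gene_id = shared$gene_id,
      probe_length_bp = shared$probe_length_bp,
      gc_percent = shared$gc_percent,
      conserved = conserved,
      true_pct_id = pct_id,
      no_hit = no_hit,
      pct_align = pct_align,
      go_terms = shared$go_terms
    )
    list(annotations = annotations, truth = truth, shared = shared)
  })
}

# Gene ids, probe covariates and a toy GO universe shared by every species
# in a study. ~85% of features map to distinct genes (the rest are repeat
# features of the same gene); ~half of all genes carry GO annotations.
make_shared_universe <- function(n) {
  feature_id <- sprintf("F%06d", seq_len(n))
  n_genes <- max(1L, round(0.85 * n))
  gene_idx <- c(seq_len(n_genes),
                if (n > n_genes) sample.int(n_genes, n - n_genes, replace = TRUE))
  gene_id <- sprintf("G%06d", gene_idx)

  probe_length_bp <- pmin(900, pmax(150, round(rnorm(n, 500, 80))))
  gc_percent <- pmin(80, pmax(20, rnorm(n, 50, 8)))

  ont <- make_toy_ontology()
  genes <- sprintf("G%06d", seq_len(n_genes))
  annotated <- runif(n_genes) < 0.5
  gene_terms <- vector("list", n_genes)
  leaf_terms <- ont$leaves
  for (i in which(annotated)) {
    gene_terms[[i]] <- sample(leaf_terms, sample.int(3L, 1L))
  }
  names(gene_terms) <- genes
  go_terms <- map_chr(gene_idx, function(i) {
    trm <- gene_terms[[i]]
    if (is.null(trm)) "" else paste(sort(trm), collapse = ";")
  })

  list(feature_id = feature_id, gene_id = gene_id,
       probe_length_bp = probe_length_bp, gc_percent = gc_percent,
       go_terms = go_terms, gene_terms = gene_terms, ontology = ont,
       n_genes = n_genes)
}

# A small rooted DAG: 48 leaves -> 8 mid-level terms -> 1 root, with some
# leaves under two parents so that propagation sees diamonds.
make_toy_ontology <- function() {
  root <- "GO:R000"
  mids <- sprintf("GO:M%03d", 1:8)
  leaves <- sprintf("GO:L%03d", 1:48)
  edges <- tibble(child = mids, parent = root)
  primary <- rep(mids, length.out = length(leaves))
  edges <- bind_rows(edges, tibble(child = leaves, parent = primary))
  extra <- leaves[seq(1, length(leaves), by = 4)]
  second <- mids[(match(extra, leaves) %% 8L) + 1L]
  edges <- bind_rows(edges, tibble(child = extra, parent = second)) |>
    distinct() |>
    filter(.data$child != .data$parent)
  list(edges = edges, root = root, mids = mids, leaves = leaves)
}

#' Generate per-feature annotations and planted truth
#'
#' Draws the static properties of a synthetic array: per-feature %ID from
#' the species profile's truncated-normal mixture, probe lengths around
#' 500 bp, GC content, percent alignment length (positively associated with
#' %ID and allowed above 100), a conserved anchor set of exactly
#' `cfg$conserved_n` features (all with %ID >= 95), missing-ortholog
#' features carrying a `NoHit` sentinel, gene ids and toy GO annotations.
#' The returned truth table additionally records each feature's planted mean
#' log2 ratio and its hybridization-kinetics deviation.
#'
#' @param cfg A [generator_config()].
#' @param profile A [species_profile()].
#' @return A list with tibbles `annotations` and `truth`, aligned by
#'   `feature_id`.
#' @export
#' @examples
#' cfg <- generator_config(n_features = 500, conserved_n = 30, seed = 1)
#' ann <- generate_feature_annotations(cfg, profile_closely_diverged())
#' dplyr::count(ann$annotations, conserved)
generate_feature_annotations <- function(cfg, profile) {
  stopifnot(inherits(cfg, "cgh_generator_config"),
            inherits(profile, "cgh_species_profile"))
  out <- generate_features_impl(cfg, profile)
  out["shared"] <- NULL
  out
}

#' Simulate two-color array scans from planted truth
#'
#' For each array and feature, forms a latent log2 ratio
#' `M = mu + kinetic_dev + technical noise`, applies the dye orientation
#' sign (half the arrays are dye-swapped), adds the dye bias and a smooth
#' intensity-dependent trend, and reconstructs two-channel foreground
#' intensities from M and a simulated average log2 intensity, on top of
#' additive backgrounds. A fraction `frac_lowquality` of observations has
#' its foreground forced below the background + 2 SD quality threshold in
#' both channels.
#'
#' @param annotations,truth Aligned tibbles from
#'   [generate_feature_annotations()].
#' @param cfg The same [generator_config()].
#' @return A named list of `cgh_scan` tibbles (columns `feature_id`, `F635`,
#'   `B635`, `F532`, `B532`, `flag`; attributes `array_id`, `dye_swapped`).
#' @export
simulate_scans <- function(annotations, truth, cfg) {
  stopifnot(inherits(cfg, "cgh_generator_config"))
  require_columns(truth, c("feature_id", "true_pct_id", "mu", "kinetic_dev"),
                  "truth")
  if (!identical(annotations$feature_id, truth$feature_id)) {
    abort("`annotations` and `truth` must be aligned by feature_id.",
          class = "cghdiv_config_error")
  }
  n <- nrow(truth)
  latent <- truth$mu + truth$kinetic_dev
  sd_tech <- cfg$sd_technical(truth$true_pct_id)

  with_seed_preserved(cfg$seed + 2000L, {
    A_f <- rnorm(n, 11.5, 1.2)
    scans <- vector("list", cfg$n_arrays)
    for (a in seq_len(cfg$n_arrays)) {
      swapped <- a %% 2L == 0L
      orient <- if (swapped) -1 else 1
      A_obs <- A_f + rnorm(n, 0, 0.2)
      eps <- rnorm(n, 0, sd_tech)
      M_raw <- orient * latent + cfg$dye_bias +
        intensity_trend(A_obs, cfg$intensity_trend_amplitude) + eps
      sig635 <- 2^(A_obs + M_raw / 2)
      sig532 <- 2^(A_obs - M_raw / 2)
      B635 <- pmax(1, rnorm(n, cfg$background_mean, cfg$background_sd))
      B532 <- pmax(1, rnorm(n, cfg$background_mean, cfg$background_sd))
      F635 <- sig635 + B635
      F532 <- sig532 + B532
      n_low <- round(cfg$frac_lowquality * n)
      if (n_low > 0) {
        low <- sample.int(n, n_low)
        F635[low] <- B635[low] + runif(n_low, 0.1, 0.8) * cfg$background_sd
        F532[low] <- B532[low] + runif(n_low, 0.1, 0.8) * cfg$background_sd
      }
      scan <- tibble(feature_id = truth$feature_id,
                     F635 = F635, B635 = B635,
                     F532 = F532, B532 = B532,
                     flag = 0L)
      attr(scan, "array_id") <- sprintf("array_%02d", a)
      attr(scan, "dye_swapped") <- swapped
      class(scan) <- c("cgh_scan", class(scan))
      scans[[a]] <- scan
    }
    names(scans) <- map_chr(scans, attr, "array_id")
    scans
  })
}

#' Simulate a complete multi-species aCGH study
#'
#' Generates one dataset per species profile over a shared universe of
#' features, genes, probe covariates and GO annotations, so that
#' cross-species analyses (four-fold-reduction intersections, GO tests) have
#' common gene ids. `cfg$n_shared_deep` genes are forced to deep divergence
#' (72-78 %ID, 30% of their features `NoHit`) in every species, providing
#' planted truth for intersection recovery. Per-species array counts can be
#' set via `n_arrays_by_species`.
#'
#' @param cfg A [generator_config()]; `cfg$seed` drives the whole study.
#' @param profiles List of [species_profile()] objects (names taken from the
#'   profiles).
#' @param n_arrays_by_species Optional integer vector (recycled) of arrays
#'   per species; defaults to `cfg$n_arrays` for each.
#' @return A list with `species` (named list of `annotations`, `truth`,
#'   `scans`, `cfg` per species), `go` (tibbles `annotations` gene-term and
#'   `edges` child-parent), and `deep_gene_ids`.
#' @export
simulate_study <- function(cfg, profiles, n_arrays_by_species = NULL) {
  stopifnot(inherits(cfg, "cgh_generator_config"), length(profiles) >= 1)
  nm <- map_chr(profiles, function(p) p$name)
  names(profiles) <- nm
  n_arr <- rep(n_arrays_by_species %||% cfg$n_arrays, length.out = length(profiles))

  shared <- with_seed_preserved(cfg$seed, make_shared_universe(cfg$n_features))
  annotated_genes <- names(shared$gene_terms)[
    !map_lgl(shared$gene_terms, is.null)]
  deep_gene_ids <- with_seed_preserved(cfg$seed + 7L, {
    k <- min(cfg$n_shared_deep, length(annotated_genes))
    # deep-divergence genes are drawn from the GO-annotated genes and leaned
    # toward two leaf terms so category over-representation has planted truth
    picked <- sample(annotated_genes, k)
    for (g in picked) {
      extra <- sample(shared$ontology$leaves[1:2], 1)
      shared$gene_terms[[g]] <- union(shared$gene_terms[[g]], extra)
    }
    picked
  })
  # refresh per-feature go strings after the deep-term enrichment
  gene_idx <- match(shared$gene_id, sprintf("G%06d", seq_len(shared$n_genes)))
  shared$go_terms <- map_chr(gene_idx, function(i) {
    trm <- shared$gene_terms[[i]]
    if (is.null(trm)) "" else paste(sort(trm), collapse = ";")
  })

  species <- vector("list", length(profiles))
  names(species) <- nm
  for (i in seq_along(profiles)) {
    sp_cfg <- cfg
    sp_cfg$seed <- cfg$seed + 10000L * i
    sp_cfg$n_arrays <- as.integer(n_arr[i])
    out <- generate_features_impl(sp_cfg, profiles[[i]], shared = shared,
                                  deep_gene_ids = deep_gene_ids)
    scans <- simulate_scans(out$annotations, out$truth, sp_cfg)
    species[[i]] <- list(annotations = out$annotations, truth = out$truth,
                         scans = scans, cfg = sp_cfg)
  }

  go_ann <- imap(shared$gene_terms, function(trm, g) {
    if (is.null(trm)) NULL else tibble(gene_id = g, term_id = trm)
  }) |> list_rbind()

  list(species = species,
       go = list(annotations = go_ann, edges = shared$ontology$edges),
       deep_gene_ids = deep_gene_ids)
}
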