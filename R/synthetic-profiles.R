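#' Species divergence profile
#'
#' Describes the distribution of per-feature percent identity (%ID) between a
#' heterologous species and the platform species, as a mixture of truncated
#' normal components on \[60, 100\] %ID, plus the proportion of array
#' features with no detectable ortholog in the heterologous genome.
#'
#' @param name Species label.
#' @param id_mixture Data frame with columns `weight`, `mean`, `sd`: mixture
#'   weights (summing to 1), component means (in \[60, 100\] %ID) and
#'   component standard deviations (> 0) of the truncated-normal %ID mixture.
#' @param frac_missing_ortholog Proportion in \[0, 1\] of features whose
#'   heterologous ortholog is absent (no BLAST hit); these are simulated at
#'   the divergence floor and carry a `NoHit` sentinel in annotation output.
#'
#' @return An object of class `cgh_species_profile`.
#' @seealso [profile_closely_diverged()], [profile_distantly_diverged()]
#' @export
#' @examples
#' species_profile("toy", data.frame(weight = 1, mean = 95, sd = 2))
species_profile <- function(name, id_mixture, frac_missing_ortholog = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string.", class = "cghdiv_config_error")
  }
  id_mixture <- as_tibble(id_mixture)
  require_columns(id_mixture, c("weight", "mean", "sd"), "id_mixture")
  if (nrow(id_mixture) < 1L) {
    abort("`id_mixture` needs at least one component.",
          class = "cghdiv_config_error")
  }
  if (abs(sum(id_mixture$weight) - 1) > 1e-9) {
    abort("mixture weights must sum to 1 (within 1e-9).",
          class = "cghdiv_config_error")
  }
  if (any(id_mixture$weight < 0)) {
    abort("mixture weights must be non-negative.",
          class = "cghdiv_config_error")
  }
  if (any(id_mixture$mean < 60 | id_mixture$mean > 100)) {
    abort("mixture means must lie in [60, 100] %ID.",
          class = "cghdiv_config_error")
  }
  if (any(id_mixture$sd <= 0)) {
    abort("mixture sds must be > 0.", class = "cghdiv_config_error")
  }
  assert_number(frac_missing_ortholog, "frac_missing_ortholog", 0, 1)
  structure(
    list(name = name, id_mixture = id_mixture,
         frac_missing_ortholog = frac_missing_ortholog),
    class = "cgh_species_profile"
  )
}

#' @export
print.cgh_species_profile <- function(x, ...) {
  cat(sprintf("<cgh_species_profile> %s\n", x$name))
  cat(sprintf("  %%ID mixture (%d components), frac no-hit = %.3f\n",
              nrow(x$id_mixture), x$frac_missing_ortholog))
  print(x$id_mixture)
  invisible(x)
}

#' Default %ID profiles for closely and distantly diverged species
#'
#' `profile_closely_diverged()` emulates a species pair a few million years
#' diverged: the %ID distribution has its mode above 95 %ID with a thin tail
#' of diverged orthologs. `profile_distantly_diverged()` emulates a pair an
#' order of magnitude more diverged: a substantial mass of orthologs below
#' 90 %ID with a long tail reaching ~73 %ID, and a larger fraction of
#' missing orthologs.
#'
#' @param name Species label.
#' @return A [species_profile()].
#' @export
profile_closely_diverged <- function(name = "close") {
  species_profile(
    name,
    tibble(weight = c(0.55, 0.35, 0.10),
           mean   = c(97.5, 95.0, 88.0),
           sd     = c(1.2, 2.0, 4.0)),
    frac_missing_ortholog = 0.03
  )
}

#' @rdname profile_closely_diverged
#' @export
profile_distantly_diverged <- function(name = "distant") {
  species_profile(
    name,
    tibble(weight = c(0.35, 0.40, 0.25),
           mean   = c(96.0, 91.0, 82.0),
           sd     = c(1.5, 3.0, 5.0)),
    frac_missing_ortholog = 0.08
  )
}

# Draw n %ID values from a profile's truncated-normal mixture.
sample_pct_id <- function(profile, n) {
  comp <- sample.int(nrow(profile$id_mixture), n, replace = TRUE,
                     prob = profile$id_mixture$weight)
  rtruncnorm(n,
             mean = profile$id_mixture$mean[comp],
             sd = profile$id_mixture$sd[comp],
             lo = 60, hi = 100)
}
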