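# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# Mid-size default-coefficient dataset used across detection/calibration
# tests: distantly diverged profile, 8 arrays.
shared_dataset <- function() {
  fixture("shared", function() {
    cfg <- generator_config(n_features = 4000, n_arrays = 8,
                            conserved_n = 300, seed = 20260901)
    gen <- generate_feature_annotations(cfg, profile_distantly_diverged())
    scans <- simulate_scans(gen$annotations, gen$truth, cfg)
    ratios <- normalize_loess_conserved(scans, gen$annotations)
    mod <- shrink_variances(fit_feature_stats(ratios))
    calls <- call_diverged(mod)
    feat <- dplyr::left_join(
      calls,
      dplyr::select(gen$annotations, feature_id, gene_id,
                    pct_id = true_pct_id, no_hit, gc_percent,
                    probe_length_bp, pct_align, conserved),
      by = "feature_id")
    list(cfg = cfg, gen = gen, scans = scans, ratios = ratios, mod = mod,
         calls = calls, feat = feat,
         analyzed = dplyr::filter(feat, n_used >= 2))
  })
}

# Noise-free dataset: no technical or kinetic noise, no dye bias, no
# intensity trend, nothing filtered; planted means are exactly recoverable.
noise_free_dataset <- function() {
  fixture("noise_free", function() {
    cfg <- generator_config(
      n_features = 600, n_arrays = 4, conserved_n = 60, seed = 7,
      sd_kinetic = function(id) rep(0, length(id)),
      sd_technical = function(id) rep(0, length(id)),
      dye_bias = 0, intensity_trend_amplitude = 0, frac_lowquality = 0)
    gen <- generate_feature_annotations(cfg, profile_closely_diverged())
    scans <- simulate_scans(gen$annotations, gen$truth, cfg)
    list(cfg = cfg, gen = gen, scans = scans)
  })
}

# Raw oriented M values recovered from scans without normalization
# (background-correct, log-ratio, orientation sign only).
raw_oriented_M <- function(scans) {
  purrr::map(scans, function(scan) {
    scan <- background_correct_minimum(scan)
    M <- log2(scan$C635 / scan$C532)
    if (isTRUE(attr(scan, "dye_swapped"))) -M else M
  })
}

# O(n^2) Benjamini-Hochberg oracle straight from the definition:
# q_i = min over observed thresholds t >= p_i of m * t / #{p <= t}, capped.
bh_oracle <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(vapply(cand, function(t) m * t / sum(p <= t), numeric(1))))
  }, numeric(1))
}

# Amplitude of the smooth trend component of residuals r over A: half the
# range of a lowess fit across the central 98% of the intensity axis
# (pointwise extremes would measure extrapolation tails, not the trend).
trend_amplitude <- function(A, r, f = 0.3) {
  sm <- stats::lowess(A, r, f = f)
  keep <- sm$x >= quantile(A, 0.01) & sm$x <= quantile(A, 0.99)
  (max(sm$y[keep]) - min(sm$y[keep])) / 2
}

# Exact hypergeometric tails by combinatorial enumeration over the count
# distribution (choose() sums, independent of phyper).
hyper_tails_oracle <- function(k, m, N, n) {
  xs <- max(0, n - (N - m)):min(n, m)
  probs <- choose(m, xs) * choose(N - m, n - xs) / choose(N, n)
  list(p_over = sum(probs[xs >= k]), p_under = sum(probs[xs <= k]))
}
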