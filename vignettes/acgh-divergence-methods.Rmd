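---
title: "Measuring sequence divergence with two-color array CGH: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sequence divergence with two-color array CGH: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cghdiv)
```

# The measurement model

Competitive genomic hybridization of a heterologous species against the
platform species yields, per array feature, a log2 ratio
`M = log2(het/plat)`. Three processes shape M:

1. **Divergence signal.** Mean M falls approximately linearly with the
   percent identity (%ID) of the heterologous ortholog to the probe over
   the range typical of congeneric comparisons (roughly 75–100 %ID;
   log-linearity is known to break down below ~75 %ID, which this package
   does not model).
2. **Hybridization kinetics.** For a *given* %ID, physical properties of
   the probe–sample duplex (GC content, alignment coverage, probe length)
   shift hybridization strength. This deviation is a property of the
   sequence pair: it is the same on every replicate array.
3. **Technical noise.** Independent per observation (feature × array).

The inference pipeline treats each feature's replicate M values as
exchangeable draws around `mu_f + kinetic_f`, estimates `mean_M` and `s2`
per feature, and tests `mean_M != 0` with an empirical Bayes moderated
t-statistic. Divergence calls are *directional*: the two-sided p-value is
computed first (features are tested for ratios different from equal) and a
feature is then reported as diverged only when its mean ratio is negative,
i.e. hybridization is reduced in the heterologous species. A one-sided test
was considered and rejected: the two-step convention keeps the reported
p-values comparable with the usual two-color workflow, and both the
directional and non-directional counts are emitted because summary tables
can reasonably be built either way.

## Variance shrinkage

With few replicate arrays (2–8), per-feature variances are unstable. We
assume the standard hierarchical model: `s2 | sigma2 ~ sigma2 * chisq_d/d`
with an inverse-chi-square prior on `sigma2` (prior df `d0`, prior scale
`s0^2`), so that marginally `s2 ~ s0^2 F(d, d0)`. Hyperparameters are
estimated by matching the mean and variance of
`e = log s2 - digamma(d/2) + log(d/2)`; the variance match requires
inverting the trigamma function, done by Newton iteration (tolerance 1e-8,
at most 100 iterations, monotone safeguard halving the step when it
undershoots zero). Two degenerate regimes are handled explicitly:

- `var(e)` *exactly* zero (all s2 identical, outside the sampling model):
  the pooled variance is that constant.
- `var(e)` positive but no larger than the chi-square sampling noise
  `mean(trigamma(d/2))`: `d0 = Inf` and the pooled variance uses the
  chi-square log-moment correction `exp(mean(e))`. Using the plain
  geometric mean here would be biased low by `exp(digamma(d/2) - log(d/2))`
  and would visibly break the uniformity of null p-values.

If estimation fails entirely the function falls back to unshrunk variances
with a warning. The implementation is validated in the test suite against
an independent route (the limma empirical Bayes fit) on simulated data; the
two agree on hyperparameters and posterior variances.

## Multiple testing

Benjamini–Hochberg step-up q-values are computed by the package itself
(sorted `m*p/i`, reverse cumulative minimum, capped at 1, ties sharing a
value); the test suite checks it against an O(n²) transcription of the
definition on a thousand random vectors and against `p.adjust`.

# Preprocessing

**Quality filter.** An observation is usable iff in *both* channels the
foreground is at least background + 2 SD of that channel's background,
with the SD taken across the array's features, and the flag is
non-negative (negative flags mark bad spots, following scanner
conventions). The boundary is inclusive. Whether one or both channels must
fail was an open choice; requiring both channels to pass is the
conservative reading and is what the filter implements. The reference
population for "2 SD" (per array, per channel, across features) is likewise
a choice the scan format does not dictate.

**Background correction ("minimum").** Corrected = foreground −
background; non-positive results are replaced by half the smallest positive
corrected value on that array and channel, keeping all intensities strictly
positive for the log ratio.

**Conserved-set loess.** The normalization curve M ~ A is fitted only on
usable conserved features (≥ 95 %ID anchors): cross-species arrays contain
many genuinely diverged features, and a curve fitted on all features would
absorb real signal. Numerical choices: span 0.4, **degree 2**, symmetric
(bisquare) family with three robustness iterations, exact ("direct")
surface so that predictions extrapolate linearly beyond the anchor range.
Degree 2 is a deliberate departure from the more common local-linear
default: measured on noise-free planted cubic intensity trends of amplitude
0.5, local lines over a 0.4 span leave a residual trend of up to 0.07 log2
units, while local quadratics leave at most ~0.01. After subtracting the
curve, the anchor set is median-centered to exactly zero — conserved
orthologs hybridize equally by definition, and the symmetric-family loess
targets a robust mean rather than a median, which otherwise leaves the
anchor median drifting by up to ~0.015 at realistic noise. Dye-swapped
arrays are negated last, so every column is oriented as
log2(heterologous/platform).

**Survival rule.** Features must be usable on at least 2 arrays ("multiple
arrays") to be analyzed; the threshold is configurable.

# Calibration

**Detection curves** use a moving window of 51 features ordered by %ID; the
window statistic is plotted against the window's *mean* %ID (the center
definition is not dictated by anything; the mean is smooth under ties), with
a lowess summary (span 0.3) per threshold.

**ID-50.** The detection limit is estimated by a binomial-logit GLM of the
per-feature diverged indicator on %ID (IRLS, tolerance 1e-10), with
`id50 = -intercept/slope`. A windowed-proportion variant is available
(`method = "windowed"`); the per-feature binary fit is the default because
it weights the data correctly without choosing a window. Fitted
probabilities saturating to 0/1 at the extremes of the %ID range are
expected for steep curves and are not treated as separation; true complete
separation (a %ID value perfectly splitting the outcomes) is detected
directly and reported as a boundary estimate with a warning. An ID-50
outside [60, 100] is reported as out of range with the side.

**Kinetics model.** `mean_M ~ %ID * (GC + length + %align)` by OLS, with an
optional full standardization (all variables z-scored) for comparable
effect sizes; `standardized_effects()` evaluates each covariate's effect as
a function of %ID from the main effect plus interaction. Rank deficiency
aborts with the collinear terms named.

**Variance partition.** In sliding windows of 301 features (wider than the
detection window because a median-based scale needs more points for
stability), *technical* = mean per-feature SE of the fitted mean, computed
from the moderated variance `sqrt(s2_post/n)` — matching what a moderated
fit reports for each feature — and *kinetic* = `median(|residual|)/0.6745`
of the residuals from the calibration line, the robust normal-consistent
scale (0.6745 is the 0.75 standard-normal quantile). The crossover is the
highest-%ID sign change of their difference, located by linear
interpolation; its natural resolution is the local window width, which is
how the parameter-recovery test judges it.

**Replication analysis.** Every k-combination of arrays is re-analyzed end
to end (statistics → shrinkage → calls → ID-50 → regression), exhaustively
up to 70 combinations per k (the 4-of-8 count, so an 8-array design is
always exhaustive) and by a seeded random sample beyond that. Per-feature
SEs are summarized within 5-%ID bins.

# The synthetic study

The generator plants, per feature: %ID from a truncated-normal mixture on
[60, 100] (profiles for a closely diverged contrast with its mode above
95 %ID, and a distantly diverged one with a tail reaching ~73 %ID); probe
length ~500 bp; GC in [20, 80]; percent alignment positively associated
with %ID and allowed above 100 (insertions inflate alignments); a conserved
anchor set of exactly `conserved_n` features at ≥ 95 %ID; and a fraction of
features with no ortholog, simulated at a floor of 60 %ID but carrying a
`NoHit` sentinel.

The planted mean is
`mu = beta0 + beta_id*(ID-100) + [beta_gc*z(GC) + beta_len*z(len) + beta_align*z(align)]*(100-ID)/20 + beta_id_gc*z(GC)*(ID-100)`.
Covariate effects scale with divergence because probe characteristics act
on the *mismatched* part of the duplex; a consequence worth stating is that
the mean at 100 %ID is exactly `beta0`, and the fitted kinetics model
recovers a positive GC main effect with a negative %ID:GC interaction —
the sign structure expected of GC stabilization of diverged duplexes.
Kinetic deviations are drawn once per feature with SD `sd_kinetic(%ID)`
(default `0.02 + 0.02*(100-ID)`), technical noise per observation with SD
`sd_technical(%ID)` (default `0.25 + 0.01*(100-ID)`); both grow with
divergence, kinetics faster, so the variance partition has a crossover near
the conserved end. Scans are reconstructed as two channels around a
per-feature average log intensity (normal, mean 11.5, SD 1.2 — the
intensity distribution is a free choice nothing in the problem pins down),
with additive dye bias (0.1), a smooth cubic intensity trend (amplitude
0.3 by default), additive normal backgrounds (mean 120, SD 25), half the
arrays dye-swapped, and 15% of observations forced below the quality
threshold (the default run then analyzes ~72% of features on a 2-array
design, matching the ~80% usable rate typical of real scans).

Multi-species studies share one universe of genes (~0.85 genes per
feature, so some genes have several features), toy GO annotations (~half
the genes annotated, a 57-term DAG with diamonds), and `n_shared_deep`
genes (default 40) forced to deep divergence in every species. Deep genes
additionally receive a deletion-strength ratio drop (`deep_extra_drop = 2`
log2 units): genes four-fold reduced in *all* species of a real study are
mostly deletions or absent orthologs whose signal falls toward background
rather than tracking the %ID calibration, and without this term planted
deep genes would sit exactly at the four-fold boundary where recovery is a
coin flip.

**What the generator does not emulate** — and hence what passing tests do
not demonstrate about real data: spatial/print-tip artifacts, paralog
cross-hybridization, probe-sequence errors, correlated backgrounds,
saturation, non-normal noise, and the breakdown of log-linearity below
~75 %ID. The planted truth validates the *statistical machinery*, not the
biophysics.

# Test and validation scale

The parameter-recovery checks run at 10,000 features × 8 arrays (slope
recovered within 3 SE on a covariate-free configuration — percent
alignment is constructed to correlate with %ID, so a nonzero alignment
coefficient changes the true marginal slope and would make "the planted
slope" ill-defined; logistic midpoint within ±0.5 %ID; variance crossover
within one window width of a population oracle computed from the planted
truth; %ID:GC sign at p < 0.01). The replication-trend check runs the
full-size default (18,000 features, 8 arrays, 127 subset analyses). Null
calibration uses twenty 2,000-feature studies with no planted signal
(Kolmogorov–Smirnov uniformity of p-values and a bounded call rate). Unit
tests use smaller fixtures (400–4,000 features) chosen to keep the whole
suite around a minute without losing statistical resolution.

# Known limitations

- The %ID calibration assumes one well-defined ortholog per feature; the
  top-BLAST-hit convention (smallest e-value, ties by bit score then file
  order, single HSP, no HSP merging) inherits that assumption.
- The GO universe is restricted to analyzed genes with at least one
  annotation, tests are unconditional hypergeometric with inclusive tails
  (`P[X >= k]`, `P[X <= k]`), and p-values are reported uncorrected at
  0.01 by default (a BH option exists); parent and child terms are
  correlated by construction, so counts of significant terms should be
  read qualitatively.
- ID-50 and % diverged are properties of a *design* (replication, noise),
  not of the species pair alone; the replication analysis quantifies
  exactly this.
- With 2-array designs and realistic low-quality rates, single-feature
  genes drop below the multi-array survival rule often enough that
  cross-species intersections are structurally under-counted; intersection
  analyses are best run on designs with ≥ 4 arrays per species.
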