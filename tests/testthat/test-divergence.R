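ratios_from_matrix <- function(M) {
  tibble::tibble(
    feature_id = rep(sprintf("F%03d", seq_len(nrow(M))), ncol(M)),
    array_id = rep(sprintf("a%02d", seq_len(ncol(M))), each = nrow(M)),
    M = as.vector(M),
    usable = !is.na(as.vector(M))
  )
}

test_that("per-feature statistics match hand arithmetic", {
  r <- ratios_from_matrix(rbind(c(-1, -1, -1, -1), c(0, 2, NA, NA)))
  st <- fit_feature_stats(r)
  expect_equal(st$n_used, c(4L, 2L))
  expect_equal(st$mean_M, c(-1, 1))
  expect_equal(st$s2, c(0, 2))

  single <- fit_feature_stats(ratios_from_matrix(cbind(c(1, 2))))
  expect_true(all(is.na(single$mean_M)))  # n_used < 2 reported as NA
  expect_error(fit_feature_stats(tibble::tibble(feature_id = character(),
                                                M = numeric())),
               "empty")
})

test_that("noise-free generator data reproduce planted means exactly", {
  ds <- noise_free_dataset()
  M <- do.call(cbind, raw_oriented_M(ds$scans))
  st <- fit_feature_stats(ratios_from_matrix(M))
  expect_equal(st$mean_M, ds$gen$truth$mu, tolerance = 1e-9)
  expect_true(all(st$s2 < 1e-18))
})

test_that("identical sample variances shrink to themselves", {
  st <- tibble::tibble(feature_id = sprintf("F%03d", 1:200),
                       n_used = 5L, mean_M = rnorm(200), s2 = 0.3)
  mod <- shrink_variances(st)
  expect_equal(attr(mod, "s0_2"), 0.3, tolerance = 1e-9)
  expect_true(is.infinite(attr(mod, "d0")))
  expect_equal(mod$s2_post, rep(0.3, 200))
})

test_that("forcing d0 = Inf pools every variance to the prior", {
  st <- tibble::tibble(feature_id = sprintf("F%03d", 1:50),
                       n_used = 4L, mean_M = 0, s2 = runif(50, 0.1, 1))
  mod <- shrink_variances(st, d0 = Inf, s0_2 = 0.25)
  expect_true(all(mod$s2_post == 0.25))
})

test_that("s2_post always lies between s2 and the prior variance", {
  set.seed(4)
  st <- tibble::tibble(feature_id = sprintf("F%04d", 1:500), n_used = 6L,
                       mean_M = rnorm(500),
                       s2 = 0.1 * rchisq(500, 5) / 5)
  mod <- shrink_variances(st)
  s0 <- attr(mod, "s0_2")
  expect_true(all(mod$s2_post >= pmin(mod$s2, s0) - 1e-12))
  expect_true(all(mod$s2_post <= pmax(mod$s2, s0) + 1e-12))
})

test_that("the variance prior is recovered from scaled-F draws", {
  # s2 ~ s0_2 * (chisq_d/d) / (chisq_d0/d0), planted d0 = 4, s0_2 = 0.04
  set.seed(2024)
  n <- 10000; d <- 7; d0 <- 4; s0_2 <- 0.04
  s2 <- s0_2 * (rchisq(n, d) / d) / (rchisq(n, d0) / d0)
  st <- tibble::tibble(feature_id = sprintf("F%05d", 1:n),
                       n_used = d + 1L, mean_M = 0, s2 = s2)
  mod <- shrink_variances(st)
  expect_lt(abs(attr(mod, "d0") - d0) / d0, 0.25)
  expect_lt(abs(attr(mod, "s0_2") - s0_2) / s0_2, 0.10)
})

test_that("moderated statistics agree with the limma empirical Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(7)
  n <- 400; k <- 6
  sigma <- sqrt(0.05 * rchisq(n, 5) / 5)
  M <- matrix(rnorm(n * k, 0, rep(sigma, k)), n, k)
  M[sample(n, 40), 1] <- NA  # unbalanced usage

  st <- fit_feature_stats(ratios_from_matrix(M))
  mod <- shrink_variances(st)

  lf <- limma::lmFit(M, cbind(rep(1, k)))
  eb <- limma::eBayes(lf)
  expect_lt(abs(attr(mod, "d0") - eb$df.prior) / eb$df.prior, 0.05)
  expect_lt(abs(attr(mod, "s0_2") - eb$s2.prior) / eb$s2.prior, 0.02)
  expect_equal(mod$s2_post, unname(eb$s2.post), tolerance = 1e-3)
  expect_gt(cor(mod$t_mod, eb$t[, 1]), 0.9999)
})

test_that("BH adjustment matches hand computation, the m = 1 identity and p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_error(bh_fdr(c(0.2, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (i in 1:50) {
    p <- round(runif(sample(2:12, 1)), 3)  # rounding forces ties
    expect_equal(bh_fdr(p), bh_oracle(p))
    expect_equal(bh_fdr(p), p.adjust(p, method = "BH"))
  }
  # NA propagation keeps order
  p <- c(0.04, NA, 0.01)
  q <- bh_fdr(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_fdr(c(0.04, 0.01)))
})

test_that("divergence calls are directional and nested across thresholds", {
  st <- tibble::tibble(
    feature_id = c("up", "down_strong", "down_weak", "flat"),
    n_used = 4L,
    mean_M = c(0.4, -1, -0.3, -0.01),
    s2 = 0.04, s2_post = 0.04, t_mod = 0,
    p = c(0.001, 0.0001, 0.04, 0.9))
  st$q <- bh_fdr(st$p)
  class(st) <- c("cgh_moderated", class(st))
  calls <- call_diverged(st)
  # significant but positive mean never counts as diverged
  expect_false(any(calls$diverged_q10[calls$mean_M > 0]))
  expect_true(calls$significant_q05[calls$feature_id == "up"])
  expect_true(all(calls$diverged_q01 <= calls$diverged_q05) &&
                all(calls$diverged_q05 <= calls$diverged_q10))
  expect_true(all(unlist(calls[calls$feature_id == "down_strong",
                               c("diverged_q10", "diverged_q05",
                                 "diverged_q01")])))

  ds <- shared_dataset()
  cc <- ds$calls
  expect_true(all(cc$diverged_q01 <= cc$diverged_q05))
  expect_true(all(cc$diverged_q05 <= cc$diverged_q10))
  expect_true(all(cc$mean_M[cc$diverged_q10] < 0))
})

test_that("calls are invariant to feature and array ordering", {
  ds <- shared_dataset()
  shuffled <- ds$ratios[sample(nrow(ds$ratios)), ]
  mod2 <- shrink_variances(fit_feature_stats(shuffled))
  calls2 <- call_diverged(mod2) |> dplyr::arrange(.data$feature_id)
  calls1 <- dplyr::arrange(ds$calls, .data$feature_id)
  expect_equal(calls1$q, calls2$q)
  expect_identical(calls1$diverged_q10, calls2$diverged_q10)
})

test_that("strongly diverged features are nearly always detected", {
  ds <- shared_dataset()
  strong <- dplyr::filter(ds$feat, !no_hit, pct_id < 85, n_used >= 2)
  expect_gt(nrow(strong), 100)
  expect_gte(mean(strong$diverged_q10), 0.95)
})

test_that("p-values are calibrated under the global null", {
  cfg <- generator_config(
    n_features = 2000, n_arrays = 4, conserved_n = 150, seed = 77,
    beta_id = 0, beta_gc = 0, beta_align = 0, beta_length = 0, beta_id_gc = 0,
    sd_kinetic = function(id) rep(0, length(id)),
    sd_technical = function(id) rep(0.25, length(id)))
  gen <- generate_feature_annotations(cfg, profile_closely_diverged())
  scans <- simulate_scans(gen$annotations, gen$truth, cfg)
  ratios <- normalize_loess_conserved(scans, gen$annotations)
  mod <- shrink_variances(fit_feature_stats(ratios))
  p <- mod$p[is.finite(mod$p)]
  frac05 <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / length(p))
  expect_lt(abs(frac05 - 0.05), 3 * se + 0.005)
})
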