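# Synthetic call tables with planted detection probabilities.
planted_calls <- function(n, prob_fun, seed = 1, id_range = c(75, 100)) {
  withr::with_seed(seed, {
    pct_id <- runif(n, id_range[1], id_range[2])
    tibble::tibble(pct_id = pct_id,
                   diverged_q10 = runif(n) < prob_fun(pct_id))
  })
}

test_that("detection curve handles degenerate and boundary inputs", {
  all_div <- tibble::tibble(pct_id = runif(200, 80, 100),
                            diverged_q10 = TRUE)
  dc <- detection_curve(all_div, window = 51)
  expect_true(all(dc$fraction == 1))

  n51 <- tibble::tibble(pct_id = sort(runif(51, 80, 100)),
                        diverged_q10 = rep(c(TRUE, FALSE), length.out = 51))
  dc1 <- detection_curve(n51, window = 51)
  expect_identical(nrow(dc1), 1L)
  expect_equal(dc1$fraction, mean(n51$diverged_q10))
  expect_equal(dc1$center_pct_id, mean(n51$pct_id))

  expect_error(detection_curve(n51, window = 52), "odd")
  expect_error(detection_curve(n51[1:20, ], window = 51), "at least")
})

test_that("a planted detectability step produces matching plateaus", {
  calls <- planted_calls(6000, function(id) ifelse(id < 92, 0.95, 0.05),
                         seed = 5)
  dc <- detection_curve(calls, window = 51)
  lo_plateau <- dplyr::filter(dc, .data$center_pct_id < 90)
  hi_plateau <- dplyr::filter(dc, .data$center_pct_id > 94)
  expect_lt(abs(mean(lo_plateau$fraction) - 0.95), 0.05)
  expect_lt(abs(mean(hi_plateau$fraction) - 0.05), 0.05)
})

test_that("ID-50 recovers a planted logistic midpoint and its slope sign", {
  calls <- planted_calls(8000,
                         function(id) plogis(-(id - 94) / 0.6), seed = 9)
  fit <- fit_id50(calls)
  expect_false(fit$out_of_range)
  expect_lt(abs(fit$id50 - 94), 0.5)
  expect_lt(fit$coefficients[["slope"]], 0)

  fitw <- fit_id50(calls, method = "windowed")
  expect_lt(abs(fitw$id50 - 94), 0.5)
})

test_that("degenerate call sets flag the ID-50 as out of range", {
  all_div <- tibble::tibble(pct_id = runif(500, 75, 100),
                            diverged_q10 = TRUE)
  fit <- suppressWarnings(fit_id50(all_div))
  expect_true(fit$out_of_range)
  expect_identical(fit$side, "high")
  expect_true(is.na(fit$id50))
})

test_that("ID-50 is invariant to row order and equivariant under %ID shifts", {
  calls <- planted_calls(4000, function(id) plogis(-(id - 90) / 1.5),
                         seed = 11)
  f1 <- fit_id50(calls)
  f2 <- fit_id50(calls[sample(nrow(calls)), ])
  expect_equal(f1$id50, f2$id50, tolerance = 1e-10)
  shifted <- dplyr::mutate(calls, pct_id = pct_id + 3)
  f3 <- fit_id50(shifted)
  expect_equal(f3$id50_raw, f1$id50_raw + 3, tolerance = 1e-6)
})

test_that("the ratio-vs-%ID regression is exact on noise-free linear data", {
  pct_id <- seq(75, 100, length.out = 200)
  dat <- tibble::tibble(pct_id = pct_id, mean_M = 0.08 * (pct_id - 100))
  lr <- linreg_ratio_id(dat)
  expect_equal(lr$slope, 0.08, tolerance = 1e-10)
  expect_equal(lr$intercept, -8, tolerance = 1e-8)
  expect_equal(lr$r_squared, 1, tolerance = 1e-12)
})

test_that("regression slope is recovered and R^2 equals squared correlation", {
  set.seed(21)
  n <- 10000
  pct_id <- runif(n, 73, 100)
  dat <- tibble::tibble(pct_id = pct_id,
                        mean_M = 0.08 * (pct_id - 100) + rnorm(n, 0, 0.4))
  lr <- linreg_ratio_id(dat)
  expect_lt(abs(lr$slope - 0.08), 3 * lr$slope_se)
  expect_equal(lr$r_squared, cor(dat$mean_M, dat$pct_id)^2,
               tolerance = 1e-12)

  shuffled <- dplyr::mutate(dat, pct_id = sample(pct_id))
  expect_lt(linreg_ratio_id(shuffled)$r_squared, 0.01)

  expect_error(linreg_ratio_id(dplyr::mutate(dat, pct_id = 90)),
               "zero variance")
})

test_that("kinetics regression recovers the planted negative %ID-by-GC sign", {
  an <- shared_dataset()$analyzed
  kin <- kinetics_regression(an)
  row <- dplyr::filter(kin$table, .data$term == "id:gc")
  expect_lt(row$estimate, 0)
  expect_lt(row$p_value, 0.01)
  gc_row <- dplyr::filter(kin$table, .data$term == "gc")
  expect_gt(gc_row$estimate, 0)
})

test_that("a zero planted length effect stays non-significant across seeds", {
  # direct draws from the mean model (length coefficient 0) keep this cheap
  n_sig <- 0
  for (seed in 1:100) {
    dat <- withr::with_seed(seed, {
      n <- 2000
      id <- runif(n, 75, 100)
      gc <- rnorm(n, 50, 8)
      len <- rnorm(n, 500, 80)
      align <- 25 + 0.78 * id + rnorm(n, 0, 6)
      w <- (100 - id) / 20
      mu <- 0.08 * (id - 100) + 0.10 * scale(gc)[, 1] * w -
        0.01 * scale(gc)[, 1] * (id - 100)
      tibble::tibble(mean_M = mu + rnorm(n, 0, 0.3), pct_id = id,
                     gc_percent = gc, probe_length_bp = len,
                     pct_align = align)
    })
    p_len <- kinetics_regression(dat)$table |>
      dplyr::filter(.data$term == "length") |>
      dplyr::pull("p_value")
    n_sig <- n_sig + (p_len < 0.05)
  }
  expect_gte(100 - n_sig, 90)
})

test_that("standardized kinetics estimates are the rescaled raw estimates", {
  an <- shared_dataset()$analyzed
  raw <- kinetics_regression(an, standardize = FALSE)
  std <- kinetics_regression(an, standardize = TRUE)
  dat <- dplyr::filter(an, is.finite(.data$mean_M), is.finite(.data$pct_id),
                       is.finite(.data$pct_align))
  s <- list(M = sd(dat$mean_M), id = sd(dat$pct_id), gc = sd(dat$gc_percent),
            length = sd(dat$probe_length_bp), align = sd(dat$pct_align))
  m <- list(id = mean(dat$pct_id), gc = mean(dat$gc_percent),
            length = mean(dat$probe_length_bp), align = mean(dat$pct_align))
  b <- setNames(raw$table$estimate, raw$table$term)
  bs <- setNames(std$table$estimate, std$table$term)
  # interaction terms rescale directly; main effects absorb centring shifts
  expect_equal(bs[["id:gc"]], b[["id:gc"]] * s$id * s$gc / s$M,
               tolerance = 1e-8)
  expect_equal(bs[["gc"]], (b[["gc"]] + b[["id:gc"]] * m$id) * s$gc / s$M,
               tolerance = 1e-8)
  expect_equal(bs[["id"]],
               (b[["id"]] + b[["id:gc"]] * m$gc + b[["id:length"]] * m$length +
                  b[["id:align"]] * m$align) * s$id / s$M,
               tolerance = 1e-8)
  eff <- standardized_effects(std, pct_id_grid = c(80, 90, 100))
  expect_identical(nrow(eff), 9L)
  gc_eff <- dplyr::filter(eff, .data$term == "gc")
  expect_true(all(diff(gc_eff$effect_size) < 0))  # GC effect fades as %ID rises
})

test_that("collinear covariates raise a rank-deficiency error", {
  an <- shared_dataset()$analyzed |>
    dplyr::mutate(pct_align = .data$gc_percent)
  expect_error(kinetics_regression(an), "collinear")
})

test_that("the robust scale estimator is consistent for normal residuals", {
  set.seed(12)
  x <- rnorm(1e5, 0, 0.3)
  expect_lt(abs(robust_scale(x) - 0.3) / 0.3, 0.02)
  # and the windowed kinetic SD sees it through variance_partition
  dat <- tibble::tibble(
    feature_id = sprintf("F%05d", 1:20000),
    pct_id = sort(runif(20000, 75, 100)),
    n_used = 8L,
    mean_M = rnorm(20000, 0, 0.3),
    s2 = 0.0)
  dat$mean_M <- dat$mean_M  # residuals around a flat line
  vp <- variance_partition(dplyr::mutate(dat, s2 = 1e-12), window = 301)
  expect_lt(abs(median(vp$kinetic_sd) - 0.3) / 0.3, 0.02)
})

test_that("noise-free data give zero technical SD everywhere", {
  dat <- tibble::tibble(
    feature_id = sprintf("F%04d", 1:1000),
    pct_id = sort(runif(1000, 80, 100)),
    n_used = 4L,
    mean_M = 0.05 * (sort(runif(1000, 80, 100)) - 100),
    s2 = 0)
  vp <- variance_partition(dat, window = 301)
  expect_true(all(vp$technical_sd == 0))
})

test_that("kinetic variation overtakes technical error below the crossover", {
  ds <- shared_dataset()
  an <- ds$analyzed
  vp <- variance_partition(an, window = 301)
  cross <- partition_crossover(vp)
  expect_true(is.finite(cross$crossover_pct_id))
  low <- dplyr::filter(vp, .data$center_pct_id <
                         cross$crossover_pct_id - cross$bin_width)
  expect_true(all(low$kinetic_sd > low$technical_sd))
  hi <- dplyr::filter(vp, .data$center_pct_id > 99)
  if (nrow(hi)) expect_true(mean(hi$technical_sd > hi$kinetic_sd) > 0.9)
})

test_that("replication analysis at k = n_arrays equals the full analysis", {
  ds <- shared_dataset()
  ann <- dplyr::transmute(ds$gen$annotations, feature_id,
                          pct_id = true_pct_id)
  rep1 <- replication_power_analysis(ds$ratios, ann, k_list = 8)
  expect_identical(rep1$summary$n_combinations, 1L)
  full_id50 <- fit_id50(ds$analyzed)$id50_raw
  full_lr <- linreg_ratio_id(ds$analyzed)
  expect_equal(rep1$summary$id50, full_id50, tolerance = 1e-8)
  expect_equal(rep1$summary$r_squared, full_lr$r_squared, tolerance = 1e-8)
  expect_equal(rep1$summary$pct_diverged,
               100 * mean(ds$analyzed$diverged_q10), tolerance = 1e-8)
  expect_error(replication_power_analysis(ds$ratios, ann, k_list = 10),
               "exceeds")
})
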