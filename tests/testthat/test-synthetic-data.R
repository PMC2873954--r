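test_that("species profiles validate their mixture", {
  expect_error(species_profile("x", data.frame(weight = c(0.5, 0.4),
                                               mean = c(90, 95),
                                               sd = c(1, 1))),
               "sum to 1")
  expect_error(species_profile("x", data.frame(weight = 1, mean = 55, sd = 1)),
               "60, 100")
  expect_error(species_profile("x", data.frame(weight = 1, mean = 95, sd = 0)),
               "sds")
  expect_error(species_profile("x", data.frame(weight = 1, mean = 95, sd = 2),
                               frac_missing_ortholog = 1.2),
               "frac_missing_ortholog")
})

test_that("generator config rejects invalid geometry", {
  expect_error(generator_config(n_arrays = 3), "even")
  expect_error(generator_config(n_features = 100, conserved_n = 200), "<=")
  expect_error(generator_config(frac_lowquality = 1), "frac_lowquality")
})

test_that("conserved set is exactly the requested size with %ID >= 95", {
  cfg <- generator_config(n_features = 1000, conserved_n = 50, seed = 7,
                          n_arrays = 2)
  gen <- generate_feature_annotations(cfg, profile_closely_diverged())
  cons <- dplyr::filter(gen$annotations, conserved)
  expect_identical(nrow(cons), 50L)
  expect_true(all(cons$true_pct_id >= 95))
  expect_false(any(cons$no_hit))
})

test_that("%ID sampling matches the truncated-normal component mean", {
  prof <- species_profile("one", data.frame(weight = 1, mean = 95.5, sd = 2))
  cfg <- generator_config(n_features = 10000, conserved_n = 0, seed = 3,
                          n_arrays = 2)
  gen <- generate_feature_annotations(cfg, prof)
  # closed-form mean of a normal truncated to [60, 100]
  a <- (60 - 95.5) / 2; b <- (100 - 95.5) / 2
  mu_trunc <- 95.5 + 2 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  se <- sd(gen$annotations$true_pct_id, na.rm = TRUE) / sqrt(10000)
  expect_lt(abs(mean(gen$annotations$true_pct_id, na.rm = TRUE) - mu_trunc),
            3 * se)
})

test_that("probe lengths are centred on ~500 bp and NoHit carries sentinels", {
  gen <- shared_dataset()$gen
  expect_lt(abs(median(gen$annotations$probe_length_bp) - 500), 15)
  expect_true(all(gen$annotations$gc_percent >= 20 &
                    gen$annotations$gc_percent <= 80))
  nh <- dplyr::filter(gen$annotations, no_hit)
  expect_gt(nrow(nh), 0)
  expect_true(all(is.na(nh$true_pct_id)))
  expect_true(all(is.na(nh$pct_align)))
  # no-hit features are simulated at the divergence floor
  expect_true(all(gen$truth$true_pct_id[gen$truth$no_hit] == 60))
})

test_that("percent alignment grows with %ID and can exceed 100", {
  ann <- shared_dataset()$gen$annotations
  ok <- !ann$no_hit
  expect_gt(cor(ann$pct_align[ok], ann$true_pct_id[ok]), 0.5)
  expect_gt(sum(ann$pct_align > 100, na.rm = TRUE), 0)
})

test_that("planted mean ratio is exactly the intercept at 100 %ID and rises with %ID", {
  # covariate effects scale with divergence, so a feature at 100 %ID with no
  # kinetic deviation sits exactly at beta0
  cfg <- generator_config(n_features = 2000, conserved_n = 0, seed = 5,
                          n_arrays = 2, beta0 = 0.25)
  prof100 <- species_profile("pinned",
                             data.frame(weight = 1, mean = 100, sd = 1e-5))
  gen <- generate_feature_annotations(cfg, prof100)
  expect_lt(max(abs(gen$truth$mu - 0.25)), 1e-4)
  # binned planted means are monotone non-decreasing in %ID (beta_id > 0)
  tr <- shared_dataset()$gen$truth
  bins <- cut(tr$true_pct_id, breaks = seq(60, 100, by = 5),
              include.lowest = TRUE)
  bin_mean <- tapply(tr$mu, bins, mean)
  bin_mean <- bin_mean[!is.na(bin_mean)]
  expect_true(all(diff(bin_mean) > 0))
})

test_that("noise-free scans return the planted means exactly after orientation", {
  ds <- noise_free_dataset()
  latent <- ds$gen$truth$mu  # kinetic_dev is 0 here
  for (M in raw_oriented_M(ds$scans)) {
    expect_lt(max(abs(M - latent)), 1e-9)
  }
})

test_that("dye bias separates raw means of the two orientations by 2x bias", {
  cfg <- generator_config(
    n_features = 800, n_arrays = 2, conserved_n = 50, seed = 11,
    sd_kinetic = function(id) rep(0, length(id)),
    sd_technical = function(id) rep(0, length(id)),
    dye_bias = 0.5, intensity_trend_amplitude = 0, frac_lowquality = 0)
  gen <- generate_feature_annotations(cfg, profile_closely_diverged())
  scans <- simulate_scans(gen$annotations, gen$truth, cfg)
  oriented <- raw_oriented_M(scans)
  swapped <- purrr::map_lgl(scans, attr, "dye_swapped")
  expect_setequal(swapped, c(TRUE, FALSE))
  m_fwd <- mean(oriented[[which(!swapped)]])
  m_swp <- mean(oriented[[which(swapped)]])
  expect_lt(abs((m_fwd - m_swp) - 2 * 0.5), 0.01)
})

test_that("the planted low-quality fraction fails the 2-SD filter", {
  cfg <- generator_config(n_features = 5000, n_arrays = 2, conserved_n = 100,
                          seed = 13, frac_lowquality = 0.2)
  gen <- generate_feature_annotations(cfg, profile_closely_diverged())
  scans <- simulate_scans(gen$annotations, gen$truth, cfg)
  for (scan in scans) {
    frac_bad <- 1 - mean(quality_filter(scan)$usable)
    expect_lt(abs(frac_bad - 0.2), 0.02)
  }
})

test_that("generation is deterministic in the config seed", {
  cfg <- generator_config(n_features = 300, n_arrays = 2, conserved_n = 20,
                          seed = 99)
  g1 <- generate_feature_annotations(cfg, profile_distantly_diverged())
  g2 <- generate_feature_annotations(cfg, profile_distantly_diverged())
  expect_identical(g1, g2)
  s1 <- simulate_scans(g1$annotations, g1$truth, cfg)
  s2 <- simulate_scans(g2$annotations, g2$truth, cfg)
  expect_identical(s1, s2)
  cfg2 <- generator_config(n_features = 300, n_arrays = 2, conserved_n = 20,
                           seed = 100)
  g3 <- generate_feature_annotations(cfg2, profile_distantly_diverged())
  expect_false(identical(g1$truth$true_pct_id, g3$truth$true_pct_id))
})

test_that("per-feature replicate SD tracks sd_technical at high replication", {
  cfg <- generator_config(
    n_features = 400, n_arrays = 64, conserved_n = 30, seed = 17,
    sd_kinetic = function(id) rep(0, length(id)),
    dye_bias = 0, intensity_trend_amplitude = 0, frac_lowquality = 0)
  gen <- generate_feature_annotations(cfg, profile_distantly_diverged())
  scans <- simulate_scans(gen$annotations, gen$truth, cfg)
  M <- do.call(cbind, raw_oriented_M(scans))
  emp_sd <- apply(M, 1, sd)
  ratio <- emp_sd / cfg$sd_technical(gen$truth$true_pct_id)
  # per-feature chi has ~9% sampling noise at 63 df; the calibration of the
  # noise scale is judged on the stratified medians
  strata <- cut(gen$truth$true_pct_id, c(60, 85, 95, 100),
                include.lowest = TRUE)
  med <- tapply(ratio, strata, median)
  expect_true(all(abs(med - 1) < 0.1))
})

test_that("datasets round-trip through disk bit-exactly", {
  ds <- noise_free_dataset()
  dir1 <- withr::local_tempdir()
  man <- write_dataset(ds$scans, ds$gen$annotations, ds$gen$truth, dir1,
                       cfg = ds$cfg)
  expect_identical(man$seed, ds$cfg$seed)
  expect_length(man$scan_files, length(ds$scans))

  back <- read_dataset(dir1)
  expect_identical(length(back$scans), length(ds$scans))
  for (nm in names(ds$scans)) {
    expect_identical(attr(back$scans[[nm]], "dye_swapped"),
                     attr(ds$scans[[nm]], "dye_swapped"))
    for (col in c("F635", "B635", "F532", "B532")) {
      expect_identical(back$scans[[nm]][[col]], ds$scans[[nm]][[col]])
    }
  }
  for (col in c("true_pct_id", "pct_align", "gc_percent")) {
    expect_identical(back$annotations[[col]], ds$gen$annotations[[col]])
  }
  expect_identical(back$truth$mu, ds$gen$truth$mu)

  # regenerating under the same seed reproduces the files byte-for-byte
  dir2 <- withr::local_tempdir()
  gen2 <- generate_feature_annotations(ds$cfg, profile_closely_diverged())
  scans2 <- simulate_scans(gen2$annotations, gen2$truth, ds$cfg)
  write_dataset(scans2, gen2$annotations, gen2$truth, dir2, cfg = ds$cfg)
  for (f in list.files(dir1)) {
    expect_identical(unname(tools::md5sum(file.path(dir2, f))),
                     unname(tools::md5sum(file.path(dir1, f))))
  }
})

test_that("an eight-array dataset writes eight scan files", {
  cfg <- generator_config(n_features = 120, n_arrays = 8, conserved_n = 10,
                          seed = 2)
  gen <- generate_feature_annotations(cfg, profile_closely_diverged())
  scans <- simulate_scans(gen$annotations, gen$truth, cfg)
  dir <- withr::local_tempdir()
  man <- write_dataset(scans, gen$annotations, gen$truth, dir)
  expect_length(man$scan_files, 8L)
  expect_true(all(file.exists(file.path(dir, man$scan_files))))
})
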