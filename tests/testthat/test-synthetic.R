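test_that("homogeneous retinal trains hit the expected rate after dead time", {
  cfg <- generator_config(duration_s = 100, rgc_rate_hz = 40, seed = 101L)
  tr <- generate_rgc(cfg)
  # Poisson proposals thinned by the 2-ms dead time: expected count is
  # bounded by the raw Poisson mean above and the dead-time-corrected
  # mean below
  n_raw <- 40 * 100
  lower <- n_raw / (1 + 40 * 0.002) - 3 * sqrt(n_raw)
  upper <- n_raw + 3 * sqrt(n_raw)
  expect_gt(length(tr$times), lower)
  expect_lt(length(tr$times), upper)
  expect_true(all(diff(tr$times) >= 0.002))
  # determinism
  expect_identical(generate_rgc(cfg)$times, tr$times)
})

test_that("grating mode concentrates spectral power at 4 Hz", {
  cfg <- generator_config(duration_s = 100, rgc_rate_hz = 40,
                          rate_mode = "grating_4hz", modulation_depth = 0.8,
                          seed = 102L)
  tr <- generate_rgc(cfg)
  counts <- bin_train(tr, 0.001)$counts
  spec <- Mod(stats::fft(counts - mean(counts)))^2
  freq <- (seq_along(spec) - 1) / 100  # Hz, duration 100 s
  band <- freq > 0.5 & freq < 20
  expect_equal(freq[band][which.max(spec[band])], 4, tolerance = 0.05)
})

test_that("zero modulation depth reproduces the homogeneous train exactly", {
  cfg_g <- generator_config(duration_s = 50, rgc_rate_hz = 30,
                            rate_mode = "grating_4hz", modulation_depth = 0,
                            seed = 103L)
  cfg_h <- generator_config(duration_s = 50, rgc_rate_hz = 30, seed = 103L)
  expect_identical(generate_rgc(cfg_g)$times, generate_rgc(cfg_h)$times)
})

test_that("slow fluctuation mode varies the local rate more than homogeneous", {
  cfg_s <- generator_config(duration_s = 200, rgc_rate_hz = 30,
                            rate_mode = "slow_fluctuation",
                            modulation_depth = 1, seed = 104L)
  cfg_h <- generator_config(duration_s = 200, rgc_rate_hz = 30, seed = 104L)
  # 100-ms bins are on the order of the 50-ms rate correlation time, where
  # the rate fluctuations are visible above Poisson counting noise
  counts_s <- bin_train(generate_rgc(cfg_s), 0.1)$counts
  counts_h <- bin_train(generate_rgc(cfg_h), 0.1)$counts
  expect_gt(var(counts_s), 2 * var(counts_h))
})

test_that("intercept calibration hits the target efficacy within 0.01", {
  for (target in c(0.097, 0.3, 0.6)) {
    cfg <- generator_config(duration_s = 100, rgc_rate_hz = 40,
                            target_efficacy = target,
                            target_contribution = 0.5, seed = 105L)
    gp <- generate_pair(cfg)
    expect_lte(abs(gp$truth$achieved_efficacy - target), 0.01)
  }
})

test_that("full contribution means every LGN spike is triggered", {
  cfg <- generator_config(duration_s = 120, rgc_rate_hz = 40,
                          target_efficacy = 0.3, target_contribution = 1,
                          seed = 106L)
  gp <- generate_pair(cfg)
  expect_equal(gp$truth$achieved_contribution, 1)
  conn <- analyze_connectivity(gp$pair)
  expect_false(is.null(conn$labels))
  # the detected window edges sit at correlogram threshold crossings, so a
  # few delay-jitter tail spikes may fall just outside it
  expect_gte(conn$labels$contribution, 0.98)
})

test_that("the detected window recovers the injected delay at 10k spikes", {
  fx <- synth_labeled_pair(seed = 21, duration = 200, rate = 40,
                           efficacy = 0.3, contribution = 0.7)
  # injected delay 2.8 ms: window must cover it tightly
  expect_lt(abs(fx$window$peak_lag - 0.0028), 3e-4)
  expect_gt(mean(fx$labels$relayed == fx$truth$relayed), 0.95)
})

test_that("cohorts are reproducible and land inside the configured ranges", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- generator_config(duration_s = 40, rgc_rate_hz = 30, seed = 1L)
  m1 <- generate_cohort(4, d1, seed = 77, cfg_base = cfg)
  m2 <- generate_cohort(4, d2, seed = 77, cfg_base = cfg)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  truths <- attr(m1, "truths")
  effs <- vapply(truths, function(tr) tr$achieved_efficacy, numeric(1))
  expect_gte(median(effs), 0.05 - 0.02)
  expect_lte(median(effs), 0.3 + 0.02)
  pairs <- read_manifest(m1)
  expect_length(pairs, 4)
})

test_that("injected bursts are found by the burst detector", {
  cfg <- generator_config(duration_s = 150, rgc_rate_hz = 25,
                          target_efficacy = 0.15, target_contribution = 0.6,
                          burst_config = list(rate_hz = 0.5, spikes_per_burst = 3,
                                              intra_isi_ms = 3, min_gap_ms = 120),
                          seed = 107L)
  gp <- generate_pair(cfg)
  expect_gt(gp$truth$injected_burst_count, 0)
  ann <- detect_bursts(gp$pair$lgn)
  expect_gte(length(ann$bursts), gp$truth$injected_burst_count)
  expect_gt(ann$burst_fraction, 0)
})

test_that("an LGN-history filter shapes relay probability causally", {
  # strong positive LGN filter at short lags: spikes following recent LGN
  # activity relay more often than baseline
  lgn_f <- c(rep(2, 10), rep(0, 40))
  cfg <- generator_config(duration_s = 120, rgc_rate_hz = 30,
                          true_filter = numeric(30) + 0.0,
                          true_lgn_filter = lgn_f,
                          target_efficacy = 0.3, target_contribution = 0.5,
                          seed = 108L)
  gp <- generate_pair(cfg)
  t <- gp$pair$rgc$times
  lgn <- gp$pair$lgn$times
  recent <- vapply(t, function(ti) any(lgn >= ti - 0.010 & lgn < ti), logical(1))
  eff_recent <- mean(gp$truth$relayed[recent])
  eff_quiet <- mean(gp$truth$relayed[!recent])
  expect_gt(eff_recent, eff_quiet + 0.1)
})
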