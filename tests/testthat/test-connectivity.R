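make_pair <- function(rgc, lgn, dur = max(c(rgc, lgn)) + 1) {
  paired_recording("t", spike_train(rgc, dur, "r"), spike_train(lgn, dur, "l"))
}

test_that("cross_correlogram places single pairs in the right lag bin", {
  cg <- cross_correlogram(make_pair(1.0, 1.003))
  hit <- which(cg$counts > 0)
  expect_length(hit, 1)
  expect_true(cg$lags[hit] <= 0.003 + 1e-9 &&
                0.003 < cg$lags[hit] + cg$bin_width + 1e-9)
  expect_equal(sum(cg$counts), 1)

  # identical trains: every spike pairs with itself at lag zero
  t <- sort(runif(100, 0, 10))
  cg2 <- cross_correlogram(make_pair(t, t, 11))
  expect_equal(which.max(cg2$counts), which(cg2$lags == 0))
  expect_gte(max(cg2$counts), 100)

  expect_error(cross_correlogram(make_pair(1, numeric(0), 2)), "nonempty")
})

test_that("correlogram counts match brute-force pair enumeration", {
  for (k in 1:20) {
    rgc <- rand_train(200, 5, 100 + k)$times
    lgn <- rand_train(200, 5, 200 + k)$times
    cg <- cross_correlogram(make_pair(rgc, lgn, 6), max_lag = 0.05)
    lag_all <- as.vector(outer(lgn, rgc, `-`))  # O(n^2) enumeration
    oracle <- vapply(cg$lags, function(lo) {
      sum(lag_all >= lo & lag_all < lo + cg$bin_width)
    }, numeric(1))
    expect_identical(cg$counts, as.integer(oracle))
  }
})

test_that("detect_window implements the mu + 3 sigma short-latency peak rule", {
  w <- 1e-4
  n_bins <- 1200  # [-60, +60] ms
  lags <- -0.06 + (seq_len(n_bins) - 1) * w
  flat <- structure(list(bin_width = w, lags = lags,
                         counts = rep(5L, n_bins)), class = "correlogram")
  # one prominent bin at +3 ms
  cg <- flat
  cg$counts[which(abs(lags - 0.003) < 1e-9)] <- 50L
  win <- detect_window(cg)
  expect_false(is.null(win))
  expect_equal(win$peak_lag, 0.003 + w / 2, tolerance = 1e-9)
  expect_equal(win$hi - win$lo, w)  # single-bin window
  expect_equal(win$mu_baseline, 5)
  expect_equal(win$sigma_baseline, 0)

  # peak outside 2-6 ms is not short-latency
  cg10 <- flat
  cg10$counts[which(abs(lags - 0.010) < 1e-9)] <- 50L
  expect_null(detect_window(cg10))

  # all-equal counts: peak not above threshold
  expect_null(detect_window(flat))
})

test_that("adding a constant to all counts preserves the detection decision", {
  set.seed(5)
  w <- 1e-4
  n_bins <- 1200
  lags <- -0.06 + (seq_len(n_bins) - 1) * w
  counts <- rpois(n_bins, 20)
  counts[which(abs(lags - 0.0025) < 1e-9)] <- 150L
  cg <- structure(list(bin_width = w, lags = lags, counts = counts),
                  class = "correlogram")
  win1 <- detect_window(cg)
  cg$counts <- cg$counts + 37L
  win2 <- detect_window(cg)
  expect_false(is.null(win1))
  expect_false(is.null(win2))
  expect_equal(win2$lo, win1$lo)
  expect_equal(win2$hi, win1$hi)
  expect_equal(win2$mu_baseline, win1$mu_baseline + 37)
  expect_equal(win2$sigma_baseline, win1$sigma_baseline)
})

test_that("label_relay matches the hand-traced example and the brute-force oracle", {
  pair <- make_pair(c(1.0, 2.0), 1.003)
  lab <- label_relay(pair, list(lo = 0.002, hi = 0.004))
  expect_equal(lab$relayed, c(TRUE, FALSE))
  expect_equal(lab$efficacy, 0.5)
  expect_equal(lab$triggered, TRUE)
  expect_equal(lab$contribution, 1.0)

  # no LGN spike near any window
  lab0 <- label_relay(make_pair(c(1, 2, 3), 10, 11), list(lo = 0.002, hi = 0.004))
  expect_equal(lab0$efficacy, 0)

  # brute-force double loop on random trains
  for (k in 1:25) {
    rgc <- rand_train(150, 5, 300 + k)$times
    lgn <- rand_train(150, 5, 400 + k)$times
    lo <- 0.002; hi <- 0.0035
    lab <- label_relay(make_pair(rgc, lgn, 6), list(lo = lo, hi = hi))
    rel_oracle <- vapply(rgc, function(t) any(lgn >= t + lo & lgn < t + hi),
                         logical(1))
    trg_oracle <- vapply(lgn, function(s) any(rgc > s - hi & rgc <= s - lo),
                         logical(1))
    expect_identical(lab$relayed, rel_oracle)
    expect_identical(lab$triggered, trg_oracle)
  }
})

test_that("relayed count never exceeds triggered count under sparse one-to-one spiking", {
  # ISIs much larger than the window: each relayed spike pairs with exactly
  # one triggered LGN spike
  set.seed(8)
  rgc <- cumsum(runif(200, 0.05, 0.2))
  lgn <- rgc[runif(200) < 0.5] + 0.0028
  pair <- make_pair(rgc, lgn, max(rgc, lgn) + 1)
  lab <- label_relay(pair, list(lo = 0.002, hi = 0.004))
  expect_equal(sum(lab$relayed), sum(lab$triggered))
})

test_that("detected window recovers generator ground truth within 0.2 ms", {
  fx <- synth_labeled_pair(seed = 21, duration = 200, rate = 40,
                           efficacy = 0.3, contribution = 0.7)
  expect_gt(length(fx$pair$rgc$times), 5000)
  win <- fx$window
  # true delay 2.8 ms with 0.2 ms jitter truncated at 3 SD: [2.2, 3.4] ms
  expect_false(is.null(win))
  expect_lt(abs(win$lo - 0.0022), 2e-4)
  expect_lt(abs(win$hi - 0.0034), 2e-4)
})
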