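test_that("bernoulli_ll evaluates the closed form and an elementwise oracle", {
  expect_equal(bernoulli_ll(c(0.5, 0.5), c(1, 0)), 2 * log(0.5))
  # perfect hard predictions are bounded by the clip, not -Inf
  expect_gt(bernoulli_ll(c(1, 0), c(1, 0)), -1e-10)
  expect_error(bernoulli_ll(0.5, c(1, 0)), "equal length")
  set.seed(51)
  for (k in 1:20) {
    n <- sample(5:200, 1)
    lam <- runif(n, 0.01, 0.99)
    y <- runif(n) < 0.5
    oracle <- 0
    for (i in seq_len(n)) {
      oracle <- oracle + if (y[i]) log(lam[i]) else log(1 - lam[i])
    }
    expect_equal(bernoulli_ll(lam, y), oracle, tolerance = 1e-12)
  }
})

test_that("i_bernoulli is zero for the homogeneous reference and maximal when perfect", {
  set.seed(52)
  y <- runif(1000) < 0.05
  expect_equal(i_bernoulli(rep(mean(y), 1000), y), 0)
  # perfect predictions attain the binary entropy of the mean efficacy
  p <- mean(y)
  entropy <- -(p * log2(p) + (1 - p) * log2(1 - p))
  expect_equal(i_bernoulli(as.numeric(y), y), entropy, tolerance = 1e-6)
  # frozen spot value from direct evaluation of the definition
  expect_equal(i_bernoulli(c(0.9, 0.1), c(1, 0)), 0.8480, tolerance = 1e-4)
  expect_error(i_bernoulli(numeric(0), numeric(0)), "empty")
})

test_that("i_bernoulli is bounded by the entropy and permutation-invariant", {
  set.seed(53)
  for (k in 1:20) {
    n <- 500
    y <- runif(n) < runif(1, 0.05, 0.5)
    lam <- pmin(pmax(as.numeric(y) + rnorm(n, 0, 0.3), 0.001), 0.999)
    p <- mean(y)
    entropy <- -(p * log2(p) + (1 - p) * log2(1 - p))
    info <- i_bernoulli(lam, y)
    expect_lte(info, entropy + 1e-12)
    perm <- sample(n)
    expect_equal(i_bernoulli(lam[perm], y[perm]), info, tolerance = 1e-12)
  }
})

test_that("fold assignment is a balanced stratified partition", {
  set.seed(54)
  y <- c(rep(TRUE, 100), rep(FALSE, 900))
  f <- make_folds(y, 10, seed = 1)
  tab <- table(f, y)
  expect_true(all(tab[, "TRUE"] == 10))
  expect_true(all(tab[, "FALSE"] == 90))

  # 13 relayed: per-fold relayed counts spread at most 1
  y2 <- c(rep(TRUE, 13), rep(FALSE, 400))
  f2 <- make_folds(y2, 10, seed = 2)
  cnt <- table(factor(f2[y2], levels = 1:10))
  expect_lte(diff(range(cnt)), 1)

  # partition property: every spike in exactly one fold
  expect_true(all(f %in% 1:10))
  expect_length(f, length(y))
  expect_error(make_folds(c(TRUE, FALSE), 10), "at least")
})

test_that("cross-validation gives ~zero information on structureless data", {
  fx <- synth_labeled_pair(seed = 61, duration = 100, rate = 40,
                           efficacy = 0.3, contribution = 0.6)
  # replace labels by coin flips at the same mean: no structure to find
  set.seed(55)
  y_null <- runif(length(fx$pair$rgc$times)) < 0.3
  grid <- small_grid()
  for (m in c("isi", "rh_time")) {
    cv <- cross_validate(m, fx$pair, y_null, grid, seed = 5)
    expect_lt(abs(cv$mean_info), 0.01)
  }
})

test_that("cross-validation is deterministic and ranks models correctly on RH data", {
  fx <- synth_labeled_pair(seed = 11)
  grid <- small_grid()
  cv1 <- cross_validate("rh_time", fx$pair, fx$labels, grid, seed = 7)
  cv2 <- cross_validate("rh_time", fx$pair, fx$labels, grid, seed = 7)
  expect_identical(cv1$per_fold_info, cv2$per_fold_info)
  expect_identical(cv1$chosen_hyperparams, cv2$chosen_hyperparams)
  expect_equal(cv1$mean_info, mean(cv1$per_fold_info))

  # the generating model integrates many lags: retinal history must beat ISI
  cv_isi <- cross_validate("isi", fx$pair, fx$labels, grid, seed = 7)
  expect_gt(cv1$mean_info, cv_isi$mean_info)
  expect_gt(cv_isi$mean_info, 0)
})

test_that("the true generative model is well calibrated; shuffling destroys it", {
  fx <- synth_labeled_pair(seed = 11)
  # reconstruct the generative probabilities from the ground truth
  truth_spec <- glm_truth(fx$truth$theta_r_true, fx$truth$intercept)$spec
  des <- build_design(fx$pair, fx$truth$relayed, truth_spec, min_time = 0)
  lam_true <- plogis(as.numeric(des$X %*% c(fx$truth$theta_r_true,
                                            fx$truth$intercept)))
  y <- fx$truth$relayed[des$spike_index]
  cc <- calibration_curve(lam_true, y, n_bins = 8)
  slope <- coef(lm(observed ~ predicted, data = cc, weights = cc$n))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)

  # constant predictions collapse to the single point (1, 1)
  cc0 <- calibration_curve(rep(mean(y), length(y)), y)
  expect_equal(nrow(cc0), 1)
  expect_equal(cc0$predicted, 1, tolerance = 1e-9)
  expect_equal(cc0$observed, 1, tolerance = 1e-9)

  # shuffled predictions: flat at 1
  set.seed(56)
  cs <- calibration_curve(sample(lam_true), y, n_bins = 8)
  slope_s <- coef(lm(observed ~ predicted, data = cs, weights = cs$n))[2]
  expect_lt(abs(slope_s), 0.2)
})

test_that("info_by_isi decomposes the overall information difference", {
  set.seed(57)
  n <- 4000
  isi <- rexp(n, 25)
  lam_true <- 0.6 * exp(-isi / 0.03) + 0.1
  y <- runif(n) < lam_true
  lam_a <- pmin(pmax(lam_true + rnorm(n, 0, 0.05), 0.01), 0.99)
  lam_b <- rep(mean(y), n)
  tab <- info_by_isi(lam_a, lam_b, y, isi)
  # identical predictions: zero everywhere
  tab0 <- info_by_isi(lam_a, lam_a, y, isi)
  expect_true(all(tab0$delta_info == 0))
  # decomposition: count-weighted bin deltas recompose the overall delta
  ref <- mean(y)
  overall <- i_bernoulli(lam_a, y, reference = ref) -
    i_bernoulli(lam_b, y, reference = ref)
  expect_equal(sum(tab$delta_info * tab$n) / sum(tab$n), overall,
               tolerance = 1e-12)

  # a model that is better only for short ISIs shows gains only there
  lam_c <- lam_b
  short <- isi < 0.01
  lam_c[short] <- pmin(pmax(as.numeric(y[short]), 0.01), 0.99)
  tab2 <- info_by_isi(lam_c, lam_b, y, isi)
  expect_gt(tab2$delta_info[1], 0)
  expect_true(all(abs(tab2$delta_info[-1]) < 1e-12))
})
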