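test_that("raised-cosine basis tiles the warped time axis", {
  b <- make_basis(8, 100, 10)
  expect_equal(dim(b$matrix), c(100, 8))
  expect_true(all(b$matrix >= 0 & b$matrix <= 1))
  # first and last bumps peak exactly at the span endpoints
  expect_equal(b$matrix[1, 1], 1)
  expect_equal(b$matrix[100, 8], 1)
  # each column attains its max at the grid point nearest its center
  u <- log(seq(0, 99) + 10)
  for (k in 1:8) {
    expect_equal(which.max(b$matrix[, k]), which.min(abs(u - b$centers_u[k])))
    # zero outside the support |u - c| >= 2 gamma
    outside <- abs(u - b$centers_u[k]) >= 2 * b$gamma
    expect_true(all(b$matrix[outside, k] == 0))
  }
  expect_error(make_basis(1, 100, 10), "n_basis")
  expect_error(make_basis(8, 100, 0), "psi")
})

test_that("large psi degenerates the basis to linear spacing", {
  b <- make_basis(6, 100, 1e6)
  lin <- seq(0, 99, length.out = 6)
  expect_lt(max(abs(b$centers - lin)) / 99, 0.01)
})

test_that("basis_to_time is linear and round-trips bandlimited filters", {
  b <- make_basis(10, 120, 10)
  for (k in c(1, 5, 10)) {
    e <- numeric(10); e[k] <- 1
    expect_equal(basis_to_time(e, b), b$matrix[, k])
  }
  expect_equal(basis_to_time(numeric(10), b), numeric(120))
  expect_error(basis_to_time(numeric(3), b), "dimension mismatch")

  # a filter in the basis span projects back with < 5% RMS error
  set.seed(41)
  coef_true <- rnorm(10)
  f <- basis_to_time(coef_true, b)
  proj <- qr.solve(b$matrix, f)  # least-squares projection oracle
  back <- basis_to_time(proj, b)
  expect_lt(sqrt(mean((back - f)^2)) / sqrt(mean(f^2)), 0.05)
})

test_that("design rows index history lags correctly and exclude the target", {
  dur <- 2
  t <- c(0.5, 0.998, 1.0)
  pair <- paired_recording("p", spike_train(t, dur), spike_train(1.0, dur))
  des <- build_design(pair, c(FALSE, FALSE, TRUE),
                      glm_spec("rh_time", 10, eta_r = 0), min_time = 0.9)
  # rows for spikes at 0.998 and 1.0; the 1.0 row sees 0.998 at lag 2 ms
  X <- as.matrix(des$X)
  row_t1 <- which(des$spike_index == 3)
  expect_equal(unname(X[row_t1, 1:10]),
               c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0))
  # target spike itself (lag 0) never appears
  expect_equal(sum(X[, 1:10]), 1)
})

test_that("summing design rows yields the autocorrelogram over the span", {
  tr <- rand_train(400, 20, 42)
  pair <- paired_recording("p", tr, spike_train(numeric(0), 20))
  span <- 30
  des <- build_design(pair, rep(FALSE, 400), glm_spec("rh_time", span, eta_r = 0))
  sums <- Matrix::colSums(des$X)[1:span]
  targets <- tr$times[des$spike_index]
  oracle <- vapply(seq_len(span), function(c) {
    sum(vapply(targets, function(t) {
      sum(tr$times >= t - c / 1000 & tr$times < t - (c - 1) / 1000)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(unname(sums), oracle)
})

test_that("LGN history is strictly causal: a spike at the target time changes nothing", {
  rgc <- rand_train(200, 10, 43)
  lgn1 <- rand_train(150, 10, 44)
  spec <- glm_spec("ch", span_r_ms = 20, eta_r = 1, span_l_ms = 20,
                   n_l = 8, eta_l = 1)
  p1 <- paired_recording("a", rgc, lgn1)
  # add an LGN spike exactly at a target retinal time
  t_target <- rgc$times[100]
  lgn2 <- spike_train(sort(c(lgn1$times, t_target)), 10)
  p2 <- paired_recording("b", rgc, lgn2)
  d1 <- build_design(p1, rep(FALSE, 200), spec)
  d2 <- build_design(p2, rep(FALSE, 200), spec)
  r <- which(d1$spike_index == 100)
  expect_equal(as.matrix(d1$X)[r, ], as.matrix(d2$X)[r, ])
})

test_that("intercept-only fit recovers the analytic Bernoulli MLE and SE", {
  set.seed(45)
  n <- 4000
  y <- runif(n) < 0.23
  p_hat <- mean(y)
  des <- manual_design(matrix(numeric(0), n, 0), y)
  fit <- fit_map(des)
  expect_lt(abs(fit$intercept - qlogis(p_hat)), 1e-8)
  fit$spec$kind <- "rh_time"  # SEs defined for time-basis fits
  fit <- standard_errors(fit, des)
  expect_lt(abs(fit$se[1] - 1 / sqrt(n * p_hat * (1 - p_hat))), 1e-6)
})

test_that("SE scales as 1/sqrt(4) when the data are replicated fourfold", {
  set.seed(46)
  n <- 500
  X <- matrix(rnorm(n), n, 1)
  y <- runif(n) < plogis(0.5 * X[, 1] - 1)
  d1 <- manual_design(X, y)
  f1 <- fit_map(d1); f1$spec$kind <- "rh_time"
  f1 <- standard_errors(f1, d1)
  d4 <- manual_design(X[rep(1:n, 4), , drop = FALSE], rep(y, 4))
  f4 <- fit_map(d4); f4$spec$kind <- "rh_time"
  f4 <- standard_errors(f4, d4)
  expect_equal(f4$se, f1$se / 2, tolerance = 1e-6)
})

test_that("SEs are refused for cosine-basis fits", {
  fx <- synth_labeled_pair()
  spec <- glm_spec("ch", span_r_ms = 30, eta_r = 1, span_l_ms = 30,
                   n_l = 8, eta_l = 1)
  des <- build_design(fx$pair, fx$labels, spec)
  fit <- fit_map(des)
  expect_error(standard_errors(fit, des), "time-basis")
})

test_that("a huge smoothing weight flattens the filter", {
  fx <- synth_labeled_pair()
  spec <- glm_spec("rh_time", span_r_ms = 30, eta_r = 1e9)
  des <- build_design(fx$pair, fx$labels, spec)
  fit <- fit_map(des)
  expect_lt(max(abs(diff(fit$theta_r_time))), 1e-4)
})

test_that("Newton MAP fits agree with a generic optimizer on random problems", {
  set.seed(47)
  for (k in 1:20) {
    n <- 200
    span <- 30
    tr <- rand_train(n, n / 40, 4700 + k)  # ~40 Hz
    pair <- paired_recording("p", tr, spike_train(numeric(0), tr$duration))
    y <- runif(n) < 0.3
    if (length(unique(y)) < 2) y[1:2] <- c(TRUE, FALSE)
    prior <- if (k %% 2 == 0) "smoothing" else "ridge"
    eta <- sample(c(0.5, 4, 32), 1)
    kind <- if (prior == "smoothing") "rh_time" else "rh_cosine"
    spec <- glm_spec(kind, span_r_ms = span, eta_r = eta)
    des <- build_design(pair, y, spec, min_time = 0)
    fit <- fit_map(des)
    X <- as.matrix(des$X)
    obj <- function(th) -oracle_penalized_ll(th, X, des$y, eta, prior, des$col_r)
    p <- ncol(X)
    opt <- optim(numeric(p), obj, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-15))
    expect_lt(max(abs(fit$theta - opt$par)), 1e-6)
  }
})

test_that("simulate_relay draws Bernoulli outcomes at the model rate", {
  tr <- rand_train(10000, 250, 48)
  truth <- glm_truth(numeric(30), qlogis(0.3))
  y <- simulate_relay(tr, truth, seed = 49)
  expect_lt(abs(mean(y) - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
  # an effectively minus-infinity intercept relays nothing
  expect_equal(sum(simulate_relay(tr, glm_truth(numeric(30), -50), seed = 49)), 0)
  # determinism
  expect_identical(y, simulate_relay(tr, truth, seed = 49))
  expect_false(identical(y, simulate_relay(tr, truth, seed = 50)))
})

test_that("single-class responses are rejected", {
  fx <- synth_labeled_pair()
  spec <- glm_spec("rh_time", 30, eta_r = 10)
  des <- build_design(fx$pair, rep(TRUE, length(fx$pair$rgc$times)), spec)
  expect_error(fit_map(des), "single class")
})
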