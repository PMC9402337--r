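# fixture builders shared across test files; everything is generated in code

# random spike train with strictly increasing times in (0, duration)
rand_train <- function(n, duration = 10, seed = 1, id = "u") {
  set.seed(seed)
  t <- sort(runif(n, 0, duration))
  while (any(diff(t) <= 1e-9)) t <- sort(runif(n, 0, duration))
  spike_train(t, duration, id)
}

# a quick connected synthetic pair with labels, cached per parameter set so
# multiple test files can reuse the same fixture without regenerating
.pair_cache <- new.env()
synth_labeled_pair <- function(seed = 11, duration = 150, rate = 40,
                               efficacy = 0.2, contribution = 0.6,
                               span_ms = 100) {
  key <- paste(seed, duration, rate, efficacy, contribution, span_ms, sep = "_")
  if (!is.null(.pair_cache[[key]])) return(.pair_cache[[key]])
  cfg <- generator_config(duration_s = duration, rgc_rate_hz = rate,
                          true_filter = doe_filter(span_ms = span_ms),
                          target_efficacy = efficacy,
                          target_contribution = contribution,
                          seed = as.integer(seed))
  gp <- generate_pair(cfg)
  conn <- analyze_connectivity(gp$pair)
  out <- list(pair = gp$pair, truth = gp$truth,
              labels = conn$labels, window = conn$window)
  .pair_cache[[key]] <- out
  out
}

# a tiny reduced hyperparameter grid for fast cross-validation tests
small_grid <- function() {
  list(isi_max = c(0.05, 0.2), isi_sigma = c(0, 0.005),
       rh_span_ms = c(30, 100), rh_eta = c(16, 256),
       ch_span_l_ms = c(50, 100), ch_n_l = 8, ch_eta = c(0.5, 4))
}

# independent penalized-objective evaluation used by optimizer-oracle tests:
# written against the model definition, not the package internals
oracle_penalized_ll <- function(theta, X, y, eta, prior = c("smoothing", "ridge"),
                                filter_cols) {
  prior <- match.arg(prior)
  lam <- 1 / (1 + exp(-as.numeric(X %*% theta)))
  lam <- pmin(pmax(lam, 1e-12), 1 - 1e-12)
  ll <- sum(y * log(lam) + (1 - y) * log(1 - lam))
  pen <- if (prior == "smoothing") {
    eta * sum(diff(theta[filter_cols])^2)
  } else {
    eta * sum(theta[filter_cols]^2)
  }
  ll - pen
}

# an intercept-plus-covariates design object accepted by fit_map, built
# directly (bypasses build_design for synthetic regression problems)
manual_design <- function(X_no_int, y, prior = "ridge", eta_r = 0) {
  X <- cbind(X_no_int, 1)
  structure(list(
    X = X, y = as.numeric(y), spike_index = seq_along(y),
    spec = structure(list(kind = "manual", prior = prior,
                          eta_r = eta_r, eta_l = 0), class = "glm_spec"),
    basis_r = NULL, basis_l = NULL,
    col_r = seq_len(ncol(X) - 1L), col_l = integer(0)),
    class = "glm_design")
}
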