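#' Partition retinal spikes by preceding LGN activity
#'
#' Counts LGN spikes in the window \code{[t_i - window, t_i)} preceding each
#' retinal spike, ranks spikes by (count, time) ascending, and splits the
#' ranks into \code{n_subsets} contiguous blocks of near-equal size. Subset
#' 1 is the lowest-activity block. The time tie-break makes the assignment
#' deterministic for discrete counts.
#'
#' @param pair a \code{paired_recording}.
#' @param window_ms counting window, ms (default 100).
#' @param n_subsets number of subsets: 4 for quartiles (default), 2 for a
#'   median split (recommended for short recordings).
#' @param min_per_subset minimum spikes required per subset (default 50);
#'   fewer triggers an error advising a median split.
#' @return an object of class \code{activity_partition}: \code{count}
#'   (LGN spikes in the window, per retinal spike), \code{subset} (integer
#'   1..n_subsets per spike), \code{window_ms}, \code{n_subsets}.
#' @export
partition_by_activity <- function(pair, window_ms = 100, n_subsets = 4L,
                                  min_per_subset = 50L) {
  stopifnot(inherits(pair, "paired_recording"))
  if (window_ms <= 0) stop("window_ms must be > 0")
  t <- pair$rgc$times
  lgn <- pair$lgn$times
  w <- window_ms / 1000
  count <- findInterval(t, lgn, left.open = TRUE) -
    findInterval(t - w, lgn, left.open = TRUE)
  n <- length(t)
  if (n < n_subsets * min_per_subset) {
    stop(sprintf(
      "too few retinal spikes (%d) for %d subsets of >= %d; consider a median split (n_subsets = 2)",
      n, n_subsets, min_per_subset))
  }
  rk <- order(count, t)
  sizes <- rep(n %/% n_subsets, n_subsets)
  extra <- n %% n_subsets
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  subset <- integer(n)
  subset[rk] <- rep.int(seq_len(n_subsets), sizes)
  structure(list(count = count, subset = subset, window_ms = window_ms,
                 n_subsets = n_subsets),
            class = "activity_partition")
}

#' Fit one GLM per activity subset
#'
#' Fits independent \code{rh_cosine} models, one per subset, sharing the
#' visualization specification (span, basis count, warp) except the ridge
#' weight, which is selected per pair by simple 10-fold cross-validation on
#' the full data before the per-subset fits.
#'
#' @param pair a \code{paired_recording}.
#' @param labels relay labels (or logical vector).
#' @param partition an \code{activity_partition}.
#' @param span_r_ms filter span, ms (default 200).
#' @param n_r basis vectors (default 16).
#' @param eta_grid candidate ridge weights (default the ch grid); a single
#'   value skips selection.
#' @param seed seed for the eta-selection folds.
#' @return list with \code{fits} (one \code{glm_fit} per subset, NULL where
#'   a fit failed -> \code{partial = TRUE}), \code{eta}, \code{partial}.
#' @export
fit_by_subset <- function(pair, labels, partition, span_r_ms = 200, n_r = 16L,
                          eta_grid = default_grids()$ch_eta, seed = 1L) {
  stopifnot(inherits(partition, "activity_partition"))
  y_all <- if (inherits(labels, "relay_labels")) labels$relayed else as.logical(labels)
  eta <- if (length(eta_grid) > 1L) {
    .select_eta(pair, y_all, span_r_ms, n_r, eta_grid, seed)
  } else eta_grid
  spec <- glm_spec("rh_cosine", span_r_ms = span_r_ms, eta_r = eta, n_r = n_r)
  des <- build_design(pair, y_all, spec)
  fits <- vector("list", partition$n_subsets)
  for (s in seq_len(partition$n_subsets)) {
    rows <- which(partition$subset[des$spike_index] == s)
    sub <- des
    sub$X <- des$X[rows, , drop = FALSE]
    sub$y <- des$y[rows]
    sub$spike_index <- des$spike_index[rows]
    fits[[s]] <- tryCatch(fit_map(sub, on_nonconvergence = "warn"),
                          error = function(e) NULL)
  }
  list(fits = fits, eta = eta, partial = any(vapply(fits, is.null, logical(1))))
}

# per-pair ridge weight by simple (non-nested) 10-fold CV on the full data
.select_eta <- function(pair, y_all, span_r_ms, n_r, eta_grid, seed) {
  spec0 <- glm_spec("rh_cosine", span_r_ms = span_r_ms, eta_r = eta_grid[1L],
                    n_r = n_r)
  des <- build_design(pair, y_all, spec0)
  fold <- make_folds(des$y, n_folds = 10L, seed = seed)
  score <- vapply(eta_grid, function(eta) {
    des$spec$eta_r <- eta
    info <- vapply(1:10, function(f) {
      tr <- which(fold != f); te <- which(fold == f)
      sub <- des
      sub$X <- des$X[tr, , drop = FALSE]
      sub$y <- des$y[tr]
      fit <- tryCatch(fit_map(sub, on_nonconvergence = "warn"),
                      error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      lam <- 1 / (1 + exp(-as.numeric(des$X[te, , drop = FALSE] %*% fit$theta)))
      i_bernoulli(lam, des$y[te])
    }, numeric(1))
    mean(info, na.rm = TRUE)
  }, numeric(1))
  # ties toward the larger penalty (parsimony)
  ord <- order(-eta_grid)
  eta_grid[ord][which.max(score[ord])]
}

#' Absolute-difference metric between two filters
#'
#' Both filters are scaled to unit Euclidean norm, then the sum of absolute
#' pointwise differences is taken over the requested lag range (all lags by
#' default, or e.g. the 30 ms immediately preceding the target spike). A
#' plain sum over 1-ms lag bins; dimensionless. This is a metric on
#' unit-norm filters (zero iff identical, symmetric, triangle inequality).
#'
#' @param theta_n,theta_m filters on the same 1-ms lag grid.
#' @param lag_range integer lag indices to include (default all).
#' @return an object of class \code{filter_comparison}:
#'   \code{abs_difference}, \code{n_lags}.
#' @export
filter_abs_difference <- function(theta_n, theta_m,
                                  lag_range = seq_along(theta_n)) {
  if (length(theta_n) != length(theta_m)) {
    stop("filters must share one lag grid")
  }
  un <- theta_n / sqrt(sum(theta_n^2))
  um <- theta_m / sqrt(sum(theta_m^2))
  structure(list(abs_difference = sum(abs(un[lag_range] - um[lag_range])),
                 n_lags = length(lag_range)),
            class = "filter_comparison")
}

#' Population-average filter with bootstrap confidence band
#'
#' Scales each pair's filter to unit norm, averages pointwise, and attaches
#' a per-lag 95 percent BCa bootstrap confidence interval across pairs.
#'
#' @param filters list (or matrix, pairs x lags) of filters on one lag grid.
#' @param n_resamples bootstrap resamples per lag (default 1000; the band is
#'   descriptive).
#' @param seed integer seed.
#' @return list with \code{mean}, \code{lo}, \code{hi} (vectors over lags)
#'   and \code{n_pairs}.
#' @export
population_average_filters <- function(filters, n_resamples = 1000L, seed = 1L) {
  M <- if (is.list(filters)) do.call(rbind, filters) else as.matrix(filters)
  if (nrow(M) < 3L) stop("need at least 3 pairs")
  M <- M / sqrt(rowSums(M^2))
  mean_f <- colMeans(M)
  lo <- hi <- numeric(ncol(M))
  for (j in seq_len(ncol(M))) {
    if (max(M[, j]) - min(M[, j]) < 1e-15) {
      lo[j] <- hi[j] <- mean_f[j]
    } else {
      ci <- bca_bootstrap(M[, j], statistic = mean, n_resamples = n_resamples,
                          seed = seed + j)
      lo[j] <- ci$lo
      hi[j] <- ci$hi
    }
  }
  list(mean = mean_f, lo = lo, hi = hi, n_pairs = nrow(M))
}

#' Split-half null distribution for filter differences
#'
#' The control against which between-subset filter differences are judged:
#' repeatedly split one subset's spikes into random halves, fit the same
#' model to each half, and record the absolute-difference metric between the
#' two half fits. Differences between activity subsets that stay below the
#' 95th percentile of this null are indistinguishable from fitting noise.
#'
#' @param pair,labels,partition as in \code{\link{fit_by_subset}}.
#' @param span_r_ms,n_r,eta model settings (eta fixed here; pass the value
#'   selected by \code{\link{fit_by_subset}}).
#' @param n_splits number of random split-half replicates (default 20).
#' @param lag_range lag indices for the metric (default all).
#' @param seed integer seed.
#' @return numeric vector of \code{n_splits * n_subsets} null differences.
#' @export
split_half_null <- function(pair, labels, partition, span_r_ms = 200,
                            n_r = 16L, eta = 1, n_splits = 20L,
                            lag_range = NULL, seed = 1L) {
  y_all <- if (inherits(labels, "relay_labels")) labels$relayed else as.logical(labels)
  spec <- glm_spec("rh_cosine", span_r_ms = span_r_ms, eta_r = eta, n_r = n_r)
  des <- build_design(pair, y_all, spec)
  rs <- .seeded_rng(seed)
  out <- numeric(0)
  for (s in seq_len(partition$n_subsets)) {
    rows <- which(partition$subset[des$spike_index] == s)
    for (k in seq_len(n_splits)) {
      perm <- rows[rs$sample(length(rows))]
      half <- length(perm) %/% 2L
      f1 <- .fit_rows(des, perm[seq_len(half)])
      f2 <- .fit_rows(des, perm[(half + 1L):length(perm)])
      if (is.null(f1) || is.null(f2)) next
      lr <- lag_range %||% seq_along(f1$theta_r_time)
      out <- c(out, filter_abs_difference(f1$theta_r_time, f2$theta_r_time,
                                          lr)$abs_difference)
    }
  }
  out
}

.fit_rows <- function(des, rows) {
  sub <- des
  sub$X <- des$X[rows, , drop = FALSE]
  sub$y <- des$y[rows]
  tryCatch(fit_map(sub, on_nonconvergence = "warn"), error = function(e) NULL)
}
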