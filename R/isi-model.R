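#' Preceding interspike intervals of a spike train
#'
#' @param train a \code{spike_train} (or numeric vector of times).
#' @return numeric vector, one per spike: the ISI preceding each spike in
#'   seconds, \code{NA} for the first spike of a recording.
#' @export
preceding_isi <- function(train) {
  times <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  if (!length(times)) return(numeric(0))
  c(NA_real_, diff(times))
}

# bin index for an ISI on the 1-ms grid covering (0, isi_max]: bin b
# (1-based) covers [(b-1), b) ms (floor convention); an ISI exactly at
# isi_max is clamped into the last bin so the range is closed on the right
.isi_bin <- function(isi, bin_width = 0.001, n_bins = NULL) {
  b <- as.integer(floor(isi / bin_width + 1e-9)) + 1L
  if (!is.null(n_bins)) b[!is.na(isi) & abs(isi / bin_width - n_bins) < 1e-9] <- n_bins
  b
}

# discrete Gaussian smoothing with a unit-area kernel truncated at +/- 4 SD,
# renormalized where the kernel runs off the edge of the support
.gauss_smooth <- function(x, sigma_bins) {
  if (sigma_bins <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_bins))
  k <- stats::dnorm(seq(-half, half), sd = sigma_bins)
  k <- k / sum(k)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    w <- k[j - i + half + 1L]
    out[i] <- sum(w * x[j]) / sum(w)
  }
  out
}

#' Build the ISI-efficacy function
#'
#' The nonparametric core of the ISI model: per 1-ms ISI bin over
#' \code{(0, isi_max]}, the fraction of spikes in that bin that were relayed
#' (a histogram of ISIs preceding relayed spikes divided, bin by bin, by the
#' histogram of all ISIs). Empty bins are filled with the training-set mean
#' efficacy (the model's own fallback value) before smoothing; the resulting
#' ratio function is then smoothed with a unit-area Gaussian of SD
#' \code{sigma} truncated at 4 SD and renormalized at the edges.
#' \code{sigma = 0} skips smoothing.
#'
#' @param isi numeric vector of preceding ISIs (seconds), \code{NA} allowed
#'   for first spikes.
#' @param y relay status per spike (logical or 0/1).
#' @param isi_max maximum ISI represented (seconds, > 0); longer ISIs are
#'   excluded from the histogram and handled at prediction time.
#' @param sigma smoothing SD in seconds (0 = none).
#' @return an object of class \code{isi_efficacy} with fields
#'   \code{bin_width}, \code{isi_max}, \code{efficacy_by_bin},
#'   \code{smoothing_sigma}, \code{train_mean_efficacy}, and (after
#'   \code{\link{calibrate_isi}}) \code{beta}, \code{alpha}.
#' @export
build_isi_function <- function(isi, y, isi_max, sigma = 0) {
  if (isi_max <= 0) stop("isi_max must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  y <- as.numeric(y)
  if (length(isi) != length(y)) stop("isi and y must have equal length")
  bw <- 0.001
  n_bins <- as.integer(ceiling(isi_max / bw - 1e-9))
  mean_eff <- mean(y)
  b <- .isi_bin(isi, bw, n_bins)
  ok <- !is.na(b) & b >= 1L & b <= n_bins
  tot <- tabulate(b[ok], nbins = n_bins)
  rel <- tabulate(b[ok & y > 0], nbins = n_bins)
  eff <- ifelse(tot > 0, rel / pmax(tot, 1L), mean_eff)
  eff <- .gauss_smooth(eff, sigma / bw)
  structure(list(bin_width = bw, isi_max = isi_max,
                 efficacy_by_bin = eff, smoothing_sigma = sigma,
                 train_mean_efficacy = mean_eff,
                 beta = NULL, alpha = NULL),
            class = "isi_efficacy")
}

#' @export
print.isi_efficacy <- function(x, ...) {
  cat(sprintf("<isi_efficacy: %d 1-ms bins to %.0f ms, sigma %.1f ms, mean eff %.3f%s>\n",
              length(x$efficacy_by_bin), x$isi_max * 1000,
              x$smoothing_sigma * 1000, x$train_mean_efficacy,
              if (is.null(x$beta)) " (uncalibrated)"
              else sprintf(", beta %.3f alpha %.3f", x$beta, x$alpha)))
  invisible(x)
}

# P value looked up for each spike; out-of-range and missing ISIs get the
# training-set mean efficacy
.isi_lookup <- function(fun, isi) {
  b <- .isi_bin(isi, fun$bin_width, length(fun$efficacy_by_bin))
  n_bins <- length(fun$efficacy_by_bin)
  out <- rep(fun$train_mean_efficacy, length(isi))
  ok <- !is.na(b) & b >= 1L & b <= n_bins
  out[ok] <- fun$efficacy_by_bin[b[ok]]
  list(P = out, in_range = ok)
}

#' Calibrate an ISI-efficacy function with an affine-logistic map
#'
#' Finds the linear transform \code{f(P) = beta * P + alpha} such that the
#' Bernoulli log-likelihood of \code{lambda = sigma(f(P))} on the training
#' data is maximized (a two-parameter logistic regression on the looked-up
#' efficacy P, fitted with the package's Newton solver). Without this step
#' the raw efficacies may be mis-scaled relative to the mean efficacy
#' (because of the ISI cutoff), which would unfairly penalize the model in
#' the information metric. Out-of-range ISIs are substituted with the
#' training-set mean efficacy before calibration. When P is constant the
#' slope is unidentifiable; \code{beta = 0} and
#' \code{alpha = logit(mean(y))} are returned, so predictions equal the mean
#' efficacy.
#'
#' @param fun an \code{isi_efficacy} from \code{\link{build_isi_function}}.
#' @param isi_train,y_train training ISIs and relay status.
#' @return the \code{isi_efficacy} with \code{beta} and \code{alpha} set.
#' @export
calibrate_isi <- function(fun, isi_train, y_train) {
  stopifnot(inherits(fun, "isi_efficacy"))
  y <- as.numeric(y_train)
  if (length(unique(y)) < 2L) {
    stop("calibration requires both outcome classes in the training data")
  }
  P <- .isi_lookup(fun, isi_train)$P
  if (stats::var(P) < 1e-14) {
    fun$beta <- 0
    fun$alpha <- stats::qlogis(mean(y))
    return(fun)
  }
  X <- cbind(P, 1)
  des <- structure(list(
    X = X, y = y, spike_index = seq_along(y),
    spec = structure(list(kind = "calibration", prior = "ridge",
                          eta_r = 0, eta_l = 0), class = "glm_spec"),
    basis_r = NULL, basis_l = NULL, col_r = 1L, col_l = integer(0)),
    class = "glm_design")
  fit <- fit_map(des, on_nonconvergence = "warn")
  fun$beta <- fit$theta[1L]
  fun$alpha <- fit$theta[2L]
  fun
}

#' Predict relay probabilities from a calibrated ISI-efficacy function
#'
#' For test spikes with ISI at most \code{isi_max} the prediction is
#' \code{sigma(beta * P(bin(ISI)) + alpha)}. Spikes with longer (or missing,
#' i.e., first-spike) ISIs receive the test-set mean efficacy exactly,
#' bypassing the affine-logistic map.
#'
#' @param fun a calibrated \code{isi_efficacy}.
#' @param isi_test test-set preceding ISIs (seconds; NA for first spikes).
#' @param test_mean_efficacy mean efficacy of the test set; values outside
#'   (0, 1) are clipped to \code{[1e-6, 1 - 1e-6]} with a warning.
#' @return numeric vector of relay probabilities in (0, 1).
#' @export
predict_isi <- function(fun, isi_test, test_mean_efficacy) {
  stopifnot(inherits(fun, "isi_efficacy"))
  if (is.null(fun$beta)) stop("predict_isi requires a calibrated function; run calibrate_isi first")
  if (test_mean_efficacy <= 0 || test_mean_efficacy >= 1) {
    warning("test_mean_efficacy outside (0,1); clipping")
    test_mean_efficacy <- min(max(test_mean_efficacy, 1e-6), 1 - 1e-6)
  }
  lk <- .isi_lookup(fun, isi_test)
  lam <- rep(test_mean_efficacy, length(isi_test))
  lam[lk$in_range] <- stats::plogis(fun$beta * lk$P[lk$in_range] + fun$alpha)
  pmin(pmax(lam, 1e-12), 1 - 1e-12)
}
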