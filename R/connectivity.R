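#' Spike-time cross-correlogram
#'
#' Counts LGN spikes relative to each retinal spike in 0.1-ms bins over a
#' symmetric lag range. \code{counts[j]} is the number of (rgc, lgn) spike
#' pairs whose lag \code{lgn - rgc} falls in the half-open bin
#' \code{[lags[j], lags[j] + bin_width)}; \code{lags} are bin left edges
#' spanning \code{[-max_lag, +max_lag)}.
#'
#' @param pair a \code{paired_recording} with both trains nonempty.
#' @param max_lag maximum lag magnitude, seconds. The default 0.06 s leaves
#'   room for the 30-50 ms baseline band on both sides of any admissible
#'   short-latency peak.
#' @param bin_width bin width, seconds (default 0.0001 = 0.1 ms).
#' @return an object of class \code{correlogram} with fields
#'   \code{bin_width}, \code{lags}, \code{counts}.
#' @export
cross_correlogram <- function(pair, max_lag = 0.06, bin_width = 0.0001) {
  stopifnot(inherits(pair, "paired_recording"))
  if (!length(pair$rgc$times) || !length(pair$lgn$times)) {
    stop("cross_correlogram requires both trains nonempty")
  }
  n_bins <- round(2 * max_lag / bin_width)
  if (abs(n_bins * bin_width - 2 * max_lag) > 1e-12) {
    stop("2*max_lag must be an integer multiple of bin_width")
  }
  n_half <- n_bins %/% 2L
  lags <- (seq_len(n_bins) - 1L - n_half) * bin_width
  rgc <- pair$rgc$times
  lgn <- pair$lgn$times
  counts <- integer(n_bins)
  # two-pointer sweep: for each rgc spike, lgn spikes within (t-max_lag, t+max_lag)
  lo <- 1L
  n_l <- length(lgn)
  for (t in rgc) {
    while (lo <= n_l && lgn[lo] < t - max_lag) lo <- lo + 1L
    k <- lo
    while (k <= n_l && lgn[k] < t + max_lag) {
      # small epsilon keeps exact bin-edge lags in their half-open bin
      j <- floor((lgn[k] - t) / bin_width + 1e-9) + n_half + 1L
      if (j >= 1 && j <= n_bins) counts[j] <- counts[j] + 1L
      k <- k + 1L
    }
  }
  structure(list(bin_width = bin_width, lags = lags, counts = counts),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("<correlogram: %d bins of %.4g ms, lags [%.1f, %.1f] ms, %d pairs>\n",
              length(x$counts), x$bin_width * 1000,
              min(x$lags) * 1000, (max(x$lags) + x$bin_width) * 1000,
              sum(x$counts)))
  invisible(x)
}

#' Detect a monosynaptic response window in a correlogram
#'
#' The peak bin is the global argmax of the correlogram (ties broken toward
#' the smallest lag, the earliest physiologically plausible latency). The
#' baseline is the set of bins whose centers lie 30-50 ms from the peak-bin
#' center, pooled from both sides. A connection is declared only if the peak
#' count exceeds \code{mu + 3*sigma} of the baseline AND the peak-bin center
#' falls within 2-6 ms after the retinal spike. The monosynaptic window is
#' the maximal contiguous run of bins including the peak whose counts all
#' exceed the threshold; \code{lo}/\code{hi} are the run's outer bin edges.
#'
#' @param cg a \code{correlogram} spanning at least peak + 50 ms.
#' @param sd_denominator \code{"population"} (denominator n, default) or
#'   \code{"sample"} (n - 1) for the baseline SD.
#' @return an object of class \code{monosyn_window} with fields \code{lo},
#'   \code{hi}, \code{peak_lag} (bin center, seconds), \code{mu_baseline},
#'   \code{sigma_baseline}; or \code{NULL} if no window qualifies.
#' @export
detect_window <- function(cg, sd_denominator = c("population", "sample")) {
  stopifnot(inherits(cg, "correlogram"))
  sd_denominator <- match.arg(sd_denominator)
  w <- cg$bin_width
  centers <- cg$lags + w / 2
  peak <- which.max(cg$counts)  # which.max takes the first maximum: smallest lag
  peak_center <- centers[peak]
  if (peak_center < 0.002 - 1e-12 || peak_center > 0.006 + 1e-12) return(NULL)
  if ((max(cg$lags) + w) - peak_center < 0.05 - 1e-12) {
    stop("correlogram too short: needs to span at least peak + 50 ms")
  }
  d <- abs(centers - peak_center)
  base <- which(d >= 0.030 - 1e-12 & d <= 0.050 + 1e-12)
  bvals <- cg$counts[base]
  mu <- mean(bvals)
  sigma <- if (sd_denominator == "population") {
    sqrt(mean((bvals - mu)^2))
  } else {
    stats::sd(bvals)
  }
  thr <- mu + 3 * sigma
  if (!(cg$counts[peak] > thr)) return(NULL)
  # maximal contiguous supra-threshold run through the peak
  i0 <- peak
  while (i0 > 1L && cg$counts[i0 - 1L] > thr) i0 <- i0 - 1L
  i1 <- peak
  while (i1 < length(cg$counts) && cg$counts[i1 + 1L] > thr) i1 <- i1 + 1L
  structure(list(lo = cg$lags[i0], hi = cg$lags[i1] + w,
                 peak_lag = peak_center,
                 mu_baseline = mu, sigma_baseline = sigma,
                 sd_denominator = sd_denominator),
            class = "monosyn_window")
}

#' @export
print.monosyn_window <- function(x, ...) {
  cat(sprintf("<monosyn_window: [%.2f, %.2f] ms, peak %.2f ms, baseline %.2f +/- %.2f>\n",
              x$lo * 1000, x$hi * 1000, x$peak_lag * 1000,
              x$mu_baseline, x$sigma_baseline))
  invisible(x)
}

#' Label relayed retinal spikes and triggered LGN spikes
#'
#' Retinal spike i is "relayed" iff at least one LGN spike falls in
#' \code{[t_i + lo, t_i + hi)}; LGN spike k is "triggered" iff at least one
#' retinal spike falls in \code{(s_k - hi, s_k - lo]} (the same pairings seen
#' from the other side). One LGN spike may mark several retinal spikes'
#' windows and vice versa; labels are defined by window membership only.
#' Efficacy is the fraction of retinal spikes relayed; contribution is the
#' fraction of LGN spikes triggered.
#'
#' @param pair a \code{paired_recording}.
#' @param win a \code{monosyn_window} (or any list with \code{lo}, \code{hi}
#'   in seconds).
#' @return an object of class \code{relay_labels} with fields
#'   \code{relayed} (logical per retinal spike), \code{triggered} (logical
#'   per LGN spike), \code{efficacy}, \code{contribution}, \code{window}.
#' @export
label_relay <- function(pair, win) {
  stopifnot(inherits(pair, "paired_recording"))
  if (is.null(win) || is.null(win$lo) || is.null(win$hi) || win$lo > win$hi) {
    stop("label_relay requires a valid window with lo <= hi")
  }
  rgc <- pair$rgc$times
  lgn <- pair$lgn$times
  # count of lgn spikes in [t + lo, t + hi): findInterval on half-open edges
  n_in <- findInterval(rgc + win$hi, lgn, left.open = TRUE) -
    findInterval(rgc + win$lo, lgn, left.open = TRUE)
  relayed <- n_in > 0
  # rgc spikes in (s - hi, s - lo]
  n_back <- findInterval(lgn - win$lo, rgc) - findInterval(lgn - win$hi, rgc)
  triggered <- n_back > 0
  structure(list(relayed = relayed, triggered = triggered,
                 efficacy = mean(relayed), contribution = mean(triggered),
                 window = c(lo = win$lo, hi = win$hi)),
            class = "relay_labels")
}

#' @export
print.relay_labels <- function(x, ...) {
  cat(sprintf("<relay_labels: efficacy %.3f (%d/%d), contribution %.3f (%d/%d), window [%.2f, %.2f] ms>\n",
              x$efficacy, sum(x$relayed), length(x$relayed),
              x$contribution, sum(x$triggered), length(x$triggered),
              x$window[["lo"]] * 1000, x$window[["hi"]] * 1000))
  invisible(x)
}

#' Detect connection and label a pair in one step
#'
#' Convenience wrapper: computes the correlogram, detects the monosynaptic
#' window (recomputing a wider correlogram if the peak sits too close to the
#' edge for the baseline band) and labels relay status.
#'
#' @inheritParams cross_correlogram
#' @return a list with \code{correlogram}, \code{window}, \code{labels}
#'   (the latter two \code{NULL} when no connection is detected).
#' @export
analyze_connectivity <- function(pair, max_lag = 0.06, bin_width = 0.0001) {
  cg <- cross_correlogram(pair, max_lag = max_lag, bin_width = bin_width)
  win <- tryCatch(detect_window(cg), error = function(e) {
    cg <<- cross_correlogram(pair, max_lag = max_lag + 0.05, bin_width = bin_width)
    detect_window(cg)
  })
  labels <- if (!is.null(win)) label_relay(pair, win) else NULL
  list(correlogram = cg, window = win, labels = labels)
}
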