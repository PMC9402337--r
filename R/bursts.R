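#' Burst detection criteria
#'
#' Classic thalamic criteria: a burst must be preceded by at least 100 ms of
#' quiescence and contain two or more spikes each separated by no more than
#' 4 ms. The relaxed variant lowers the quiescence requirement to 50 ms and
#' raises the maximum intra-burst ISI to 6 ms, admitting more high-frequency
#' events. Both inequalities are inclusive.
#'
#' @param quiescence_ms minimum pre-burst silence, ms (> 0).
#' @param max_isi_ms maximum intra-burst ISI, ms (> 0).
#' @return an object of class \code{burst_criteria}.
#' @export
burst_criteria <- function(quiescence_ms = 100, max_isi_ms = 4) {
  if (quiescence_ms <= 0 || max_isi_ms <= 0) {
    stop("both criteria must be > 0")
  }
  structure(list(quiescence_ms = quiescence_ms, max_isi_ms = max_isi_ms),
            class = "burst_criteria")
}

#' @rdname burst_criteria
#' @export
classic_burst_criteria <- function() burst_criteria(100, 4)

#' @rdname burst_criteria
#' @export
relaxed_burst_criteria <- function() burst_criteria(50, 6)

#' Detect thalamic bursts in a spike train
#'
#' Spike i starts a burst iff it is preceded by at least the quiescence
#' duration of silence (the first spike of a recording qualifies when its
#' time is at least the quiescence duration, since nothing can have preceded
#' it) and the next ISI is at most the maximum intra-burst ISI. The burst
#' extends maximally while consecutive ISIs stay within the maximum. The
#' first spike of each burst is the "cardinal" spike; the rest are
#' noncardinal. Burst windows are evaluated independently, so a burst's
#' trailing spike may also satisfy the quiescence condition of a following
#' burst.
#'
#' @param train a \code{spike_train}.
#' @param crit a \code{burst_criteria} (default classic).
#' @return an object of class \code{burst_annotation}: \code{bursts} (list
#'   of integer index ranges into the train), \code{in_burst} and
#'   \code{is_cardinal} (logical per spike), \code{burst_fraction} (percent
#'   of spikes in bursts) and \code{noncardinal_fraction} (percent excluding
#'   cardinal spikes).
#' @export
detect_bursts <- function(train, crit = classic_burst_criteria()) {
  stopifnot(inherits(train, "spike_train"), inherits(crit, "burst_criteria"))
  t <- train$times
  n <- length(t)
  q <- crit$quiescence_ms / 1000
  mx <- crit$max_isi_ms / 1000
  in_burst <- logical(n)
  cardinal <- logical(n)
  bursts <- list()
  if (n >= 2L) {
    gap_ok <- c(t[1L] >= q, diff(t) >= q)
    i <- 1L
    while (i < n) {
      if (gap_ok[i] && (t[i + 1L] - t[i]) <= mx) {
        j <- i + 1L
        while (j < n && (t[j + 1L] - t[j]) <= mx) j <- j + 1L
        bursts[[length(bursts) + 1L]] <- c(start = i, end = j)
        in_burst[i:j] <- TRUE
        cardinal[i] <- TRUE
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  n_in <- sum(in_burst)
  structure(list(bursts = bursts, in_burst = in_burst, is_cardinal = cardinal,
                 burst_fraction = if (n) 100 * n_in / n else 0,
                 noncardinal_fraction = if (n) 100 * (n_in - length(bursts)) / n else 0,
                 criteria = crit),
            class = "burst_annotation")
}

#' @export
print.burst_annotation <- function(x, ...) {
  cat(sprintf("<burst_annotation: %d bursts, %.1f%% of spikes in bursts (%.1f%% noncardinal)>\n",
              length(x$bursts), x$burst_fraction, x$noncardinal_fraction))
  invisible(x)
}

#' Remove noncardinal burst spikes from the LGN train of a pair
#'
#' Deletes every burst spike except the cardinal (first) spike of each
#' burst; the retinal train is untouched. Relay labels must be recomputed
#' downstream on the returned pair.
#'
#' @param pair a \code{paired_recording}.
#' @param annotation a \code{burst_annotation} computed on \code{pair$lgn}.
#' @return a new \code{paired_recording} with the pruned LGN train.
#' @export
remove_noncardinal <- function(pair, annotation) {
  stopifnot(inherits(pair, "paired_recording"),
            inherits(annotation, "burst_annotation"))
  if (length(annotation$in_burst) != length(pair$lgn$times)) {
    stop("annotation does not match the pair's LGN train")
  }
  keep <- !annotation$in_burst | annotation$is_cardinal
  lgn <- spike_train(pair$lgn$times[keep], pair$lgn$duration, pair$lgn$unit_id)
  paired_recording(pair$pair_id, pair$rgc, lgn,
                   condition = pair$condition, state = pair$state)
}
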