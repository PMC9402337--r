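#' Spike train object
#'
#' A spike train is an ordered vector of spike times (seconds) for one unit,
#' together with the recording duration. Times must be strictly increasing
#' (duplicate times within one train are rejected: physiological
#' refractoriness makes them impossible at the resolutions used here) and lie
#' within \code{[0, duration]}.
#'
#' @param times numeric vector of spike times in seconds.
#' @param duration recording length in seconds (> 0).
#' @param unit_id text label for the unit.
#' @return an object of class \code{spike_train} with fields \code{unit_id},
#'   \code{times} and \code{duration}.
#' @export
spike_train <- function(times, duration, unit_id = "unit") {
  times <- as.numeric(times)
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0) {
    stop("duration must be a single positive finite number")
  }
  if (anyNA(times) || any(!is.finite(times))) {
    stop("spike times must be finite numbers")
  }
  if (length(times) > 1L) {
    d <- diff(times)
    bad <- which(d <= 0)
    if (length(bad)) {
      stop(sprintf(
        "spike times must be strictly increasing: violation at index %d (%.9f -> %.9f)",
        bad[1L] + 1L, times[bad[1L]], times[bad[1L] + 1L]))
    }
  }
  if (length(times) && (times[1L] < 0 || times[length(times)] > duration)) {
    idx <- if (times[1L] < 0) 1L else length(times)
    stop(sprintf("spike time out of [0, duration] at index %d: %.9f", idx, times[idx]))
  }
  structure(list(unit_id = as.character(unit_id)[1L],
                 times = times, duration = duration),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train '%s': %d spikes over %.3f s (%.2f spikes/s)>\n",
              x$unit_id, length(x$times), x$duration,
              length(x$times) / x$duration))
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

#' Paired RGC-LGN recording
#'
#' Bundles one retinal (or S-potential) spike train and one LGN spike train
#' recorded simultaneously on a shared clock. The unit of analysis for every
#' downstream operation.
#'
#' @param pair_id nonempty text identifier.
#' @param rgc,lgn \code{spike_train} objects sharing one duration.
#' @param condition stimulus condition: one of \code{"binary_noise"},
#'   \code{"grating"}, \code{"uncontrolled"}.
#' @param state recording state: \code{"anesthetized"} or \code{"awake"}.
#' @return an object of class \code{paired_recording}.
#' @export
paired_recording <- function(pair_id, rgc, lgn,
                             condition = c("binary_noise", "grating", "uncontrolled"),
                             state = c("anesthetized", "awake")) {
  condition <- match.arg(condition)
  state <- match.arg(state)
  if (!nzchar(pair_id)) stop("pair_id must be nonempty")
  stopifnot(inherits(rgc, "spike_train"), inherits(lgn, "spike_train"))
  if (!isTRUE(all.equal(rgc$duration, lgn$duration))) {
    stop("rgc and lgn trains must share one duration (one clock)")
  }
  structure(list(pair_id = as.character(pair_id)[1L], rgc = rgc, lgn = lgn,
                 condition = condition, state = state),
            class = "paired_recording")
}

#' @export
print.paired_recording <- function(x, ...) {
  cat(sprintf("<paired_recording '%s' [%s, %s]: %d RGC / %d LGN spikes, %.1f s>\n",
              x$pair_id, x$condition, x$state,
              length(x$rgc$times), length(x$lgn$times), x$rgc$duration))
  invisible(x)
}

#' Read spike times from a plain-text file
#'
#' One time per line, seconds; blank lines and lines starting with \code{#}
#' are ignored.
#'
#' @param path file path.
#' @param duration recording duration in seconds.
#' @param unit_id unit label (default: file name without extension).
#' @return a \code{spike_train}.
#' @export
read_spike_file <- function(path, duration, unit_id = NULL) {
  if (!file.exists(path)) stop(sprintf("spike file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  times <- suppressWarnings(as.numeric(lines))
  if (anyNA(times)) {
    stop(sprintf("non-numeric spike time in %s (line content '%s')",
                 path, lines[which(is.na(times))[1L]]))
  }
  if (is.null(unit_id)) unit_id <- sub("\\.[^.]*$", "", basename(path))
  spike_train(times, duration, unit_id)
}

#' Write spike times to a plain-text file
#'
#' @param train a \code{spike_train}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_spike_file <- function(train, path) {
  stopifnot(inherits(train, "spike_train"))
  # 9 decimal places: round-trips at nanosecond precision
  writeLines(sprintf("%.9f", train$times), path)
  invisible(path)
}

#' Read a pair from a manifest entry
#'
#' A manifest is a JSON array of records with fields \code{pair_id},
#' \code{rgc_file}, \code{lgn_file}, \code{duration_s}, \code{condition},
#' \code{state} and optional \code{spotential_shift_s}. File paths are
#' resolved relative to the manifest's directory when \code{base_dir} is set.
#' When \code{spotential_shift_s > 0} the RGC (S-potential) train is shifted
#' backwards by that amount before anything else (see
#' \code{\link{shift_spotentials}}).
#'
#' @param entry a named list (one manifest record).
#' @param base_dir directory against which relative paths are resolved.
#' @return a \code{paired_recording}.
#' @export
read_pair <- function(entry, base_dir = ".") {
  need <- c("pair_id", "rgc_file", "lgn_file", "duration_s", "condition", "state")
  miss <- setdiff(need, names(entry))
  if (length(miss)) stop("manifest entry missing fields: ", paste(miss, collapse = ", "))
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  dur <- as.numeric(entry$duration_s)
  rgc <- read_spike_file(resolve(entry$rgc_file), dur)
  lgn <- read_spike_file(resolve(entry$lgn_file), dur)
  shift <- entry$spotential_shift_s
  if (!is.null(shift) && as.numeric(shift) > 0) {
    rgc <- shift_spotentials(rgc, as.numeric(shift))
  }
  paired_recording(entry$pair_id, rgc, lgn,
                   condition = entry$condition, state = entry$state)
}

#' Read a full pair manifest
#'
#' @param manifest_path path to a JSON manifest (array of entries).
#' @return list of \code{paired_recording} objects.
#' @export
read_manifest <- function(manifest_path) {
  entries <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  lapply(entries, read_pair, base_dir = dirname(manifest_path))
}

#' Write a pair to spike files
#'
#' Writes \code{<pair_id>_rgc.txt} and \code{<pair_id>_lgn.txt} under
#' \code{dir} and returns the manifest entry describing them.
#'
#' @param pair a \code{paired_recording}.
#' @param dir output directory (created if needed).
#' @return the manifest entry (named list), invisibly.
#' @export
write_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "paired_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rf <- sprintf("%s_rgc.txt", pair$pair_id)
  lf <- sprintf("%s_lgn.txt", pair$pair_id)
  write_spike_file(pair$rgc, file.path(dir, rf))
  write_spike_file(pair$lgn, file.path(dir, lf))
  invisible(list(pair_id = pair$pair_id, rgc_file = rf, lgn_file = lf,
                 duration_s = pair$rgc$duration, condition = pair$condition,
                 state = pair$state, spotential_shift_s = 0))
}

#' Shift S-potential times backwards
#'
#' In awake recordings the retinal spike train is inferred from S-potentials
#' recorded within the LGN, so the apparent S-potential-to-LGN delay is much
#' shorter than a true retina-to-LGN conduction delay. Shifting S-potential
#' times backwards by 2.4 ms restores a median delay matching the
#' anesthetized retina-to-LGN median (2.8 ms), so that the same relay
#' labeling criteria apply to both datasets. Spikes shifted below time 0 are
#' dropped (not clamped) and the count is recorded in the result's
#' \code{n_dropped} attribute.
#'
#' @param train a \code{spike_train}.
#' @param shift_s nonnegative shift in seconds (default 0.0024).
#' @return the shifted \code{spike_train}; attribute \code{n_dropped} holds
#'   the number of spikes removed at the origin.
#' @export
shift_spotentials <- function(train, shift_s = 0.0024) {
  stopifnot(inherits(train, "spike_train"))
  if (!is.numeric(shift_s) || length(shift_s) != 1L || shift_s < 0) {
    stop("shift_s must be a single nonnegative number")
  }
  shifted <- train$times - shift_s
  keep <- shifted >= 0
  out <- spike_train(shifted[keep], train$duration, train$unit_id)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Bin a spike train into counts
#'
#' Half-open 1-ms (by default) bins \code{[t0 + j*w, t0 + (j+1)*w)};
#' spikes outside the span are ignored.
#'
#' @param train a \code{spike_train}.
#' @param bin_width bin width in seconds (default 0.001).
#' @param t0 left edge of the first bin, seconds.
#' @param n_bins number of bins (>= 1); default covers the full duration.
#' @return an object of class \code{binned_train} with fields
#'   \code{bin_width}, \code{counts}, \code{t0}.
#' @export
bin_train <- function(train, bin_width = 0.001, t0 = 0,
                      n_bins = ceiling((train$duration - t0) / bin_width)) {
  stopifnot(inherits(train, "spike_train"))
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (n_bins < 1L) stop("n_bins must be >= 1")
  idx <- floor((train$times - t0) / bin_width)
  idx <- idx[idx >= 0 & idx < n_bins]
  counts <- tabulate(idx + 1L, nbins = n_bins)
  structure(list(bin_width = bin_width, counts = counts, t0 = t0),
            class = "binned_train")
}
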