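#' Difference-of-exponentials filter
#'
#' The canonical ground-truth retinal filter shape: a fast positive lobe
#' (facilitation by recent retinal spikes) minus a slower negative lobe
#' (suppression by earlier activity), evaluated on the 1-ms lag grid.
#'
#' @param a,tau_fast_ms amplitude and time constant of the fast lobe.
#' @param b,tau_slow_ms amplitude and time constant of the slow lobe.
#' @param span_ms filter span in ms.
#' @return numeric filter of length \code{span_ms} (lags 1..span ms).
#' @export
doe_filter <- function(a = 3, tau_fast_ms = 5, b = 0.6, tau_slow_ms = 60,
                       span_ms = 100) {
  t <- seq_len(span_ms)
  a * exp(-t / tau_fast_ms) - b * exp(-t / tau_slow_ms)
}

#' Synthetic pair generator configuration
#'
#' Defines the study conditions a generated pair emulates: retinal rates of
#' roughly 10-60 spikes/s with optional 4-Hz sinusoidal modulation
#' (grating-like) or slow stochastic rate fluctuation, relay decisions drawn
#' from a ground-truth history GLM, mean efficacies spanning the observed
#' ~0.05-0.72 range (default 0.097, the binary-noise population median),
#' retinal contributions of ~0.14-1 (default 0.247, the corresponding
#' median), a relay delay of 2.8 ms (the anesthetized median) with 0.2 ms
#' truncated-Gaussian jitter, and optional thalamic burst injection.
#'
#' @param duration_s recording length, seconds.
#' @param rgc_rate_hz base retinal rate, spikes/s.
#' @param rate_mode \code{"homogeneous"}, \code{"grating_4hz"} or
#'   \code{"slow_fluctuation"}.
#' @param modulation_depth sinusoidal modulation depth in [0, 1]
#'   (grating mode) or log-rate SD (slow fluctuation mode, where 0.4 is a
#'   typical value).
#' @param refractory_ms absolute retinal refractory period, ms.
#' @param true_filter ground-truth retinal filter over 1-ms lags (numeric
#'   vector; default \code{doe_filter()}).
#' @param true_lgn_filter optional ground-truth LGN-history filter over 1-ms
#'   lags (positive early lobe mimics burst-linked facilitation; negative,
#'   gain-control-like).
#' @param target_efficacy desired mean relay efficacy in (0, 1).
#' @param target_contribution desired retinal contribution in (0, 1].
#' @param relay_delay_ms,jitter_ms monosynaptic delay and its jitter SD
#'   (Gaussian truncated at 3 SD).
#' @param burst_config NULL, or list(rate_hz, spikes_per_burst, intra_isi_ms,
#'   min_gap_ms) for burst injection into quiescent gaps.
#' @param two_regime NULL, or list(filter_high, count_threshold, window_ms)
#'   switching to \code{filter_high} when the LGN spike count in the
#'   preceding window reaches the threshold (activity-dependent integration).
#' @param seed integer seed (mandatory).
#' @return an object of class \code{generator_config}.
#' @export
generator_config <- function(duration_s = 200, rgc_rate_hz = 30,
                             rate_mode = c("homogeneous", "grating_4hz",
                                           "slow_fluctuation"),
                             modulation_depth = 0.5, refractory_ms = 2,
                             true_filter = doe_filter(),
                             true_lgn_filter = NULL,
                             target_efficacy = 0.097,
                             target_contribution = 0.247,
                             relay_delay_ms = 2.8, jitter_ms = 0.2,
                             burst_config = NULL, two_regime = NULL,
                             seed) {
  rate_mode <- match.arg(rate_mode)
  if (missing(seed)) stop("seed is mandatory")
  if (duration_s <= 0 || rgc_rate_hz <= 0) stop("rates and durations must be > 0")
  if (target_efficacy <= 0 || target_efficacy >= 1) {
    stop("target_efficacy must be in (0, 1)")
  }
  if (target_contribution <= 0 || target_contribution > 1) {
    stop("target_contribution must be in (0, 1]")
  }
  structure(list(duration_s = duration_s, rgc_rate_hz = rgc_rate_hz,
                 rate_mode = rate_mode, modulation_depth = modulation_depth,
                 refractory_ms = refractory_ms, true_filter = true_filter,
                 true_lgn_filter = true_lgn_filter,
                 target_efficacy = target_efficacy,
                 target_contribution = target_contribution,
                 relay_delay_ms = relay_delay_ms, jitter_ms = jitter_ms,
                 burst_config = burst_config, two_regime = two_regime,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a retinal spike train
#'
#' Inhomogeneous Poisson process by thinning with an absolute refractory
#' period. Grating mode uses rate \code{r0 (1 + m sin(2 pi 4 t))}; slow
#' fluctuation mode exponentiates an AR(1) process on a 10-ms grid with a
#' 50-ms correlation time (log-SD = \code{modulation_depth}), normalized so
#' the mean rate stays near \code{r0}. Deterministic per seed. A warning is
#' emitted if refractoriness truncates more than 20 percent of accepted
#' proposals.
#'
#' @param cfg a \code{generator_config}.
#' @param seed override the config seed.
#' @return a \code{spike_train}.
#' @export
generate_rgc <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  rs <- .seeded_rng(seed)
  r0 <- cfg$rgc_rate_hz
  dur <- cfg$duration_s
  if (cfg$rate_mode == "slow_fluctuation") {
    dt <- 0.01
    n_grid <- ceiling(dur / dt) + 1L
    phi <- exp(-dt / 0.05)  # 50 ms correlation time
    sd_lr <- cfg$modulation_depth
    z <- numeric(n_grid)
    eps <- rs$rnorm(n_grid, sd = sd_lr * sqrt(1 - phi^2))
    z[1L] <- rs$rnorm(1L, sd = sd_lr)
    for (i in 2:n_grid) z[i] <- phi * z[i - 1L] + eps[i]
    rate_at <- function(t) {
      r0 * exp(z[pmin(floor(t / dt) + 1L, n_grid)] - sd_lr^2 / 2)
    }
    rmax <- r0 * exp(max(z) - sd_lr^2 / 2)
  } else if (cfg$rate_mode == "grating_4hz") {
    m <- cfg$modulation_depth
    rate_at <- function(t) r0 * (1 + m * sin(2 * pi * 4 * t))
    rmax <- r0 * (1 + m)
  } else {
    rate_at <- function(t) rep(r0, length(t))
    rmax <- r0
  }
  n_prop <- rs$rpois(1L, rmax * dur)
  prop <- sort(rs$runif(n_prop)) * dur
  u <- rs$runif(n_prop)
  accept_rate <- u < rate_at(prop) / rmax
  cand <- prop[accept_rate]
  refr <- cfg$refractory_ms / 1000
  keep <- logical(length(cand))
  last <- -Inf
  for (i in seq_along(cand)) {
    if (cand[i] - last >= refr) {
      keep[i] <- TRUE
      last <- cand[i]
    }
  }
  if (length(cand) && mean(!keep) > 0.2) {
    warning(sprintf("refractory period truncated %.0f%% of proposals; rate may be unrealistic",
                    100 * mean(!keep)))
  }
  spike_train(cand[keep], dur, "rgc_synth")
}

# relay-probability linear predictor from retinal history (vector per spike)
.rh_drive <- function(times, theta_r) {
  span <- length(theta_r)
  tr <- .history_triplets(times, times, span)
  drive <- numeric(length(times))
  if (length(tr$i)) {
    agg <- rowsum(theta_r[tr$j], tr$i)
    drive[as.integer(rownames(agg))] <- agg[, 1L]
  }
  drive
}

#' Generate a synthetic RGC-LGN pair with known ground truth
#'
#' Draws the retinal train, simulates each spike's relay status from the
#' ground-truth history GLM (retinal filter, optional LGN filter, optional
#' activity-dependent two-regime switch), calibrating the intercept by
#' bisection on realized efficacy (common random numbers across bisection
#' steps; tolerance 0.01, at most 40 iterations). Relayed spikes produce LGN
#' spikes at the retinal time plus the relay delay plus truncated Gaussian
#' jitter; non-triggered LGN spikes are added as an independent homogeneous
#' Poisson process sized to the target contribution; optional bursts are
#' injected into quiescent gaps. Duplicate LGN times are jittered apart by
#' 0.1 ms.
#'
#' @param cfg a \code{generator_config}.
#' @return list with \code{pair} (a \code{paired_recording}) and
#'   \code{truth} (class \code{synthetic_ground_truth}: \code{theta_r_true},
#'   \code{theta_l_true}, \code{intercept}, \code{relayed} (true status per
#'   retinal spike), \code{achieved_efficacy}, \code{achieved_contribution},
#'   \code{injected_burst_count}, \code{seed}).
#' @export
generate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  rgc <- generate_rgc(cfg)
  times <- rgc$times
  n <- length(times)
  if (n < 10L) stop("generated retinal train too short; increase duration or rate")
  rs <- .seeded_rng(cfg$seed + 1L)
  u <- rs$runif(n)  # common random numbers for the bisection
  drive_r <- .rh_drive(times, cfg$true_filter)
  drive_r_hi <- if (!is.null(cfg$two_regime)) {
    .rh_drive(times, cfg$two_regime$filter_high)
  } else NULL

  sequential <- !is.null(cfg$true_lgn_filter) || !is.null(cfg$two_regime)
  delay <- cfg$relay_delay_ms / 1000
  jit <- pmin(pmax(rs$rnorm(n, sd = cfg$jitter_ms / 1000),
                   -3 * cfg$jitter_ms / 1000), 3 * cfg$jitter_ms / 1000)

  # background (non-triggered) LGN spikes, sized from the targets
  exp_relayed <- max(1, round(cfg$target_efficacy * n))
  n_bg <- round(exp_relayed * (1 / cfg$target_contribution - 1))
  bg <- sort(rs$runif(n_bg)) * cfg$duration_s

  realize <- function(intercept) {
    if (!sequential) {
      relayed <- u < stats::plogis(drive_r + intercept)
      return(list(relayed = relayed))
    }
    theta_l <- cfg$true_lgn_filter
    span_l <- length(theta_l)
    trig <- numeric(n)
    n_trig <- 0L
    relayed <- logical(n)
    tw <- if (!is.null(cfg$two_regime)) cfg$two_regime$window_ms / 1000 else NULL
    for (j in seq_len(n)) {
      t <- times[j]
      dr <- drive_r[j]
      if (!is.null(cfg$two_regime)) {
        cnt <- (findInterval(t - 1e-12, bg) -
                  findInterval(t - tw, bg)) +
          (findInterval(t - 1e-12, trig[seq_len(n_trig)]) -
             findInterval(t - tw, trig[seq_len(n_trig)]))
        if (cnt >= cfg$two_regime$count_threshold) dr <- drive_r_hi[j]
      }
      dl <- 0
      if (!is.null(theta_l)) {
        for (src in list(bg, trig[seq_len(n_trig)])) {
          a <- findInterval(t - span_l / 1000, src) + 1L
          b <- findInterval(t - 1e-12, src)
          if (b >= a) {
            lag_bins <- ceiling((t - src[a:b]) * 1000 - 1e-9)
            lag_bins <- lag_bins[lag_bins >= 1 & lag_bins <= span_l]
            dl <- dl + sum(theta_l[lag_bins])
          }
        }
      }
      if (u[j] < stats::plogis(dr + dl + intercept)) {
        relayed[j] <- TRUE
        n_trig <- n_trig + 1L
        trig[n_trig] <- t + delay + jit[j]
      }
    }
    list(relayed = relayed)
  }

  eff_at <- function(c0) mean(realize(c0)$relayed)
  lo <- -20; hi <- 20
  if (eff_at(lo) > cfg$target_efficacy || eff_at(hi) < cfg$target_efficacy) {
    stop(sprintf("intercept calibration cannot bracket target efficacy %.3f (range [%.3f, %.3f])",
                 cfg$target_efficacy, eff_at(lo), eff_at(hi)))
  }
  intercept <- NA_real_
  for (it in seq_len(40L)) {
    mid <- (lo + hi) / 2
    e <- eff_at(mid)
    if (abs(e - cfg$target_efficacy) <= 0.01) { intercept <- mid; break }
    if (e < cfg$target_efficacy) lo <- mid else hi <- mid
  }
  if (is.na(intercept)) intercept <- (lo + hi) / 2
  relayed <- realize(intercept)$relayed

  trig_times <- times[relayed] + delay + jit[relayed]
  lgn_times <- sort(c(bg, trig_times))
  lgn_times <- lgn_times[lgn_times > 0 & lgn_times <= cfg$duration_s]
  # separate coincident spikes by 0.1 ms
  while (any(diff(lgn_times) <= 0)) {
    k <- which(diff(lgn_times) <= 0)[1L] + 1L
    lgn_times[k] <- lgn_times[k - 1L] + 1e-4
    lgn_times <- sort(lgn_times)
  }

  injected <- 0L
  if (!is.null(cfg$burst_config)) {
    bc <- cfg$burst_config
    intra <- (bc$intra_isi_ms %||% 3) / 1000
    nsp <- bc$spikes_per_burst %||% 3
    min_gap <- (bc$min_gap_ms %||% 120) / 1000
    burst_len <- (nsp - 1) * intra
    n_bursts <- rs$rpois(1L, bc$rate_hz * cfg$duration_s)
    gaps <- which(diff(lgn_times) >= min_gap + burst_len + 0.005)
    if (length(gaps) && n_bursts > 0) {
      pick <- gaps[rs$sample(length(gaps), size = min(n_bursts, length(gaps)))]
      new_spikes <- unlist(lapply(lgn_times[pick], function(g0) {
        g0 + min_gap + (seq_len(nsp) - 1L) * intra
      }))
      lgn_times <- sort(c(lgn_times, new_spikes))
      injected <- length(pick)
    }
  }

  pair <- paired_recording(
    sprintf("synth_%d", cfg$seed), rgc,
    spike_train(lgn_times, cfg$duration_s, "lgn_synth"),
    condition = switch(cfg$rate_mode, grating_4hz = "grating",
                       slow_fluctuation = "binary_noise", "uncontrolled"),
    state = "anesthetized")
  truth <- structure(list(
    theta_r_true = cfg$true_filter, theta_l_true = cfg$true_lgn_filter,
    intercept = intercept, relayed = relayed,
    achieved_efficacy = mean(relayed),
    achieved_contribution = length(trig_times) / length(lgn_times),
    injected_burst_count = injected, seed = cfg$seed),
    class = "synthetic_ground_truth")
  list(pair = pair, truth = truth)
}

#' Generate a cohort of synthetic pairs on disk
#'
#' Writes per-pair spike files, a JSON manifest readable by
#' \code{\link{read_manifest}}, and a ground-truth JSON. Per-pair seeds are
#' derived deterministically from the master seed, so the same master seed
#' reproduces the cohort byte for byte.
#'
#' @param n_pairs number of pairs (>= 1).
#' @param out_dir output directory.
#' @param seed master seed.
#' @param efficacy_range range from which per-pair target efficacies are
#'   drawn uniformly (default [0.05, 0.3]).
#' @param contribution_range analogous for contributions.
#' @param cfg_base a \code{generator_config} supplying all other settings.
#' @return path to the manifest, invisibly; ground truths as attribute
#'   \code{truths}.
#' @export
generate_cohort <- function(n_pairs, out_dir, seed,
                            efficacy_range = c(0.05, 0.3),
                            contribution_range = c(0.2, 0.8),
                            cfg_base = generator_config(seed = seed)) {
  if (n_pairs < 1L) stop("n_pairs must be >= 1")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rs <- .seeded_rng(seed)
  effs <- efficacy_range[1L] + rs$runif(n_pairs) * diff(efficacy_range)
  cons <- contribution_range[1L] + rs$runif(n_pairs) * diff(contribution_range)
  entries <- vector("list", n_pairs)
  truths <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    cfg <- cfg_base
    cfg$seed <- as.integer(seed + i * 101L)
    cfg$target_efficacy <- effs[i]
    cfg$target_contribution <- cons[i]
    gp <- generate_pair(cfg)
    gp$pair$pair_id <- sprintf("pair_%03d", i)
    gp$pair$rgc$unit_id <- sprintf("pair_%03d_rgc", i)
    gp$pair$lgn$unit_id <- sprintf("pair_%03d_lgn", i)
    entries[[i]] <- write_pair(gp$pair, out_dir)
    truths[[i]] <- gp$truth
  }
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, digits = NA)
  gt <- lapply(truths, function(tr) {
    list(intercept = tr$intercept, achieved_efficacy = tr$achieved_efficacy,
         achieved_contribution = tr$achieved_contribution,
         injected_burst_count = tr$injected_burst_count, seed = tr$seed)
  })
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  out <- manifest
  attr(out, "truths") <- truths
  invisible(out)
}
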