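#' Bernoulli log-likelihood
#'
#' \code{sum(y * log(lambda) + (1 - y) * log(1 - lambda))}, in nats.
#' Probabilities are clipped to \code{[1e-12, 1 - 1e-12]} before the logs.
#'
#' @param lambda predicted probabilities.
#' @param y binary outcomes (0/1 or logical), same length.
#' @return scalar log-likelihood in nats.
#' @export
bernoulli_ll <- function(lambda, y) {
  if (length(lambda) != length(y)) stop("lambda and y must have equal length")
  lam <- pmin(pmax(lambda, 1e-12), 1 - 1e-12)
  y <- as.numeric(y)
  sum(y * log(lam) + (1 - y) * log(1 - lam))
}

#' Cross-validated single-event Bernoulli information
#'
#' The per-spike log-likelihood gain, in bits, of a model's predicted relay
#' probabilities over a homogeneous Bernoulli model that predicts the
#' test-set mean efficacy for every spike:
#' \deqn{I = (L(\lambda; y) - L(\bar\lambda; y)) / (n \log 2).}
#' Zero means no better than the homogeneous model; a perfect model attains
#' the binary entropy of the test-set mean efficacy (e.g., 0.286 bits/spike
#' at efficacy 0.05); negative values indicate a model that generalizes
#' worse than the homogeneous reference.
#'
#' @param lambda_pred predicted relay probabilities for the test spikes.
#' @param y_test observed relay status (0/1 or logical).
#' @param reference optional homogeneous reference probability; defaults to
#'   \code{mean(y_test)} (clipped into (0,1) if degenerate).
#' @return bits/spike (scalar).
#' @export
i_bernoulli <- function(lambda_pred, y_test, reference = NULL) {
  if (!length(y_test)) stop("empty test set")
  y <- as.numeric(y_test)
  lam_bar <- reference %||% mean(y)
  lam_bar <- min(max(lam_bar, 1e-12), 1 - 1e-12)
  (bernoulli_ll(lambda_pred, y) - bernoulli_ll(rep(lam_bar, length(y)), y)) /
    (length(y) * log(2))
}

#' Balanced stratified fold assignment
#'
#' Relayed and nonrelayed spikes are shuffled independently (seeded) and
#' dealt round-robin across folds, so every test fold contains approximately
#' the same number of relayed spikes (per-class fold counts differ by at
#' most 1). This balancing stabilizes the information metric for pairs with
#' low mean efficacy.
#'
#' @param y relay status per spike (logical or 0/1).
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return integer vector of fold ids (1..n_folds), one per spike.
#' @export
make_folds <- function(y, n_folds = 10L, seed = 1L) {
  y <- as.logical(y)
  if (sum(y) < n_folds || sum(!y) < n_folds) {
    stop(sprintf("need at least %d spikes of each class for %d folds",
                 n_folds, n_folds))
  }
  fold <- integer(length(y))
  rs <- .seeded_rng(seed)
  for (cls in c(TRUE, FALSE)) {
    idx <- which(y == cls)
    idx <- idx[rs$sample(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# small seeded RNG sandbox so package functions never disturb the caller's
# random state
.seeded_rng <- function(seed) {
  env <- new.env()
  local_seed <- function(expr_fun) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv())) {
              rm(".Random.seed", envir = globalenv())
            })
    if (is.null(env$state)) {
      set.seed(seed)
    } else {
      assign(".Random.seed", env$state, envir = globalenv())
    }
    res <- expr_fun()
    env$state <- get(".Random.seed", envir = globalenv())
    res
  }
  list(
    sample = function(n, size = n, replace = FALSE) {
      local_seed(function() sample.int(n, size = size, replace = replace))
    },
    runif = function(n) local_seed(function() stats::runif(n)),
    rnorm = function(n, mean = 0, sd = 1) {
      local_seed(function() stats::rnorm(n, mean, sd))
    },
    rbinom = function(n, size, prob) {
      local_seed(function() stats::rbinom(n, size, prob))
    },
    rpois = function(n, lambda) local_seed(function() stats::rpois(n, lambda)),
    rexp = function(n, rate = 1) local_seed(function() stats::rexp(n, rate))
  )
}

#' Default hyperparameter grids
#'
#' The predefined per-pair search sets: \code{isi_max} — eight log10-spaced
#' values in [0.03, 0.5] s; \code{isi_sigma} — seven log10-spaced values in
#' [0.002, 0.03] s plus 0 (no smoothing); \code{rh_span_ms} — the
#' \code{isi_max} values rounded to the nearest ms; \code{rh_eta} — five
#' log2-spaced values in [4, 4096]; \code{ch_span_l_ms} — eight log10-spaced
#' values in [0.04, 0.6] s rounded to ms; \code{ch_n_l} — {8, 12, 18, 24,
#' 32}; \code{ch_eta} — five log2-spaced values in [0.125, 8] (used for both
#' components). Endpoints are members of each set. The basis warp constants
#' are fixed (10 retinal, 8 LGN) and the retinal basis count is fixed at 16.
#'
#' @return named list of numeric vectors.
#' @export
default_grids <- function() {
  isi_max <- 10^seq(log10(0.03), log10(0.5), length.out = 8)
  list(
    isi_max = isi_max,
    isi_sigma = c(0, 10^seq(log10(0.002), log10(0.03), length.out = 7)),
    rh_span_ms = round(isi_max * 1000),
    rh_eta = 2^seq(log2(4), log2(4096), length.out = 5),
    ch_span_l_ms = round(10^seq(log10(0.04), log10(0.6), length.out = 8) * 1000),
    ch_n_l = c(8, 12, 18, 24, 32),
    ch_eta = 2^seq(log2(0.125), log2(8), length.out = 5)
  )
}

# candidate hyperparameter tables per model kind; ties in selection are
# broken toward the smaller span, then the larger penalty (parsimony)
.grid_table <- function(model, grid, span_r_ms = NULL) {
  switch(model,
    isi = expand.grid(isi_max = grid$isi_max, isi_sigma = grid$isi_sigma),
    rh_time = ,
    rh_cosine = expand.grid(span_r_ms = grid$rh_span_ms, eta_r = grid$rh_eta),
    ch = {
      if (is.null(span_r_ms)) stop("ch models require span_r_ms (fixed from RH fitting)")
      expand.grid(span_l_ms = grid$ch_span_l_ms, n_l = grid$ch_n_l,
                  eta_r = grid$ch_eta, eta_l = grid$ch_eta)
    },
    stop("unknown model kind: ", model))
}

.tie_break_order <- function(model, tab) {
  spans <- switch(model,
    isi = tab$isi_max,
    rh_time = ,
    rh_cosine = tab$span_r_ms,
    ch = tab$span_l_ms)
  pen <- switch(model,
    isi = tab$isi_sigma,
    rh_time = ,
    rh_cosine = tab$eta_r,
    ch = tab$eta_r + tab$eta_l)
  order(spans, -pen)
}

# fit the given model on (isi, y) / design data restricted to 'train' and
# return predictions for 'test'; shared by the outer and nested CV loops.
# 'ctx' carries precomputed per-spike covariates for the whole pair.
.fit_and_predict <- function(model, hp, ctx, train, test) {
  if (model == "isi") {
    fun <- build_isi_function(ctx$isi[train], ctx$y[train],
                              isi_max = hp$isi_max, sigma = hp$isi_sigma)
    fun <- calibrate_isi(fun, ctx$isi[train], ctx$y[train])
    predict_isi(fun, ctx$isi[test], mean(ctx$y[test]))
  } else {
    spec <- if (model == "ch") {
      glm_spec("ch", span_r_ms = ctx$span_r_ms, eta_r = hp$eta_r,
               span_l_ms = hp$span_l_ms, n_l = hp$n_l, eta_l = hp$eta_l)
    } else {
      glm_spec(model, span_r_ms = hp$span_r_ms, eta_r = hp$eta_r)
    }
    key <- paste(spec$kind, spec$span_r_ms, spec$span_l_ms %||% 0,
                 spec$n_l %||% 0, sep = "_")
    des <- ctx$design_cache[[key]]
    if (is.null(des)) {
      des <- build_design(ctx$pair, ctx$y_all, spec)
      ctx$design_cache[[key]] <- des
    }
    des$spec <- spec  # same design, possibly different penalty weights
    # map retinal-train spike indices to design rows (all train/test spikes
    # are eligible for every span in the grid by construction)
    tr_rows <- match(train, des$spike_index); tr_rows <- tr_rows[!is.na(tr_rows)]
    te_rows <- match(test, des$spike_index); te_rows <- te_rows[!is.na(te_rows)]
    sub <- des
    sub$X <- des$X[tr_rows, , drop = FALSE]
    sub$y <- des$y[tr_rows]
    fit <- fit_map(sub, on_nonconvergence = "warn")
    lam <- 1 / (1 + exp(-as.numeric(des$X[te_rows, , drop = FALSE] %*% fit$theta)))
    lam
  }
}

#' Cross-validated model performance with nested hyperparameter search
#'
#' Scores one model on one pair with train-on-90% / test-on-10% 10-fold
#' cross-validation. Within each outer training set a nested 10-subfold
#' search over the hyperparameter grid selects the combination maximizing
#' the mean subfold information; the model is then refit on the full outer
#' training set with those hyperparameters and scored on the held-out fold.
#' Overall performance is the arithmetic mean of the per-fold information
#' values. Deterministic given \code{seed}. Spikes without an eligible
#' design row (GLM targets earlier than one span into the recording) are
#' scored only by models that can predict them; fold assignment covers all
#' spikes with an ISI (GLM rows are the subset that exists for each span).
#'
#' @param model one of \code{"isi"}, \code{"rh_time"}, \code{"rh_cosine"},
#'   \code{"ch"}.
#' @param pair a \code{paired_recording}.
#' @param labels a \code{relay_labels} (or logical relay status vector).
#' @param grid hyperparameter grid (see \code{\link{default_grids}}); may be
#'   a reduced named list for speed.
#' @param seed integer seed for fold assignment.
#' @param n_folds,n_subfolds outer and nested fold counts (default 10).
#' @param span_r_ms for \code{ch} models: the retinal span fixed from RH
#'   model fitting.
#' @param nested set \code{FALSE} to skip the nested search when the grid
#'   has a single row.
#' @return an object of class \code{cv_result}: \code{per_fold_info},
#'   \code{mean_info}, \code{chosen_hyperparams} (data frame, one row per
#'   fold), \code{model_kind}, \code{partial} (TRUE if any fold failed).
#' @export
cross_validate <- function(model = c("isi", "rh_time", "rh_cosine", "ch"),
                           pair, labels, grid = default_grids(), seed = 1L,
                           n_folds = 10L, n_subfolds = 10L,
                           span_r_ms = NULL, nested = TRUE) {
  model <- match.arg(model)
  y_all <- if (inherits(labels, "relay_labels")) labels$relayed else as.logical(labels)
  isi <- preceding_isi(pair$rgc)

  # eligibility: GLM rows exist only for spikes >= max span into the recording;
  # restrict scoring to spikes eligible under the largest span in the grid so
  # every hyperparameter choice sees the same spikes
  max_span_ms <- switch(model,
    isi = 0,
    rh_time = ,
    rh_cosine = max(grid$rh_span_ms),
    ch = max(max(grid$ch_span_l_ms), span_r_ms %||% stop("ch requires span_r_ms")))
  eligible <- which(pair$rgc$times >= max_span_ms / 1000 & !is.na(isi))
  y <- y_all[eligible]
  fold <- make_folds(y, n_folds = n_folds, seed = seed)

  ctx <- new.env()
  ctx$pair <- pair
  ctx$y_all <- y_all
  ctx$y <- y_all
  ctx$isi <- isi
  ctx$span_r_ms <- span_r_ms
  ctx$design_cache <- new.env()

  tab <- .grid_table(model, grid, span_r_ms)
  pref <- .tie_break_order(model, tab)

  per_fold <- numeric(n_folds)
  chosen <- vector("list", n_folds)
  failed <- logical(n_folds)
  for (f in seq_len(n_folds)) {
    test_idx <- eligible[fold == f]
    train_idx <- eligible[fold != f]
    hp <- tab[1L, , drop = FALSE]
    if (nested && nrow(tab) > 1L) {
      sub_fold <- make_folds(y_all[train_idx], n_folds = n_subfolds,
                             seed = seed + 1000L * f)
      score <- matrix(NA_real_, nrow(tab), n_subfolds)
      for (sf in seq_len(n_subfolds)) {
        ste <- train_idx[sub_fold == sf]
        str <- train_idx[sub_fold != sf]
        for (g in seq_len(nrow(tab))) {
          lam <- tryCatch(
            .fit_and_predict(model, tab[g, , drop = FALSE], ctx, str, ste),
            error = function(e) NULL)
          if (!is.null(lam)) score[g, sf] <- i_bernoulli(lam, y_all[ste])
        }
      }
      mean_score <- rowMeans(score, na.rm = TRUE)
      if (all(!is.finite(mean_score))) {
        best <- 1L
      } else {
        best <- pref[which.max(mean_score[pref])]
      }
      hp <- tab[best, , drop = FALSE]
    }
    lam <- tryCatch(.fit_and_predict(model, hp, ctx, train_idx, test_idx),
                    error = function(e) NULL)
    if (is.null(lam)) {
      failed[f] <- TRUE
      per_fold[f] <- NA_real_
    } else {
      per_fold[f] <- i_bernoulli(lam, y_all[test_idx])
    }
    chosen[[f]] <- hp
  }
  structure(list(per_fold_info = per_fold,
                 mean_info = mean(per_fold, na.rm = any(failed)),
                 chosen_hyperparams = do.call(rbind, chosen),
                 model_kind = model, seed = seed,
                 partial = any(failed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result [%s]: mean I_Bernoulli %.4f bits/spike over %d folds%s>\n",
              x$model_kind, x$mean_info, length(x$per_fold_info),
              if (x$partial) " (partial: some folds failed)" else ""))
  invisible(x)
}

#' Calibration curve of predicted vs observed efficacy
#'
#' Groups spikes into bins of normalized predicted efficacy (prediction
#' divided by the pair's mean efficacy) and reports, per bin, the observed
#' efficacy normalized the same way. A perfectly calibrated model lies on
#' the identity line.
#'
#' @param lambda_pred per-spike predicted relay probabilities.
#' @param y observed relay status.
#' @param n_bins number of prediction bins (default 10, equal-count).
#' @return data frame with columns \code{predicted} (bin mean of normalized
#'   prediction), \code{observed} (normalized observed efficacy),
#'   \code{n} (spikes per bin), \code{mad} (MAD of normalized predictions in
#'   the bin). Empty bins are dropped.
#' @export
calibration_curve <- function(lambda_pred, y, n_bins = 10L) {
  y <- as.numeric(y)
  mean_eff <- mean(y)
  if (mean_eff <= 0 || mean_eff >= 1) stop("degenerate mean efficacy")
  norm_pred <- lambda_pred / mean_eff
  if (stats::var(norm_pred) < 1e-20) {
    return(data.frame(predicted = mean(norm_pred),
                      observed = mean(y) / mean_eff,
                      n = length(y), mad = 0))
  }
  qs <- unique(stats::quantile(norm_pred, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(norm_pred, breaks = qs, include.lowest = TRUE)
  keep <- !is.na(bin)
  agg <- split(seq_along(norm_pred)[keep], bin[keep], drop = TRUE)
  out <- do.call(rbind, lapply(agg, function(ii) {
    data.frame(predicted = mean(norm_pred[ii]),
               observed = mean(y[ii]) / mean_eff,
               n = length(ii),
               mad = mad_stat(norm_pred[ii]))
  }))
  rownames(out) <- NULL
  out
}

#' Information difference between two models as a function of ISI
#'
#' For each ISI bin, the difference in per-spike Bernoulli information
#' between two prediction sets scored on identical spikes. Both per-bin
#' information values use the same homogeneous reference (the full test-set
#' mean efficacy), so bin values weighted by bin counts sum to the overall
#' information difference.
#'
#' @param lambda_a,lambda_b predictions from models A and B on the same
#'   spikes.
#' @param y observed relay status.
#' @param isi preceding ISI per spike (seconds).
#' @param isi_breaks bin edges in seconds (half-open \code{[lo, hi)}).
#' @return data frame with \code{isi_lo}, \code{isi_hi}, \code{n},
#'   \code{delta_info} (A minus B, bits/spike) and \code{flagged}
#'   (TRUE for bins with fewer than 10 spikes).
#' @export
info_by_isi <- function(lambda_a, lambda_b, y, isi,
                        isi_breaks = c(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5, Inf)) {
  stopifnot(length(lambda_a) == length(y), length(lambda_b) == length(y),
            length(isi) == length(y))
  y <- as.numeric(y)
  ref <- mean(y)
  bin <- findInterval(isi, isi_breaks, left.open = FALSE)
  out <- lapply(seq_len(length(isi_breaks) - 1L), function(b) {
    ii <- which(bin == b & !is.na(isi))
    if (!length(ii)) return(NULL)
    di <- i_bernoulli(lambda_a[ii], y[ii], reference = ref) -
      i_bernoulli(lambda_b[ii], y[ii], reference = ref)
    data.frame(isi_lo = isi_breaks[b], isi_hi = isi_breaks[b + 1L],
               n = length(ii), delta_info = di, flagged = length(ii) < 10L)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
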