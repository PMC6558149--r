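# Multi-lag curve parameterisation: 21 features per (channel, metric) curve.

curve_values <- function(curve, taus_needed, call = rlang::caller_env()) {
  if (!is.data.frame(curve) || !all(c("tau", "value") %in% names(curve))) {
    abort("`curve` must be a data frame with columns `tau` and `value`.", call = call)
  }
  missing <- setdiff(taus_needed, curve$tau)
  if (length(missing) > 0) {
    abort(
      sprintf("Curve does not cover required lags: missing tau = %s.",
              paste(missing, collapse = ", ")),
      call = call
    )
  }
  curve$value[match(taus_needed, curve$tau)]
}

#' Slope of a multi-lag entropy curve
#'
#' Slope of the straight line connecting the entropy at lag 1 to the entropy
#' at `tau_end`: `(E[tau_end] - E[1]) / (tau_end - 1)`, in entropy units per
#' lag. Positive values mean entropy grows with the embedding delay.
#'
#' @param curve Data frame with columns `tau` and `value` (one metric, one
#'   channel), covering at least lags 1 and `tau_end`.
#' @param tau_end Final lag of the segment, integer >= 2 present in `curve`.
#' @return A single numeric value.
#' @examples
#' curve <- data.frame(tau = 1:4, value = c(0.5, 0.6, 0.7, 0.8))
#' curve_slope(curve, 4)
#' @export
curve_slope <- function(curve, tau_end) {
  if (tau_end < 2) abort("`tau_end` must be >= 2.")
  e <- curve_values(curve, c(1L, as.integer(tau_end)))
  (e[2L] - e[1L]) / (tau_end - 1)
}

#' Area under a multi-lag entropy curve
#'
#' Composite trapezoidal area under the piecewise-linear curve through the
#' observed points, from lag 1 to `tau_end`, with the lag axis taken as
#' unit-spaced. Requires the curve to cover every integer lag in
#' `1..tau_end`.
#'
#' @inheritParams curve_slope
#' @return A single numeric value (entropy x lag units).
#' @examples
#' curve_area(data.frame(tau = 1:3, value = c(0.5, 0.7, 0.9)), 3)  # 1.4
#' @export
curve_area <- function(curve, tau_end) {
  if (tau_end < 2) abort("`tau_end` must be >= 2.")
  e <- curve_values(curve, seq_len(as.integer(tau_end)))
  sum((e[-1L] + e[-length(e)]) / 2)
}

#' Arc length of a multi-lag entropy curve
#'
#' `sum_{tau = 2..tau_max} sqrt(1 + (E[tau] - E[tau - 1])^2)`: the length of
#' the polyline through the entropy values with unit lag steps and
#' unnormalised entropy differences. With `tau_max = 10` this is nine terms,
#' so the value is always >= 9, with equality exactly when the curve is flat.
#'
#' @param curve Data frame with columns `tau` and `value` covering
#'   `1..tau_max`.
#' @param tau_max Last lag of the curve (default 10).
#' @return A single numeric value, at least `tau_max - 1`.
#' @export
curve_arc_length <- function(curve, tau_max = 10) {
  if (tau_max < 2) abort("`tau_max` must be >= 2.")
  e <- curve_values(curve, seq_len(as.integer(tau_max)))
  sum(sqrt(1 + diff(e)^2))
}

#' The 21 scalar features of one multi-lag entropy curve
#'
#' Parameterises a curve over lags `1..tau_max` into: the single-lag entropy
#' at every lag (`tau1..tau10`), the slopes `Slp1-2, Slp1-4, ..., Slp1-10`
#' from lag 1 to each even lag, the trapezoidal areas `Ar1-2, ..., Ar1-10`
#' over the same segments, and the arc length `AL` — 21 features for the
#' default `tau_max = 10`.
#'
#' @inheritParams curve_arc_length
#' @param segment_ends Final lags for slopes and areas (default
#'   `c(2, 4, 6, 8, 10)`).
#' @return A one-row tibble with named feature columns (`tau1`, ...,
#'   `Slp1-2`, ..., `Ar1-2`, ..., `AL`).
#' @export
curve_features <- function(curve, tau_max = 10, segment_ends = c(2, 4, 6, 8, 10)) {
  taus <- seq_len(as.integer(tau_max))
  e <- curve_values(curve, taus)
  cv <- data.frame(tau = taus, value = e)
  single <- rlang::set_names(as.list(e), paste0("tau", taus))
  slopes <- rlang::set_names(
    lapply(segment_ends, function(t2) curve_slope(cv, t2)),
    paste0("Slp1-", segment_ends)
  )
  areas <- rlang::set_names(
    lapply(segment_ends, function(t2) curve_area(cv, t2)),
    paste0("Ar1-", segment_ends)
  )
  tibble::as_tibble(c(single, slopes, areas, list(AL = curve_arc_length(cv, tau_max))))
}

#' Feature row for one trial from its entropy curves
#'
#' Turns the per-channel, per-metric entropy curves of a single trial into one
#' wide row of named features, `21 * 2 * n_channels` columns for the default
#' lags and both metrics. Column names follow `channel/metric/feature`, e.g.
#' `P3/PME/Slp1-4`, and are stable across runs.
#'
#' @param curves Tibble with columns `channel`, `metric`, `tau`, `value`
#'   (output of [trial_entropy_curves()]), each (channel, metric) curve
#'   complete over `1..tau_max`.
#' @inheritParams curve_features
#' @return A one-row tibble.
#' @export
featurize_curves <- function(curves, tau_max = 10, segment_ends = c(2, 4, 6, 8, 10)) {
  if (!all(c("channel", "metric", "tau", "value") %in% names(curves))) {
    abort("`curves` needs columns channel, metric, tau, value.")
  }
  groups <- dplyr::group_split(dplyr::group_by(curves, .data$channel, .data$metric))
  cols <- purrr::map(groups, function(g) {
    feats <- curve_features(g, tau_max = tau_max, segment_ends = segment_ends)
    rlang::set_names(
      feats,
      paste(g$channel[1L], g$metric[1L], names(feats), sep = "/")
    )
  })
  dplyr::bind_cols(cols)
}

#' Multi-lag entropy curves for every channel of a trial
#'
#' @param trial An [eeg_trial()] or a channels x samples numeric matrix with
#'   rownames as channel labels.
#' @inheritParams entropy_curve
#' @return Tibble with columns `channel`, `metric`, `tau`, `value`.
#' @export
trial_entropy_curves <- function(trial, m = 6, taus = 1:10,
                                 metrics = c("DPE", "PME"), K = 0.5) {
  sig <- if (inherits(trial, "eeg_trial")) trial$signal else trial
  if (!is.matrix(sig)) abort("`trial` must be an eeg_trial or a numeric matrix.")
  labels <- rownames(sig)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(sig)))
  purrr::map_dfr(seq_len(nrow(sig)), function(i) {
    dplyr::mutate(
      entropy_curve(sig[i, ], m = m, taus = taus, metrics = metrics, K = K),
      channel = labels[i], .before = 1L
    )
  })
}

# Plain-numeric fast path used by featurize_trials: per-channel DPE/PME
# curves and their 21 features with no intermediate data frames. Must agree
# with entropy_curve() + curve_features() exactly (tested).
fast_channel_curves <- function(x, m, taus, K) {
  fm <- factorial(m)
  ln_fm <- log(fm)
  dpe <- pme <- numeric(length(taus))
  for (i in seq_along(taus)) {
    emb <- embed_ordinal(x, m, taus[i])
    w <- K * emb$aa + (1 - K) * emb$ra
    tot <- sum(w)
    if (tot <= 0) abort("Degenerate input: total amplitude weight is zero.")
    p <- rowsum(w, emb$ids)[, 1L] / tot
    dpe[i] <- -sum(p * log(p)) / ln_fm
    counts <- tabulate(emb$ids, nbins = fm)
    pme[i] <- -log(max(counts) / emb$n) / ln_fm
  }
  list(DPE = dpe, PME = pme)
}

fast_curve_features <- function(e, taus, segment_ends) {
  tau_max <- max(taus)
  vals <- c(e,
            (e[segment_ends] - e[1L]) / (segment_ends - 1),
            cumsum((e[-1L] + e[-length(e)]) / 2)[segment_ends - 1L],
            sum(sqrt(1 + diff(e)^2)))
  vals
}

feature_names_for <- function(channels, taus, segment_ends) {
  per_metric <- c(paste0("tau", taus),
                  if (length(segment_ends) > 0)
                    c(paste0("Slp1-", segment_ends),
                      paste0("Ar1-", segment_ends), "AL"))
  unlist(lapply(channels, function(ch) {
    c(paste(ch, "DPE", per_metric, sep = "/"),
      paste(ch, "PME", per_metric, sep = "/"))
  }))
}

#' Feature matrix for a set of trials
#'
#' Runs [trial_entropy_curves()] and [featurize_curves()] over every trial of
#' a trial set and binds the rows into a trials x features tibble, with
#' `trial_id`, `group`, `arousal` and `valence` leading columns. With 32
#' channels and the default lags this is 1344 feature columns (21 features x
#' 2 metrics x 32 channels).
#'
#' @param trials A `trial_set` (see [generate_dataset()]) or a list of
#'   [eeg_trial()] objects.
#' @inheritParams trial_entropy_curves
#' @param channels Optional character vector restricting the analysis to a
#'   subset of channel labels.
#' @return A tibble, one row per trial.
#' @export
featurize_trials <- function(trials, m = 6, taus = 1:10, K = 0.5,
                             channels = NULL) {
  trial_list <- if (inherits(trials, "trial_set")) trials$trials else trials
  taus <- as.integer(taus)
  if (!identical(taus, seq_len(max(taus)))) {
    abort("`taus` must be the contiguous range 1..tau_max.")
  }
  segment_ends <- intersect(c(2L, 4L, 6L, 8L, 10L), taus)
  degenerate <- max(taus) < 2
  rows <- vector("list", length(trial_list))
  nms <- NULL
  for (i in seq_along(trial_list)) {
    tr <- trial_list[[i]]
    sig <- tr$signal
    if (!is.null(channels)) {
      missing <- setdiff(channels, rownames(sig))
      if (length(missing) > 0) {
        abort(sprintf("Trial %s lacks channels: %s.", i,
                      paste(missing, collapse = ", ")))
      }
      sig <- sig[channels, , drop = FALSE]
    }
    labels <- rownames(sig) %||% paste0("ch", seq_len(nrow(sig)))
    if (is.null(nms)) {
      nms <- if (degenerate) {
        feature_names_for(labels, taus, integer(0))
      } else {
        feature_names_for(labels, taus, segment_ends)
      }
    }
    row <- unlist(lapply(seq_len(nrow(sig)), function(ch) {
      cur <- fast_channel_curves(sig[ch, ], m, taus, K)
      if (degenerate) {
        c(cur$DPE, cur$PME)
      } else {
        c(fast_curve_features(cur$DPE, taus, segment_ends),
          fast_curve_features(cur$PME, taus, segment_ends))
      }
    }))
    rows[[i]] <- row
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- nms
  meta <- tibble::tibble(
    trial_id = purrr::imap_chr(trial_list,
                               function(tr, i) tr$id %||% as.character(i)),
    group = purrr::map_chr(trial_list,
                           function(tr) tr$group %||% NA_character_),
    arousal = purrr::map_dbl(trial_list,
                             function(tr) tr$arousal %||% NA_real_),
    valence = purrr::map_dbl(trial_list,
                             function(tr) tr$valence %||% NA_real_)
  )
  dplyr::bind_cols(meta, tibble::as_tibble(mat))
}

#' @importFrom rlang %||%
NULL
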