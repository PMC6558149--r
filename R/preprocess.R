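# Trial cleaning: decimation, common-average reference, zero-phase band
# limiting, FASTER-style independent-component artifact scoring, and
# noisy-channel interpolation. The fixed pipeline order is: downsample ->
# re-reference -> band-limit -> noisy-channel detection -> IC scoring and
# removal -> channel interpolation (detection happens before ICA so that the
# flagged channels are measured on unmixed data, interpolation after so its
# smoothing never enters the decomposition).

#' Downsample an EEG trial
#'
#' Integer-factor decimation with an anti-aliasing low-pass filter
#' ([signal::decimate()], 30-tap FIR applied zero-phase). Identity when
#' `target_fs == fs`.
#'
#' @param trial An [eeg_trial()].
#' @param target_fs Target sampling rate in Hz; must divide `trial$fs`.
#' @return The downsampled `eeg_trial`.
#' @export
eeg_downsample <- function(trial, target_fs = 128) {
  stopifnot(inherits(trial, "eeg_trial"))
  if (target_fs > trial$fs) abort("`target_fs` cannot exceed the current rate.")
  if (target_fs == trial$fs) return(trial)
  q <- trial$fs / target_fs
  if (abs(q - round(q)) > 1e-9) {
    abort("`fs` must be an integer multiple of `target_fs`.")
  }
  q <- as.integer(round(q))
  dec <- function(v) signal::decimate(v, q, ftype = "fir")
  trial$signal <- t(apply(trial$signal, 1L, dec))
  rownames(trial$signal) <- trial$channels
  if (!is.null(trial$eog)) trial$eog <- t(apply(trial$eog, 1L, dec))
  trial$fs <- target_fs
  trial
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean across all channels, so the average
#' potential of the montage is zero. Idempotent.
#'
#' @param trial An [eeg_trial()] with at least 2 channels.
#' @return The re-referenced `eeg_trial`.
#' @export
eeg_rereference <- function(trial) {
  stopifnot(inherits(trial, "eeg_trial"))
  if (nrow(trial$signal) < 2L) {
    abort("Common-average reference needs at least 2 channels.")
  }
  trial$signal <- sweep(trial$signal, 2L, colMeans(trial$signal))
  trial
}

#' Zero-phase band limiting
#'
#' 4th-order Butterworth high-pass at `hp_hz` and low-pass at `lp_hz`, each
#' applied forward and backward ([signal::filtfilt()]) so the output has zero
#' phase shift and effectively doubled rolloff.
#'
#' @param trial An [eeg_trial()].
#' @param hp_hz High-pass cutoff in Hz (removes drift/baseline).
#' @param lp_hz Low-pass cutoff in Hz (removes line noise and EMG); must stay
#'   below the Nyquist frequency.
#' @param order Butterworth order per pass.
#' @return The filtered `eeg_trial`.
#' @export
eeg_bandlimit <- function(trial, hp_hz = 3, lp_hz = 45, order = 4) {
  stopifnot(inherits(trial, "eeg_trial"))
  nyq <- trial$fs / 2
  if (lp_hz >= nyq) abort("`lp_hz` must be below the Nyquist frequency.")
  if (hp_hz <= 0 || hp_hz >= lp_hz) abort("need 0 < hp_hz < lp_hz.")
  hp <- signal::butter(order, hp_hz / nyq, type = "high")
  lp <- signal::butter(order, lp_hz / nyq, type = "low")
  f <- function(v) {
    signal::filtfilt(lp, signal::filtfilt(hp, v))
  }
  trial$signal <- t(apply(trial$signal, 1L, f))
  rownames(trial$signal) <- trial$channels
  trial
}

# ---- independent components -------------------------------------------------

#' FastICA decomposition of a trial
#'
#' Delegates the unmixing to [ica::icafast()] (FastICA, logcosh contrast,
#' symmetric orthogonalisation) on the channel-centered data. The number of
#' components defaults to the numerical rank of the channel covariance, so a
#' common-average-referenced trial (rank `n_channels - 1`) is decomposed and
#' reconstructed without blowing up the null dimension.
#'
#' @param trial An [eeg_trial()].
#' @param n_comp Number of components; default the covariance rank.
#' @param seed Integer seed for the random initial rotation.
#' @return A list of class `eeg_ica`: `S` (samples x components activations),
#'   `M` (channels x components mixing matrix), `center` (per-channel means),
#'   plus the trial's `fs`, `channels` and dimensions.
#' @export
eeg_ica <- function(trial, n_comp = NULL, seed = 1L) {
  stopifnot(inherits(trial, "eeg_trial"))
  X <- t(trial$signal)  # samples x channels
  if (is.null(n_comp)) {
    ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
    n_comp <- sum(ev > max(ev) * 1e-9)
  }
  if (n_comp < 2L) abort("Need at least 2 components.")
  set.seed(seed)
  dec <- ica::icafast(X, nc = n_comp, center = TRUE, maxit = 200, tol = 1e-7)
  structure(
    list(S = dec$S, M = dec$M, center = colMeans(X), fs = trial$fs,
         channels = trial$channels, n_comp = n_comp),
    class = "eeg_ica"
  )
}

# Detrended fluctuation analysis: slope of log F(n) vs log n over log-spaced
# window sizes in [4, N/4]; ~0.5 for white noise, ~1.5 for Brownian-like
# trends. Used as an IC and channel quality statistic.
dfa_hurst <- function(x, n_windows = 10) {
  n <- length(x)
  prof <- cumsum(x - mean(x))
  sizes <- unique(round(exp(seq(log(4), log(n / 4), length.out = n_windows))))
  sizes <- sizes[sizes >= 4]
  fl <- vapply(sizes, function(w) {
    k <- n %/% w
    idx <- seq_len(k * w)
    seg <- matrix(prof[idx], nrow = w)
    t_in <- seq_len(w)
    # residual variance after linear detrend, per segment, done in closed form
    tc <- t_in - mean(t_in)
    denom <- sum(tc^2)
    segc <- sweep(seg, 2L, colMeans(seg))
    beta <- colSums(segc * tc) / denom
    res <- segc - outer(tc, beta)
    sqrt(mean(res^2))
  }, numeric(1))
  ok <- fl > 0
  if (sum(ok) < 2) return(NA_real_)
  unname(stats::coef(stats::lm(log(fl[ok]) ~ log(sizes[ok])))[2L])
}

spectral_slope <- function(x, fs, f_lo = 8, f_hi = 45) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = 11,
                          plot = FALSE, detrend = TRUE)
  keep <- sp$freq >= f_lo & sp$freq <= min(f_hi, fs / 2 * 0.99)
  if (sum(keep) < 3) return(NA_real_)
  unname(stats::coef(stats::lm(log(sp$spec[keep]) ~ log(sp$freq[keep])))[2L])
}

#' Score independent components for artifact signatures
#'
#' Computes, for every component, the five quality statistics used for
#' automatic artifact identification: maximum absolute correlation with the
#' EOG reference traces, spatial kurtosis of the scalp map (mixing column),
#' slope of the log power spectrum over 8-45 Hz, Hurst exponent of the
#' activation (via detrended fluctuation analysis), and median absolute
#' gradient of the activation. Each statistic is standardised across
#' components and a component is flagged for removal when any statistic lies
#' more than `z_max` standard deviations from the mean of all components; a
#' statistic with zero spread across components flags nothing.
#'
#' @param decomposition An `eeg_ica` object, or a samples x components
#'   activation matrix (then `mixing` must be given).
#' @param eog Optional traces x samples matrix of EOG references; the EOG
#'   correlation criterion is skipped when absent.
#' @param mixing Channels x components mixing matrix (taken from
#'   `decomposition` when it is an `eeg_ica`).
#' @param fs Sampling rate (taken from an `eeg_ica` automatically).
#' @param z_max Rejection threshold in standard deviations (default 3).
#' @return A tibble of class `ic_scores`: one row per component with the raw
#'   statistics, their z-scores (`z_` prefix) and a logical `rejected` mask.
#' @export
score_components <- function(decomposition, eog = NULL, mixing = NULL,
                             fs = NULL, z_max = 3) {
  if (inherits(decomposition, "eeg_ica")) {
    S <- decomposition$S
    mixing <- decomposition$M
    fs <- fs %||% decomposition$fs
  } else {
    S <- decomposition
  }
  if (!is.matrix(S) || ncol(S) < 2L) abort("Need at least 2 components.")
  if (is.null(mixing)) abort("`mixing` is required.")
  if (is.null(fs)) abort("`fs` is required.")
  nc <- ncol(S)
  eog_corr <- if (!is.null(eog)) {
    apply(abs(stats::cor(S, t(eog))), 1L, max)
  } else {
    rep(NA_real_, nc)
  }
  scores <- tibble::tibble(
    component = seq_len(nc),
    eog_corr = eog_corr,
    spatial_kurtosis = apply(mixing, 2L, e1071::kurtosis),
    spectral_slope = apply(S, 2L, spectral_slope, fs = fs),
    hurst = apply(S, 2L, dfa_hurst),
    median_gradient = apply(S, 2L, function(v) median(abs(diff(v))))
  )
  crit <- c("eog_corr", "spatial_kurtosis", "spectral_slope", "hurst",
            "median_gradient")
  rejected <- rep(FALSE, nc)
  for (cn in crit) {
    v <- scores[[cn]]
    if (all(is.na(v))) {
      scores[[paste0("z_", cn)]] <- NA_real_
      next
    }
    s <- sd(v, na.rm = TRUE)
    z <- if (is.na(s) || s == 0) rep(0, nc) else (v - mean(v, na.rm = TRUE)) / s
    scores[[paste0("z_", cn)]] <- z
    rejected <- rejected | (!is.na(z) & abs(z) > z_max)
  }
  scores$rejected <- rejected
  class(scores) <- c("ic_scores", class(scores))
  scores
}

#' Reconstruct a trial from its retained independent components
#'
#' Zeroes the activations of the masked (artifactual) components and remixes
#' the remainder; with an empty mask the reconstruction returns the input
#' within numerical tolerance.
#'
#' @param trial The [eeg_trial()] that was decomposed.
#' @param decomposition The matching `eeg_ica`.
#' @param mask Logical vector (length = number of components) or integer
#'   indices of components to remove.
#' @return The reconstructed `eeg_trial`.
#' @export
remove_components_and_reconstruct <- function(trial, decomposition, mask) {
  stopifnot(inherits(trial, "eeg_trial"), inherits(decomposition, "eeg_ica"))
  nc <- decomposition$n_comp
  if (is.logical(mask)) {
    if (length(mask) != nc) abort("`mask` length must equal the component count.")
    drop_idx <- which(mask)
  } else {
    drop_idx <- as.integer(mask)
    if (length(drop_idx) > 0 && (min(drop_idx) < 1 || max(drop_idx) > nc)) {
      abort("`mask` indices out of range.")
    }
  }
  S <- decomposition$S
  if (length(drop_idx) > 0) S[, drop_idx] <- 0
  Xr <- tcrossprod(S, decomposition$M)
  if (length(drop_idx) < nc) {
    Xr <- sweep(Xr, 2L, decomposition$center, `+`)
  }
  trial$signal <- t(Xr)
  rownames(trial$signal) <- trial$channels
  trial
}

# ---- noisy channels ---------------------------------------------------------

robust_z <- function(v) {
  med <- median(v)
  s <- stats::mad(v)
  if (s == 0) return(rep(0, length(v)))
  (v - med) / s
}

#' Detect channels carrying high-amplitude noise
#'
#' Flags a channel when the robust z-score (median/MAD) of its log variance
#' exceeds `z_max` (one-sided: only abnormally large amplitude counts), or
#' when the robust z-score of its Hurst exponent exceeds `z_max` in absolute
#' value. Because the MAD of a small montage can be tiny, each criterion also
#' requires a minimal raw effect: at least a doubling of variance over the
#' montage median, or a Hurst deviation of 0.15. Aborts if more than
#' `max_fraction` of the montage is flagged, since interpolation can no
#' longer be trusted.
#'
#' @param trial An [eeg_trial()].
#' @param z_max Threshold in robust standard deviations (default 3).
#' @param max_fraction Maximum tolerated fraction of bad channels (default
#'   0.25).
#' @return Character vector of flagged channel labels (possibly empty).
#' @export
detect_noisy_channels <- function(trial, z_max = 3, max_fraction = 0.25) {
  stopifnot(inherits(trial, "eeg_trial"))
  lv <- log(apply(trial$signal, 1L, var))
  hu <- apply(trial$signal, 1L, dfa_hurst)
  bad <- (robust_z(lv) > z_max & lv - median(lv) > log(2)) |
    (abs(robust_z(hu)) > z_max & abs(hu - median(hu, na.rm = TRUE)) > 0.15)
  bad[is.na(bad)] <- FALSE
  if (mean(bad) > max_fraction) {
    abort(sprintf(
      "Quality failure: %d of %d channels flagged as noisy (> %d%%).",
      sum(bad), length(bad), round(max_fraction * 100)
    ))
  }
  trial$channels[bad]
}

#' Interpolate channels from their montage neighbours
#'
#' Replaces each listed channel by the inverse-distance-weighted average of
#' its `n_neighbors` nearest good channels in the 2D montage.
#'
#' @param trial An [eeg_trial()].
#' @param bad Character vector of channel labels to replace.
#' @param montage Tibble with columns `channel`, `x`, `y` covering every
#'   channel of the trial (default [standard_montage()]).
#' @param n_neighbors Number of neighbouring channels to average (default 3).
#' @return The `eeg_trial` with the listed channels replaced.
#' @export
interpolate_channels <- function(trial, bad, montage = standard_montage(),
                                 n_neighbors = 3) {
  stopifnot(inherits(trial, "eeg_trial"))
  if (length(bad) == 0) return(trial)
  missing <- setdiff(trial$channels, montage$channel)
  if (length(missing) > 0) {
    abort(sprintf("Montage positions missing for: %s.",
                  paste(missing, collapse = ", ")))
  }
  pos <- montage[match(trial$channels, montage$channel), ]
  good <- setdiff(trial$channels, bad)
  if (length(good) < n_neighbors) abort("Not enough good channels to interpolate.")
  for (ch in bad) {
    i <- match(ch, trial$channels)
    gi <- match(good, trial$channels)
    d <- sqrt((pos$x[gi] - pos$x[i])^2 + (pos$y[gi] - pos$y[i])^2)
    ord <- order(d)[seq_len(n_neighbors)]
    w <- 1 / pmax(d[ord], 1e-9)
    w <- w / sum(w)
    trial$signal[i, ] <- as.vector(w %*% trial$signal[gi[ord], , drop = FALSE])
  }
  trial
}

#' Full preprocessing of one trial
#'
#' Applies the fixed cleaning order: downsample to `target_fs`, common-average
#' re-reference, zero-phase band limiting, noisy-channel detection (before any
#' component arithmetic), IC artifact scoring and removal, and finally
#' interpolation of the flagged channels.
#'
#' @param trial An [eeg_trial()].
#' @param target_fs Output sampling rate (default 128 Hz).
#' @param hp_hz,lp_hz Band-limiting cutoffs (defaults 3 and 45 Hz).
#' @param run_ica Set to `FALSE` to skip the IC cleaning stage (e.g. for
#'   already-clean synthetic data).
#' @param interpolate Set to `FALSE` to skip noisy-channel handling.
#' @param montage Montage positions for interpolation.
#' @param seed Seed for the ICA initial rotation.
#' @return A list of class `preprocessed_trial`: `trial` (the cleaned
#'   [eeg_trial()]), `removed_components` (integer indices), `ic_scores`
#'   (tibble or `NULL`), `interpolated` (channel labels).
#' @export
preprocess_trial <- function(trial, target_fs = 128, hp_hz = 3, lp_hz = 45,
                             run_ica = TRUE, interpolate = TRUE,
                             montage = standard_montage(), seed = 1L) {
  stopifnot(inherits(trial, "eeg_trial"))
  trial <- eeg_downsample(trial, target_fs)
  trial <- eeg_rereference(trial)
  trial <- eeg_bandlimit(trial, hp_hz, lp_hz)
  bad <- if (interpolate) detect_noisy_channels(trial) else character()
  scores <- NULL
  removed <- integer()
  if (run_ica) {
    dec <- eeg_ica(trial, seed = seed)
    scores <- score_components(dec, eog = trial$eog)
    removed <- which(scores$rejected)
    trial <- remove_components_and_reconstruct(trial, dec, scores$rejected)
  }
  if (interpolate && length(bad) > 0) {
    trial <- interpolate_channels(trial, bad, montage = montage)
  }
  structure(
    list(trial = trial, removed_components = removed, ic_scores = scores,
         interpolated = bad),
    class = "preprocessed_trial"
  )
}
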