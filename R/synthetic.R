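# Seeded synthetic two-class EEG generator. Each channel is an AR(2)
# stochastic oscillation (pole at the alpha band) plus an explicit alpha-band
# sinusoid and white sensor noise. The "distress" class has a stronger,
# narrower-band AR pole and larger oscillation than "calmness", which gives it
# more repetitive ordinal structure and hence lower permutation entropies --
# the qualitative signature the analysis is designed to detect. Trial-level
# and channel-level jitter of the pole radius creates realistic within-class
# overlap. A separate scenario expresses the class difference only through a
# slow (< 6 Hz) component, so it becomes visible only at embedding delays
# greater than one.

#' Configuration for the synthetic EEG generator
#'
#' Returns the full set of generator parameters, with defaults emulating the
#' study conditions: 32 channels at 128 Hz, 30-s trials, 122 distress and 137
#' calmness trials, SAM ratings drawn inside each class's arousal/valence
#' region. Class dynamics defaults: calmness AR pole radius 0.70 with alpha
#' oscillation amplitude 0.6, distress pole 0.88 with amplitude 1.5; pole
#' jitter SD 0.05 shared across channels of a trial plus 0.04 per channel.
#'
#' @param n_distress,n_calmness Trials per class.
#' @param n_channels Number of EEG channels (up to 32, labelled from
#'   [standard_montage()]).
#' @param fs Sampling rate in Hz.
#' @param duration Trial length in seconds (`fs * duration` must be integer).
#' @param calmness,distress Per-class dynamics: list with `pole` (mean AR(2)
#'   pole radius in (0, 1)), `osc_amp` (mean 10 Hz oscillation amplitude),
#'   `slow_amp` (amplitude of a slow rhythm at `slow_hz`).
#' @param osc_hz Oscillation frequency (default 10 Hz, alpha band).
#' @param slow_hz Frequency of the slow class-contrast rhythm (default 3 Hz).
#' @param noise_sd Broadband innovation SD driving the AR process.
#' @param sensor_sd Additive white sensor-noise SD.
#' @param pole_jitter_trial,pole_jitter_channel SD of Gaussian jitter added to
#'   the class pole radius, shared across a trial's channels and per channel
#'   respectively. The trial-level jitter models subject/trial state
#'   variability and is what makes the classes overlap; the channel-level
#'   jitter averages out across the montage, so multichannel classifiers can
#'   beat any single channel.
#' @param osc_jitter_trial,osc_jitter_channel Trial-level additive SD
#'   (truncated at 0) and channel-level multiplicative SD of the oscillation
#'   amplitude.
#' @param blink_rate Expected blinks per trial (0 disables).
#' @param pop_prob Probability that a trial contains one electrode-pop
#'   channel.
#' @param seed Master seed; fixes the entire dataset.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_distress = 122, n_calmness = 137,
                             n_channels = 32, fs = 128, duration = 30,
                             calmness = list(pole = 0.78, osc_amp = 0.8,
                                             slow_amp = 0),
                             distress = list(pole = 0.88, osc_amp = 1.2,
                                             slow_amp = 0),
                             osc_hz = 10, slow_hz = 3,
                             noise_sd = 1, sensor_sd = 0.2,
                             pole_jitter_trial = 0.035,
                             pole_jitter_channel = 0.05,
                             osc_jitter_trial = 0.25,
                             osc_jitter_channel = 0.15,
                             blink_rate = 0, pop_prob = 0,
                             seed = 1L) {
  cfg <- list(
    n_distress = n_distress, n_calmness = n_calmness,
    n_channels = n_channels, fs = fs, duration = duration,
    calmness = calmness, distress = distress,
    osc_hz = osc_hz, slow_hz = slow_hz,
    noise_sd = noise_sd, sensor_sd = sensor_sd,
    pole_jitter_trial = pole_jitter_trial,
    pole_jitter_channel = pole_jitter_channel,
    osc_jitter_trial = osc_jitter_trial,
    osc_jitter_channel = osc_jitter_channel,
    blink_rate = blink_rate, pop_prob = pop_prob,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  n <- cfg$fs * cfg$duration
  if (abs(n - round(n)) > 1e-9) abort("`fs * duration` must be an integer.")
  if (cfg$n_distress < 0 || cfg$n_calmness < 0) abort("Trial counts must be >= 0.")
  if (cfg$n_channels < 1 || cfg$n_channels > 32) {
    abort("`n_channels` must be between 1 and 32.")
  }
  for (cl in c("calmness", "distress")) {
    p <- cfg[[cl]]$pole
    if (p < 0 || p >= 1) {
      abort(sprintf("Unstable AR specification: %s pole radius must be in [0, 1).", cl))
    }
    if (cfg[[cl]]$osc_amp < 0 || cfg[[cl]]$slow_amp < 0) {
      abort("Amplitudes must be >= 0.")
    }
  }
  if (cfg$noise_sd < 0 || cfg$sensor_sd < 0 || cfg$blink_rate < 0 ||
      cfg$pop_prob < 0 || cfg$pop_prob > 1) {
    abort("Noise/artifact settings out of range.")
  }
  invisible(cfg)
}

draw_ratings <- function(group) {
  # Continuous uniform draws strictly inside each class's SAM region:
  # distress needs arousal > 5 and valence < 3; calmness arousal < 4 and
  # valence in [4, 6].
  if (group == "distress") {
    list(arousal = runif(1, 5 + 1e-3, 9), valence = runif(1, 1, 3 - 1e-3))
  } else {
    list(arousal = runif(1, 1, 4 - 1e-3), valence = runif(1, 4, 6))
  }
}

#' Generate one synthetic EEG trial
#'
#' Draws a single `fs * duration`-sample trial of `n_channels` AR(2)-based
#' signals for the given class, with SAM ratings inside the class's
#' arousal/valence region. The AR(2) process has complex poles at radius
#' `pole` and frequency `osc_hz`, giving a stochastic alpha-band rhythm whose
#' regularity grows with the pole radius.
#'
#' @param group `"calmness"` or `"distress"`.
#' @param config A [synthetic_config()].
#' @param seed Integer seed for this trial.
#' @param id Optional trial identifier.
#' @return An [eeg_trial()].
#' @export
generate_trial <- function(group = c("calmness", "distress"),
                           config = synthetic_config(), seed = 1L, id = NULL) {
  group <- match.arg(group)
  validate_synthetic_config(config)
  set.seed(as.integer(seed))
  n <- as.integer(round(config$fs * config$duration))
  nch <- config$n_channels
  pars <- config[[group]]
  labels <- standard_montage()$channel[seq_len(nch)]
  tt <- seq_len(n) / config$fs
  pole_trial <- pars$pole + rnorm(1, 0, config$pole_jitter_trial)
  osc_trial <- max(0, pars$osc_amp + rnorm(1, 0, config$osc_jitter_trial))
  sig <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    r <- pole_trial + rnorm(1, 0, config$pole_jitter_channel)
    r <- min(max(r, 0), 0.995)
    a1 <- 2 * r * cos(2 * pi * config$osc_hz / config$fs)
    a2 <- -r^2
    e <- rnorm(n, sd = config$noise_sd)
    base <- as.numeric(stats::filter(e, c(a1, a2), method = "recursive"))
    amp_ch <- osc_trial * max(0, 1 + rnorm(1, 0, config$osc_jitter_channel))
    osc <- amp_ch * sin(2 * pi * config$osc_hz * tt + runif(1, 0, 2 * pi))
    slow <- if (pars$slow_amp > 0) {
      pars$slow_amp * sin(2 * pi * config$slow_hz * tt + runif(1, 0, 2 * pi))
    } else 0
    sig[ch, ] <- base + osc + slow + rnorm(n, sd = config$sensor_sd)
  }
  ratings <- draw_ratings(group)
  eog <- matrix(rnorm(2L * n, sd = 0.5), 2L, n)  # quiet EOG baseline
  tr <- eeg_trial(sig, fs = config$fs, channels = labels, eog = eog,
                  arousal = ratings$arousal, valence = ratings$valence,
                  group = group, id = id)
  if (config$blink_rate > 0 || config$pop_prob > 0) {
    tr <- inject_artifacts(tr, settings = config, seed = seed + 500000L)$trial
  }
  tr
}

#' Generate a full two-class synthetic dataset
#'
#' Produces `n_distress + n_calmness` trials with per-trial seeds derived from
#' the master seed, plus a manifest (config and seed) sufficient to regenerate
#' the set bit-identically.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `trial_set`: `trials` (list of [eeg_trial()]) and
#'   `manifest` (config, seed, counts).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  groups <- c(rep("distress", config$n_distress),
              rep("calmness", config$n_calmness))
  trials <- purrr::imap(groups, function(g, i) {
    generate_trial(g, config, seed = config$seed + 1000L * i,
                   id = sprintf("trial%03d", i))
  })
  structure(
    list(
      trials = trials,
      manifest = list(config = unclass(config), seed = config$seed,
                      n_trials = length(trials),
                      groups = table(groups))
    ),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials", length(x$trials)))
  if (length(x$trials) > 0) {
    gr <- table(vapply(x$trials, function(t) t$group, character(1)))
    cat(" (", paste(sprintf("%s: %d", names(gr), gr), collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

# Canonical blink waveform: smooth positive lobe ~300 ms wide.
blink_shape <- function(fs, width_s = 0.3) {
  t <- seq(-2 * width_s, 2 * width_s, by = 1 / fs)
  exp(-0.5 * (t / (width_s / 2))^2)
}

#' Inject ocular and electrode-pop artifacts into a trial
#'
#' Blinks are smooth ~300 ms transients added to the frontal channels with
#' gains decreasing towards the back of the montage, and mirrored (amplified)
#' in the two EOG reference traces. An electrode pop superimposes
#' high-amplitude noise on one randomly chosen channel. Ground truth is
#' returned for validating the cleaning stages.
#'
#' @param trial An [eeg_trial()].
#' @param settings List with `blink_rate` (expected blinks per trial),
#'   `pop_prob` (probability of one pop channel), optional `blink_amp`
#'   (default 25) and `pop_scale` (default 100, multiple of the channel's SD).
#' @param seed Integer seed.
#' @return List: `trial` (with artifacts), `blink_times` (sample indices),
#'   `pop_channel` (label or `NA`).
#' @export
inject_artifacts <- function(trial, settings, seed = 1L) {
  stopifnot(inherits(trial, "eeg_trial"))
  set.seed(as.integer(seed))
  n <- ncol(trial$signal)
  blink_amp <- settings$blink_amp %||% 25
  pop_scale <- settings$pop_scale %||% 100
  blink_times <- integer()
  if ((settings$blink_rate %||% 0) > 0) {
    n_blinks <- stats::rpois(1, settings$blink_rate)
    if (n_blinks > 0) {
      shape <- blink_shape(trial$fs)
      half <- length(shape) %/% 2
      blink_times <- sort(sample(seq(half + 1L, n - length(shape) + half),
                                 n_blinks))
      pos <- standard_montage()
      yy <- pos$y[match(trial$channels, pos$channel)]
      gain <- pmax(yy, 0)^2  # frontal channels only
      if (all(gain == 0)) gain[which.max(yy)] <- 1
      blink <- numeric(n)
      for (bt in blink_times) {
        idx <- seq(bt - half, length.out = length(shape))
        blink[idx] <- blink[idx] + shape
      }
      trial$signal <- trial$signal + blink_amp * outer(gain, blink)
      if (!is.null(trial$eog)) {
        trial$eog <- trial$eog + 1.5 * blink_amp * rbind(blink, 0.8 * blink)
      }
    }
  }
  pop_channel <- NA_character_
  if ((settings$pop_prob %||% 0) > 0 && runif(1) < settings$pop_prob) {
    ch <- sample(seq_len(nrow(trial$signal)), 1L)
    pop_channel <- trial$channels[ch]
    trial$signal[ch, ] <- trial$signal[ch, ] +
      rnorm(n, sd = pop_scale * sd(trial$signal[ch, ]))
  }
  list(trial = trial, blink_times = blink_times, pop_channel = pop_channel)
}

#' Lag-contrast scenario: class difference only in a slow rhythm
#'
#' Generates a dataset in which both classes share identical fast dynamics
#' (same AR pole and oscillation) and differ only in the amplitude of a slow
#' (`slow_hz`, default 3 Hz) rhythm carried by the distress class. Over the
#' few samples spanned by a lag-1 embedding window the slow rhythm is nearly
#' constant and the ordinal patterns are dominated by the shared fast
#' activity, so the classes are hard to tell apart; at large delays the
#' window spans a substantial part of the slow cycle and the distress
#' patterns become markedly more regular. The between-class entropy
#' difference therefore grows with the embedding delay.
#'
#' @param config A [synthetic_config()]; its class dynamics are overridden
#'   with the matched fast parameters, except that `distress$slow_amp` is set
#'   to `contrast`.
#' @param contrast Amplitude of the distress-only slow rhythm (default 2).
#' @param pole Shared AR pole radius (default 0.75).
#' @param osc_amp Shared oscillation amplitude (default 0.8).
#' @return A `trial_set`.
#' @export
lag_contrast_scenario <- function(config = synthetic_config(), contrast = 2,
                                  pole = 0.75, osc_amp = 0.8) {
  if (contrast < 0) abort("`contrast` must be >= 0.")
  config$calmness <- list(pole = pole, osc_amp = osc_amp, slow_amp = 0)
  config$distress <- list(pole = pole, osc_amp = osc_amp, slow_amp = contrast)
  config$pole_jitter_trial <- min(config$pole_jitter_trial, 0.03)
  config$pole_jitter_channel <- min(config$pole_jitter_channel, 0.03)
  generate_dataset(config)
}
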