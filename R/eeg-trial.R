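# Single-trial EEG container: channels x samples matrix plus recording
# metadata. Deliberately lightweight (a classed list), with a long-format
# as_tibble() for tidy workflows.

#' Construct an EEG trial
#'
#' @param signal Channels x samples numeric matrix (microvolts). Rownames, if
#'   present, must agree with `channels`.
#' @param fs Sampling rate in Hz.
#' @param channels Character vector of channel labels (10-20 names), unique,
#'   one per signal row.
#' @param eog Optional 2 x samples matrix of electrooculography reference
#'   traces.
#' @param arousal,valence Optional SAM ratings on the 1-9 scale.
#' @param group Optional group label (`"calmness"`, `"distress"`, `"other"`).
#' @param id Optional trial identifier.
#' @return An object of class `eeg_trial`.
#' @export
eeg_trial <- function(signal, fs, channels = rownames(signal), eog = NULL,
                      arousal = NULL, valence = NULL, group = NULL, id = NULL) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    abort("`signal` must be a numeric matrix (channels x samples).")
  }
  if (any(!is.finite(signal))) abort("`signal` must be finite.")
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number.")
  }
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(signal)))
  channels <- as.character(channels)
  if (length(channels) != nrow(signal)) {
    abort("`channels` must name every row of `signal`.")
  }
  if (anyDuplicated(channels)) abort("`channels` must be unique.")
  rownames(signal) <- channels
  if (!is.null(eog)) {
    if (!is.matrix(eog) || ncol(eog) != ncol(signal)) {
      abort("`eog` must be a matrix with the same number of samples as `signal`.")
    }
  }
  for (r in list(arousal = arousal, valence = valence)) {
    if (!is.null(r) && (length(r) != 1L || r < 1 || r > 9)) {
      abort("SAM ratings must be single values in [1, 9].")
    }
  }
  structure(
    list(signal = signal, fs = fs, channels = channels, eog = eog,
         arousal = arousal, valence = valence, group = group, id = id),
    class = "eeg_trial"
  )
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf(
    "<eeg_trial%s> %d channels x %d samples @ %g Hz (%.1f s)\n",
    if (!is.null(x$id)) paste0(" ", x$id) else "",
    nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs
  ))
  if (!is.null(x$group)) {
    cat(sprintf("  group: %s (arousal %.2f, valence %.2f)\n",
                x$group, x$arousal %||% NA, x$valence %||% NA))
  }
  cat("  channels:", paste(utils::head(x$channels, 8L), collapse = ", "),
      if (length(x$channels) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @export
as_tibble.eeg_trial <- function(x, ...) {
  tibble::tibble(
    channel = rep(x$channels, each = ncol(x$signal)),
    time = rep(seq_len(ncol(x$signal)) / x$fs, times = nrow(x$signal)),
    value = as.vector(t(x$signal))
  )
}

#' Standard 2D montage positions for the 32-channel 10-20 layout
#'
#' Approximate projected head-disk coordinates (nose towards +y, right ear
#' towards +x, unit radius at the outer electrode ring) for the 32 scalp
#' electrodes of the standard emotion-EEG montage. Used for noisy-channel
#' interpolation neighbourhoods.
#'
#' @return Tibble with columns `channel`, `x`, `y`.
#' @export
standard_montage <- function() {
  tibble::tribble(
    ~channel, ~x, ~y,
    "Fp1", -0.309, 0.951,
    "AF3", -0.330, 0.850,
    "F3",  -0.450, 0.550,
    "F7",  -0.809, 0.588,
    "FC5", -0.750, 0.280,
    "FC1", -0.250, 0.270,
    "C3",  -0.500, 0.000,
    "T7",  -1.000, 0.000,
    "CP5", -0.750, -0.280,
    "CP1", -0.250, -0.270,
    "P3",  -0.450, -0.550,
    "P7",  -0.809, -0.588,
    "PO3", -0.330, -0.850,
    "O1",  -0.309, -0.951,
    "Oz",   0.000, -1.000,
    "Pz",   0.000, -0.500,
    "Fp2",  0.309, 0.951,
    "AF4",  0.330, 0.850,
    "Fz",   0.000, 0.500,
    "F4",   0.450, 0.550,
    "F8",   0.809, 0.588,
    "FC6",  0.750, 0.280,
    "FC2",  0.250, 0.270,
    "Cz",   0.000, 0.000,
    "C4",   0.500, 0.000,
    "T8",   1.000, 0.000,
    "CP6",  0.750, -0.280,
    "CP2",  0.250, -0.270,
    "P4",   0.450, -0.550,
    "P8",   0.809, -0.588,
    "PO4",  0.330, -0.850,
    "O2",   0.309, -0.951
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
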