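# On-disk trial container: one CSV matrix per trial (channels x samples,
# first column = channel label) plus a JSON sidecar with the sampling rate,
# labels, ratings and group. Feature matrices round-trip through CSV with
# the channel/metric/feature header convention; CV reports serialise to JSON.

#' Write a set of trials to a directory
#'
#' @param trials A `trial_set` or list of [eeg_trial()] objects.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trials <- function(trials, dir) {
  trial_list <- if (inherits(trials, "trial_set")) trials$trials else trials
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  purrr::iwalk(trial_list, function(tr, i) {
    id <- tr$id %||% sprintf("trial%03d", i)
    mat <- tibble::as_tibble(as.data.frame(tr$signal), .name_repair = "minimal")
    names(mat) <- paste0("s", seq_len(ncol(mat)))
    readr::write_csv(dplyr::bind_cols(tibble::tibble(channel = tr$channels), mat),
                     file.path(dir, paste0(id, ".csv")), progress = FALSE)
    side <- list(fs = tr$fs, channels = tr$channels, arousal = tr$arousal,
                 valence = tr$valence, group = tr$group, id = id)
    if (!is.null(tr$eog)) side$eog <- apply(tr$eog, 1L, identity, simplify = FALSE)
    jsonlite::write_json(side, file.path(dir, paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  })
  if (inherits(trials, "trial_set")) {
    jsonlite::write_json(trials$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(dir)
}

#' Read a directory of trials written by [write_trials()]
#'
#' @param dir Directory containing `<id>.csv` / `<id>.json` pairs.
#' @return A `trial_set`.
#' @export
read_trials <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "^trial.*\\.json$", full.names = TRUE))
  if (length(sidecars) == 0) abort(sprintf("No trial sidecars found in %s.", dir))
  trials <- purrr::map(sidecars, function(sc) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    mat <- readr::read_csv(sub("\\.json$", ".csv", sc),
                           col_types = readr::cols(
                             channel = readr::col_character(),
                             .default = readr::col_double()
                           ), progress = FALSE)
    sig <- as.matrix(mat[, -1L])
    dimnames(sig) <- list(mat$channel, NULL)
    eog <- if (!is.null(meta$eog)) do.call(rbind, meta$eog) else NULL
    eeg_trial(sig, fs = meta$fs, channels = mat$channel, eog = eog,
              arousal = meta$arousal, valence = meta$valence,
              group = meta$group, id = meta$id)
  })
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL
  structure(list(trials = trials, manifest = manifest), class = "trial_set")
}

#' Write / read a feature matrix as CSV
#'
#' Column names follow the `channel/metric/feature` convention and are
#' preserved verbatim.
#'
#' @param features Tibble from [featurize_trials()].
#' @param path CSV path.
#' @return `path` (write) or the tibble (read).
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    trial_id = readr::col_character(),
    group = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE, name_repair = "minimal")
}

#' Serialise a cross-validation report to JSON
#'
#' @param report An `ordlag_cv`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  jsonlite::write_json(
    list(summary = report$summary, folds = report$folds,
         selection = report$selection, config = report$config),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
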