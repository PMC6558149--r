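#' @keywords internal
"_PACKAGE"

## usethis namespace: start
#' @importFrom rlang abort warn .data :=
#' @importFrom stats sd var cor median rnorm runif quantile
#' @importFrom utils head tail
#' @importFrom Rcpp sourceCpp
#' @useDynLib ordlag, .registration = TRUE
## usethis namespace: end
NULL

# ---- validation helpers -----------------------------------------------------

check_series <- function(x, m, tau, call = rlang::caller_env()) {
  if (!is.numeric(x)) {
    abort("`x` must be a numeric vector.", call = call)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort("`x` must contain only finite values.", call = call)
  }
  check_embedding(m, tau, call = call)
  n_min <- (m - 1L) * tau + 1L
  if (length(x) < n_min) {
    abort(
      sprintf(
        "Series of length %d is too short for (m = %d, tau = %d); need at least %d samples.",
        length(x), m, tau, n_min
      ),
      call = call
    )
  }
  invisible(x)
}

check_embedding <- function(m, tau, call = rlang::caller_env()) {
  if (length(m) != 1L || m != as.integer(m) || m < 2L) {
    abort("`m` must be a single integer >= 2.", call = call)
  }
  if (m > 10L) {
    abort("`m` > 10 is not supported (m! pattern bins become impractical).", call = call)
  }
  if (length(tau) != 1L || tau != as.integer(tau) || tau < 1L) {
    abort("`tau` must be a single integer >= 1.", call = call)
  }
  invisible(TRUE)
}

# ---- ordinal pattern extraction ---------------------------------------------

# Embed x into its n x m delay matrix and encode each row's ordinal pattern as
# a Lehmer-code index in 1..m! (compiled kernel). Ties are broken by temporal
# order (the earlier sample ranks lower), the usual Bandt-Pompe convention, so
# the encoding is deterministic and invariant under strictly increasing
# transforms.
embed_ordinal <- function(x, m, tau) {
  out <- .pattern_ids_amplitudes(as.numeric(x), m, tau)
  out$n <- length(out$ids)
  out
}

#' Extract ordinal patterns from a time series
#'
#' Slides a delay-embedding window of length `m` with lag `tau` over `x` and
#' encodes the rank order of each embedded vector as an integer pattern
#' identifier in `1..factorial(m)` (Lehmer code of the sorting permutation).
#' Equal samples are ranked by temporal order, earlier index first.
#'
#' @param x Numeric vector, the time series (all values finite).
#' @param m Pattern length (embedding dimension), integer between 2 and 10.
#' @param tau Embedding delay in samples, integer >= 1. `tau = 1` uses
#'   consecutive samples.
#' @return A tibble with one row per embedded vector: `index` (start position
#'   in `x`), `pattern` (integer identifier in `1..m!`). Exactly
#'   `length(x) - (m - 1) * tau` rows.
#' @examples
#' extract_ordinal_patterns(c(3, 1, 2), m = 3, tau = 1)
#' @seealso [pattern_distribution()], [ordinal_pattern_label()]
#' @export
extract_ordinal_patterns <- function(x, m = 6, tau = 1) {
  m <- as.integer(m); tau <- as.integer(tau)
  check_series(x, m, tau)
  emb <- embed_ordinal(x, m, tau)
  tibble::tibble(index = seq_len(emb$n), pattern = emb$ids)
}

#' Decode an ordinal pattern identifier
#'
#' Inverse of the Lehmer-code encoding used by [extract_ordinal_patterns()]:
#' returns the permutation `(r0, ..., r_{m-1})` of `0..m-1` such that the
#' embedded samples at those (0-based) positions are in non-decreasing order.
#'
#' @param id Integer pattern identifier in `1..factorial(m)`.
#' @param m Pattern length.
#' @return Integer vector of length `m`.
#' @export
ordinal_pattern_label <- function(id, m) {
  m <- as.integer(m)
  if (id < 1 || id > factorial(m)) {
    abort(sprintf("`id` must lie in 1..%d for m = %d.", factorial(m), m))
  }
  rem <- id - 1L
  pool <- 0:(m - 1L)
  out <- integer(m)
  for (r in seq_len(m)) {
    f <- factorial(m - r)
    take <- rem %/% f
    rem <- rem %% f
    out[r] <- pool[take + 1L]
    pool <- pool[-(take + 1L)]
  }
  out
}

# ---- pattern distributions --------------------------------------------------

new_ordinal_distribution <- function(probs, m, tau, n_vectors, weighted) {
  structure(
    list(probs = probs, m = m, tau = tau, n_vectors = n_vectors,
         weighted = weighted),
    class = "ordinal_distribution"
  )
}

#' @export
print.ordinal_distribution <- function(x, ...) {
  cat(sprintf(
    "<ordinal_distribution> m = %d, tau = %d, %s\n  %d embedded vectors over %d patterns (%d observed)\n",
    x$m, x$tau,
    if (x$weighted) "amplitude-weighted" else "relative frequencies",
    x$n_vectors, length(x$probs), sum(x$probs > 0)
  ))
  invisible(x)
}

#' Ordinal-pattern probability distribution
#'
#' Relative frequency of each of the `m!` ordinal patterns among the
#' `N - (m - 1) * tau` embedded vectors of `x`.
#'
#' @inheritParams extract_ordinal_patterns
#' @return An `ordinal_distribution` object: a list with `probs` (length `m!`,
#'   sums to 1), `m`, `tau`, `n_vectors` and `weighted = FALSE`.
#' @examples
#' d <- pattern_distribution(c(2, 1, 2, 1, 2), m = 2, tau = 1)
#' d$probs  # 0.5 ascending, 0.5 descending
#' @export
pattern_distribution <- function(x, m = 6, tau = 1) {
  m <- as.integer(m); tau <- as.integer(tau)
  check_series(x, m, tau)
  emb <- embed_ordinal(x, m, tau)
  probs <- tabulate(emb$ids, nbins = factorial(m)) / emb$n
  new_ordinal_distribution(probs, m, tau, emb$n, weighted = FALSE)
}

#' Amplitude-aware ordinal-pattern distribution
#'
#' Each embedded vector contributes to its pattern a weight
#' `K * AA + (1 - K) * RA`, where `AA` is the mean absolute amplitude of the
#' vector's samples and `RA` the mean absolute successive difference; the
#' resulting per-pattern weight totals are normalised to a probability
#' distribution. `K` balances level against variation information.
#'
#' @inheritParams extract_ordinal_patterns
#' @param K Amplitude-adjusting coefficient in `[0, 1]` (default 0.5, equal
#'   balance).
#' @return An `ordinal_distribution` with `weighted = TRUE`.
#' @examples
#' aape_distribution(c(0, 2, 1), m = 2, tau = 1, K = 0.5)
#' @export
aape_distribution <- function(x, m = 6, tau = 1, K = 0.5) {
  m <- as.integer(m); tau <- as.integer(tau)
  check_series(x, m, tau)
  if (length(K) != 1L || !is.finite(K) || K < 0 || K > 1) {
    abort("`K` must be a single value in [0, 1].")
  }
  emb <- embed_ordinal(x, m, tau)
  w <- K * emb$aa + (1 - K) * emb$ra
  tot <- sum(w)
  if (tot <= 0) {
    abort("Degenerate input: total amplitude weight is zero (all-zero signal?).")
  }
  sums <- rowsum(w, emb$ids)
  probs <- numeric(factorial(m))
  probs[as.integer(rownames(sums))] <- sums[, 1L]
  new_ordinal_distribution(probs / tot, m, tau, emb$n, weighted = TRUE)
}

check_distribution <- function(dist, call = rlang::caller_env()) {
  if (!inherits(dist, "ordinal_distribution")) {
    abort("`dist` must be an `ordinal_distribution` (see `pattern_distribution()`).",
          call = call)
  }
  invisible(dist)
}

# ---- entropy functionals ----------------------------------------------------

#' Normalised Shannon entropy of an ordinal-pattern distribution
#'
#' `-sum(p * log(p)) / log(m!)`, with `0 * log(0)` taken as 0, so the value
#' lies in `[0, 1]`: 0 for a fully predictable series (one pattern only), 1
#' when all `m!` patterns are equiprobable. On an unweighted distribution this
#' is permutation entropy (PE); on an amplitude-weighted distribution it is
#' amplitude-aware permutation entropy, called delayed permutation entropy
#' (DPE) when evaluated across embedding delays.
#'
#' @param dist An `ordinal_distribution`.
#' @return A single numeric value in `[0, 1]`.
#' @export
shannon_permutation_entropy <- function(dist) {
  check_distribution(dist)
  p <- dist$probs[dist$probs > 0]
  -sum(p * log(p)) / log(factorial(dist$m))
}

#' Normalised Renyi entropy of an ordinal-pattern distribution
#'
#' `log(sum(p^q)) / ((1 - q) * log(m!))` for bias order `q >= 0`, `q != 1`.
#' Orders `q < 1` emphasise rare patterns, `q > 1` salient ones; the Shannon
#' functional is the `q -> 1` limit and [permutation_min_entropy()] the
#' `q -> Inf` limit.
#'
#' @param dist An `ordinal_distribution`.
#' @param q Renyi order, `q >= 0` and `q != 1`.
#' @return A single numeric value in `[0, 1]`.
#' @export
renyi_permutation_entropy <- function(dist, q) {
  check_distribution(dist)
  if (length(q) != 1L || !is.finite(q) || q < 0) {
    abort("`q` must be a single finite value >= 0.")
  }
  if (q == 1) {
    abort("`q` = 1 is the Shannon limit; use `shannon_permutation_entropy()`.")
  }
  p <- dist$probs[dist$probs > 0]
  log(sum(p^q)) / ((1 - q) * log(factorial(dist$m)))
}

#' Permutation min-entropy
#'
#' The `q -> Inf` limit of the Renyi family: `-log(max(p)) / log(m!)`. It
#' depends only on the most probable ordinal pattern, which makes it sensitive
#' to subtle temporal structure that leaves the bulk of the distribution
#' unchanged. Defined on the unweighted (relative-frequency) distribution
#' only; an amplitude-weighted distribution is rejected.
#'
#' @param dist An unweighted `ordinal_distribution`.
#' @return A single numeric value in `[0, 1]`.
#' @export
permutation_min_entropy <- function(dist) {
  check_distribution(dist)
  if (isTRUE(dist$weighted)) {
    abort(paste0(
      "Permutation min-entropy is defined on the unweighted pattern ",
      "distribution; supply `pattern_distribution()` output."
    ))
  }
  -log(max(dist$probs)) / log(factorial(dist$m))
}

# ---- convenience single-call forms ------------------------------------------

#' Single-lag entropy values of a time series
#'
#' Convenience wrappers composing pattern extraction and the entropy
#' functionals: `permutation_entropy()` is Shannon entropy of the unweighted
#' distribution; `delayed_permutation_entropy()` is Shannon entropy of the
#' amplitude-weighted distribution (AAPE at lag `tau`, i.e. DPE); `pme()` is
#' permutation min-entropy.
#'
#' @inheritParams extract_ordinal_patterns
#' @param K Amplitude-adjusting coefficient in `[0, 1]`.
#' @param q Renyi order for `rpe()`.
#' @return A single numeric value in `[0, 1]`.
#' @export
permutation_entropy <- function(x, m = 6, tau = 1) {
  shannon_permutation_entropy(pattern_distribution(x, m, tau))
}

#' @rdname permutation_entropy
#' @export
delayed_permutation_entropy <- function(x, m = 6, tau = 1, K = 0.5) {
  shannon_permutation_entropy(aape_distribution(x, m, tau, K))
}

#' @rdname permutation_entropy
#' @export
pme <- function(x, m = 6, tau = 1) {
  permutation_min_entropy(pattern_distribution(x, m, tau))
}

#' @rdname permutation_entropy
#' @export
rpe <- function(x, q, m = 6, tau = 1) {
  renyi_permutation_entropy(pattern_distribution(x, m, tau), q)
}

# ---- multi-lag curves -------------------------------------------------------

#' Multi-lag entropy curve of a single time series
#'
#' Computes DPE (Shannon entropy of the amplitude-weighted distribution)
#' and/or PME (min-entropy of the unweighted distribution) at each embedding
#' delay in `taus`. Pattern extraction is shared between the two metrics at
#' each lag.
#'
#' @inheritParams extract_ordinal_patterns
#' @param taus Integer vector of embedding delays (default `1:10`).
#' @param metrics Character subset of `c("DPE", "PME")`.
#' @param K Amplitude-adjusting coefficient for DPE.
#' @return A tibble with columns `metric`, `tau`, `value`, ordered by metric
#'   then tau.
#' @examples
#' entropy_curve(rnorm(500), m = 4, taus = 1:5)
#' @export
entropy_curve <- function(x, m = 6, taus = 1:10, metrics = c("DPE", "PME"),
                          K = 0.5) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  taus <- as.integer(taus)
  if (length(taus) < 1L || any(taus < 1L)) {
    abort("`taus` must be positive integers.")
  }
  m <- as.integer(m)
  check_series(x, m, max(taus))
  fm <- factorial(m)
  rows <- purrr::map(taus, function(tau) {
    emb <- embed_ordinal(x, m, tau)
    out <- list()
    if ("DPE" %in% metrics) {
      w <- K * emb$aa + (1 - K) * emb$ra
      tot <- sum(w)
      if (tot <= 0) {
        abort("Degenerate input: total amplitude weight is zero.")
      }
      sums <- rowsum(w, emb$ids)[, 1L] / tot
      out$DPE <- -sum(sums * log(sums)) / log(fm)
    }
    if ("PME" %in% metrics) {
      counts <- tabulate(emb$ids, nbins = fm)
      out$PME <- -log(max(counts) / emb$n) / log(fm)
    }
    tibble::tibble(metric = names(out), tau = tau,
                   value = unname(unlist(out)))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$metric, .data$tau)
}

#' Read a one-column numeric series from a text file
#'
#' Standalone helper so the entropy functions can be used on plain exported
#' traces: reads the first column of a headerless CSV/TSV (delimiter
#' auto-detected from the first line) as a numeric vector.
#'
#' @param path Path to the file.
#' @return Numeric vector.
#' @export
read_series <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, col_names = FALSE,
                          col_types = readr::cols(.default = readr::col_double()),
                          progress = FALSE)
  as.numeric(df[[1L]])
}
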