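# broom-style accessors for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation report
#'
#' @param x An `ordlag_cv` object.
#' @param ... Unused.
#' @return Per-fold tibble (`fold`, `n_test`, `se`, `sp`, `acc`, and
#'   `n_selected` for SFS runs).
#' @export
tidy.ordlag_cv <- function(x, ...) {
  x$folds
}

#' @describeIn tidy.ordlag_cv One-row tibble of fold-averaged sensitivity,
#'   specificity and accuracy (percent).
#' @export
glance.ordlag_cv <- function(x, ...) {
  x$summary
}

#' Tidy an ordinal-pattern distribution
#'
#' @param x An `ordinal_distribution`.
#' @param drop_zero Keep only patterns with positive mass (default `TRUE`).
#' @param ... Unused.
#' @return Tibble `pattern`, `permutation` (dash-separated 0-based ranks),
#'   `prob`.
#' @export
tidy.ordinal_distribution <- function(x, drop_zero = TRUE, ...) {
  ids <- seq_along(x$probs)
  keep <- if (drop_zero) x$probs > 0 else rep(TRUE, length(ids))
  tibble::tibble(
    pattern = ids[keep],
    permutation = vapply(ids[keep], function(i) {
      paste(ordinal_pattern_label(i, x$m), collapse = "-")
    }, character(1)),
    prob = x$probs[keep]
  )
}

#' @describeIn tidy.ordinal_distribution One-row summary with the entropy
#'   functionals that apply (Shannon always; min-entropy for unweighted
#'   distributions).
#' @export
glance.ordinal_distribution <- function(x, ...) {
  tibble::tibble(
    m = x$m, tau = x$tau, n_vectors = x$n_vectors, weighted = x$weighted,
    n_observed = sum(x$probs > 0),
    shannon = shannon_permutation_entropy(x),
    min_entropy = if (x$weighted) NA_real_ else permutation_min_entropy(x)
  )
}

#' Tidy a fitted ROC-threshold model
#'
#' @param x A `roc_threshold` object.
#' @param ... Unused.
#' @return One-row tibble with `threshold`, `polarity`, `positive` and
#'   training accuracy.
#' @export
tidy.roc_threshold <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold, polarity = x$polarity, positive = x$positive,
    train_accuracy = x$train_accuracy
  )
}
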