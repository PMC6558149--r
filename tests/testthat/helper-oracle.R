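# Independent brute-force implementations used as oracles: explicit loop over
# every embedded vector, explicit stable sort, direct evaluation of the
# weighting formulas. Deliberately naive and separate from the package's
# vectorised/compiled path.

brute_patterns <- function(x, m, tau) {
  n <- length(x) - (m - 1) * tau
  ids <- integer(n)
  for (i in seq_len(n)) {
    v <- x[i + (0:(m - 1)) * tau]
    kappa <- order(v) - 1L  # stable: earlier index first on ties
    id <- 0L
    for (r in 1:(m - 1)) {
      id <- id + sum(kappa[(r + 1):m] < kappa[r]) * factorial(m - r)
    }
    ids[i] <- id + 1L
  }
  ids
}

brute_distribution <- function(x, m, tau) {
  ids <- brute_patterns(x, m, tau)
  tabulate(ids, nbins = factorial(m)) / length(ids)
}

brute_aape <- function(x, m, tau, K = 0.5) {
  ids <- brute_patterns(x, m, tau)
  n <- length(ids)
  w <- numeric(n)
  for (i in seq_len(n)) {
    v <- x[i + (0:(m - 1)) * tau]
    aa <- mean(abs(v))
    ra <- mean(abs(diff(v)))
    w[i] <- K * aa + (1 - K) * ra
  }
  p <- numeric(factorial(m))
  for (i in seq_len(n)) p[ids[i]] <- p[ids[i]] + w[i]
  p / sum(w)
}

# Random valid pattern distribution over m! bins (Dirichlet-ish).
random_distribution <- function(m, weighted = FALSE) {
  p <- stats::rgamma(factorial(m), shape = 0.5)
  p <- p / sum(p)
  ordlag:::new_ordinal_distribution(p, m, 1L, n_vectors = 100L,
                                    weighted = weighted)
}

# Small flat EEG trial with controllable content.
toy_trial <- function(n_channels = 4, n = 512, fs = 128, seed = 1) {
  set.seed(seed)
  labels <- standard_montage()$channel[seq_len(n_channels)]
  eeg_trial(matrix(rnorm(n_channels * n), n_channels, n), fs, labels)
}
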