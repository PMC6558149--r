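# Ordinal pattern extraction and the four entropy functionals.

test_that("pattern extraction matches the ordering definition and tie rule", {
  # (3, 1, 2): smallest at index 1, then 2, then 0 (0-based)
  p <- extract_ordinal_patterns(c(3, 1, 2), m = 3, tau = 1)
  expect_equal(nrow(p), 1L)
  expect_equal(ordinal_pattern_label(p$pattern, 3), c(1L, 2L, 0L))

  # monotone series with a gap delay: both vectors ascending
  p <- extract_ordinal_patterns(c(1, 2, 3, 4), m = 2, tau = 2)
  expect_equal(nrow(p), 2L)
  expect_equal(unique(p$pattern), 1L)  # ascending = identity permutation

  # tie broken by temporal order: equal samples read as ascending
  p_tie <- extract_ordinal_patterns(c(1, 1), m = 2, tau = 1)
  p_asc <- extract_ordinal_patterns(c(1, 2), m = 2, tau = 1)
  expect_equal(p_tie$pattern, p_asc$pattern)
})

test_that("vector count is exactly N - (m-1)*tau and bounds are enforced", {
  for (N in c(10, 37, 100)) {
    x <- rnorm(N)
    for (m in 2:4) {
      for (tau in 1:3) {
        if (N >= (m - 1) * tau + 1) {
          expect_equal(nrow(extract_ordinal_patterns(x, m, tau)),
                       N - (m - 1) * tau)
        }
      }
    }
  }
  expect_error(extract_ordinal_patterns(rnorm(5), m = 6, tau = 1), "too short")
  expect_error(extract_ordinal_patterns(c(1, NA, 2), m = 2, tau = 1), "finite")
  expect_error(pattern_distribution(rnorm(10), m = 1, tau = 1), "integer >= 2")
  expect_error(pattern_distribution(rnorm(10), m = 2, tau = 0), "integer >= 1")
})

test_that("distributions match the brute-force oracle to 1e-12", {
  set.seed(42)
  for (rep in 1:10) {
    x <- rnorm(200)
    for (m in 2:4) {
      for (tau in 1:3) {
        expect_equal(pattern_distribution(x, m, tau)$probs,
                     brute_distribution(x, m, tau), tolerance = 1e-12)
        expect_equal(aape_distribution(x, m, tau, K = 0.5)$probs,
                     brute_aape(x, m, tau, K = 0.5), tolerance = 1e-12)
      }
    }
  }
})

test_that("unweighted distribution frequencies are exact on tiny examples", {
  d <- pattern_distribution(c(2, 1, 2, 1, 2), m = 2, tau = 1)
  expect_equal(sort(d$probs), c(0.5, 0.5))
  expect_equal(d$n_vectors, 4L)
  expect_false(d$weighted)

  # strictly increasing series: all mass on the ascending pattern
  d <- pattern_distribution(1:30, m = 4, tau = 2)
  expect_equal(d$probs[1L], 1)
  expect_equal(sum(d$probs), 1)

  # single-vector series
  d <- pattern_distribution(c(5, 1, 3), m = 3, tau = 1)
  expect_equal(sum(d$probs == 1), 1L)
})

test_that("amplitude weighting follows the AA/RA mixture", {
  # (0,2): AA=1, RA=2 -> w=1.5 (ascending); (2,1): AA=1.5, RA=1 -> w=1.25
  d <- aape_distribution(c(0, 2, 1), m = 2, tau = 1, K = 0.5)
  expect_equal(d$probs, c(1.5, 1.25) / 2.75, tolerance = 1e-12)
  expect_true(d$weighted)

  # equal |samples| and K = 1: collapses to the unweighted distribution
  x <- rep(c(1, -1), 10)
  expect_equal(aape_distribution(x, 2, 1, K = 1)$probs,
               pattern_distribution(x, 2, 1)$probs, tolerance = 1e-12)

  # monotone series concentrates all weighted mass regardless of K
  expect_equal(max(aape_distribution(seq(0.1, 2, by = 0.1), 3, 1, 0.3)$probs), 1)

  expect_error(aape_distribution(rep(0, 50), m = 3, tau = 1), "Degenerate")
  expect_error(aape_distribution(rnorm(50), 3, 1, K = 1.2), "K")
})

test_that("Shannon entropy hits its analytic limits and the worked example", {
  one <- pattern_distribution(1:50, m = 3, tau = 1)       # predictable
  expect_identical(shannon_permutation_entropy(one), 0)
  expect_identical(permutation_min_entropy(one), 0)

  unif <- ordlag:::new_ordinal_distribution(rep(1 / 6, 6), 3L, 1L, 600L, FALSE)
  expect_equal(shannon_permutation_entropy(unif), 1, tolerance = 1e-15)
  expect_equal(permutation_min_entropy(unif), 1, tolerance = 1e-15)

  # worked two-pattern example: direct arithmetic as the oracle
  d <- aape_distribution(c(0, 2, 1), m = 2, tau = 1, K = 0.5)
  p <- c(6, 5) / 11
  expect_equal(shannon_permutation_entropy(d),
               -sum(p * log(p)) / log(2), tolerance = 1e-12)
})

test_that("Renyi entropy: closed forms, q validation, Shannon limit", {
  half <- ordlag:::new_ordinal_distribution(c(0.5, 0.5), 2L, 1L, 10L, FALSE)
  expect_equal(renyi_permutation_entropy(half, q = 2), 1, tolerance = 1e-15)
  one <- pattern_distribution(1:20, 3, 1)
  for (q in c(0.5, 2, 7)) {
    expect_equal(renyi_permutation_entropy(one, q), 0)
  }
  expect_error(renyi_permutation_entropy(half, q = 1), "Shannon")
  expect_error(renyi_permutation_entropy(half, q = -0.1), ">= 0")

  set.seed(11)
  for (i in 1:5) {
    d <- random_distribution(3)
    pe <- shannon_permutation_entropy(d)
    expect_equal(renyi_permutation_entropy(d, 1 + 1e-6), pe, tolerance = 1e-4)
    expect_equal(renyi_permutation_entropy(d, 1 - 1e-6), pe, tolerance = 1e-4)
  }
})

test_that("min-entropy is the max-probability functional on unweighted input", {
  d <- ordlag:::new_ordinal_distribution(c(0.5, 0.25, 0.25, 0, 0, 0),
                                         3L, 1L, 8L, FALSE)
  expect_equal(permutation_min_entropy(d), -log(0.5) / log(6),
               tolerance = 1e-12)
  w <- aape_distribution(rnorm(100), 3, 1)
  expect_error(permutation_min_entropy(w), "unweighted")
})

test_that("entropies stay in [0, 1] and PME <= RPE <= bounds ordering holds", {
  set.seed(99)
  for (i in 1:100) {
    m <- sample(2:4, 1)
    d <- random_distribution(m)
    pe <- shannon_permutation_entropy(d)
    pm <- permutation_min_entropy(d)
    expect_true(pe >= 0 && pe <= 1)
    expect_true(pm >= 0 && pm <= 1)
    expect_true(pm <= pe + 1e-12)
    for (q in c(0.5, 2, 10)) {
      rq <- renyi_permutation_entropy(d, q)
      expect_true(pm <= rq + 1e-12)
    }
  }
})

test_that("PE and PME are invariant under strictly increasing transforms", {
  set.seed(7)
  transforms <- list(function(v) exp(v), function(v) v^3 + 2 * v,
                     function(v) atan(v) * 10 + 0.1 * v)
  for (i in 1:10) {
    x <- rnorm(150)
    f <- transforms[[1 + (i %% length(transforms))]]
    for (tau in 1:2) {
      expect_identical(extract_ordinal_patterns(x, 3, tau)$pattern,
                       extract_ordinal_patterns(f(x), 3, tau)$pattern)
    }
    # AAPE has no such guarantee; its weights see the amplitudes
    expect_false(isTRUE(all.equal(
      aape_distribution(x, 3, 1)$probs,
      aape_distribution(exp(x), 3, 1)$probs
    )))
  }
})

test_that("entropy curves cover the requested lags for both metrics", {
  x <- rnorm(600)
  ec <- entropy_curve(x, m = 4, taus = 1:6)
  expect_equal(nrow(ec), 12L)
  expect_equal(sort(unique(ec$tau)), 1:6)
  expect_true(all(ec$value >= 0 & ec$value <= 1))

  # agreement with the single-lag wrappers
  expect_equal(ec$value[ec$metric == "DPE" & ec$tau == 3],
               delayed_permutation_entropy(x, 4, 3))
  expect_equal(ec$value[ec$metric == "PME" & ec$tau == 5], pme(x, 4, 5))

  mono <- entropy_curve(seq_len(200), m = 3, taus = 1:5)
  expect_true(all(mono$value == 0))

  single <- entropy_curve(x, m = 3, taus = 1)
  expect_equal(nrow(single), 2L)
  expect_equal(single$value[single$metric == "PME"], pme(x, 3, 1))
})

test_that("degenerate all-equal series yields entropy 0, not an error", {
  x <- rep(3.7, 40)
  expect_identical(permutation_entropy(x, 3, 1), 0)
  expect_identical(pme(x, 3, 1), 0)
  d <- pattern_distribution(x, 3, 1)
  expect_equal(d$probs[1L], 1)  # ascending under the tie rule
})

test_that("one-column series reader handles CSV and TSV", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1.5", "-2", "3.25"), p)
  expect_equal(read_series(p), c(1.5, -2, 3.25))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t9", "2\t8"), p2)
  expect_equal(read_series(p2), c(1, 2))
})
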