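# Cleaning pipeline: decimation, re-referencing, filtering, IC scoring,
# reconstruction, noisy-channel handling.

test_that("downsampling scales length, keeps the passband, validates rates", {
  fs <- 512; n <- 15360
  t <- seq_len(n) / fs
  tr <- eeg_trial(rbind(sin(2 * pi * 5 * t), cos(2 * pi * 5 * t)), fs,
                  c("C3", "C4"))
  d <- eeg_downsample(tr, 128)
  expect_equal(d$fs, 128)
  expect_equal(ncol(d$signal), 3840L)
  core <- 200:3600  # away from filter edge effects
  expect_gt(max(abs(d$signal[1, core])) / max(abs(tr$signal[1, ])), 0.99)

  expect_identical(eeg_downsample(tr, 512), tr)
  expect_error(eeg_downsample(tr, 1024), "cannot exceed")
  expect_error(eeg_downsample(tr, 100), "integer multiple")
})

test_that("common-average re-referencing zeroes the montage mean, idempotent", {
  tr <- eeg_trial(matrix(c(1, 3), 2, 5), 128, c("C3", "C4"))
  r <- eeg_rereference(tr)
  expect_equal(r$signal[, 1], c(C3 = -1, C4 = 1))

  tr32 <- toy_trial(n_channels = 8, n = 100, seed = 2)
  r1 <- eeg_rereference(tr32)
  expect_lt(max(abs(colMeans(r1$signal))), 1e-10)
  expect_equal(eeg_rereference(r1)$signal, r1$signal, tolerance = 1e-12)

  expect_error(eeg_rereference(eeg_trial(matrix(1, 1, 10), 128, "Cz")),
               "at least 2")
})

test_that("band limiting is zero-phase with the expected pass/stop behaviour", {
  fs <- 128; n <- 3840
  t <- seq_len(n) / fs
  tr <- eeg_trial(rbind(sin(2 * pi * 10 * t), sin(2 * pi * 0.5 * t),
                        sin(2 * pi * 60 * t)), fs, c("a", "b", "c"))
  f <- eeg_bandlimit(tr)
  core <- 500:3300
  ratio <- function(i) sd(f$signal[i, core]) / sd(tr$signal[i, core])
  expect_gt(ratio(1), 0.95)   # 10 Hz passband
  expect_lt(ratio(2), 0.1)    # drift removed
  expect_lt(ratio(3), 0.1)    # high-frequency tone removed

  # zero phase: cross-correlation of the 10 Hz channel peaks at lag 0
  cc <- stats::ccf(f$signal[1, core], tr$signal[1, core], lag.max = 5,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # linearity
  tr2 <- tr; tr2$signal <- 3.5 * tr$signal
  f2 <- eeg_bandlimit(tr2)
  expect_equal(f2$signal, 3.5 * f$signal, tolerance = 1e-8)

  expect_error(eeg_bandlimit(tr, lp_hz = 70), "Nyquist")
  expect_error(eeg_bandlimit(tr, hp_hz = 50, lp_hz = 45), "hp_hz")
})

test_that("IC reconstruction with no masked components is lossless", {
  tr <- eeg_rereference(toy_trial(n_channels = 6, n = 2000, seed = 4))
  dec <- eeg_ica(tr, seed = 1)
  rec <- remove_components_and_reconstruct(tr, dec, rep(FALSE, dec$n_comp))
  expect_lt(max(abs(rec$signal - tr$signal)) / max(abs(tr$signal)), 1e-8)

  zero <- remove_components_and_reconstruct(tr, dec, rep(TRUE, dec$n_comp))
  expect_equal(max(abs(zero$signal)), 0)

  expect_error(remove_components_and_reconstruct(tr, dec, c(TRUE, FALSE)),
               "length")
})

test_that("an EOG-mirrored component is flagged by the correlation criterion", {
  # NB the 3-SD rule needs enough components: with n components the largest
  # attainable z is (n-1)/sqrt(n), so montages below ~12 channels can never
  # trigger it. Realistic montages (16-32) are used throughout.
  set.seed(10)
  n <- 2000; nc <- 16
  S <- matrix(rnorm(nc * n), n, nc)
  blink <- rep(0, n); blink[seq(100, 1950, by = 400) + rep(0:30, each = 5)] <- 8
  S[, 3] <- blink + rnorm(n, sd = 0.1)
  M <- matrix(rnorm(nc * nc), nc, nc)
  sc <- score_components(S, mixing = M, eog = rbind(blink, 0.7 * blink),
                         fs = 128)
  expect_true(sc$rejected[3])
  expect_gt(sc$eog_corr[3], 0.95)
})

test_that("identically distributed components are rarely flagged", {
  set.seed(12)
  flags <- replicate(20, {
    S <- matrix(rnorm(8 * 1500), 1500, 8)
    M <- matrix(rnorm(64), 8, 8)
    sum(score_components(S, mixing = M, fs = 128)$rejected)
  })
  # 3-SD rule on homogeneous components: flags are rare
  expect_lt(mean(flags), 1)
})

test_that("a spiky component is flagged through kurtosis/median-gradient", {
  set.seed(13)
  n <- 1500; nc <- 16
  S <- matrix(rnorm(nc * n), n, nc)
  spike_map <- c(8, rep(0.05, nc - 1))  # spatially concentrated component
  M <- cbind(spike_map, matrix(rnorm(nc * (nc - 1), sd = 0.5), nc, nc - 1))
  S[, 1] <- rnorm(n, sd = 0.05); S[, 1][700:703] <- 40  # one huge transient
  sc <- score_components(S, mixing = M, fs = 128)
  expect_true(sc$rejected[1])
})

test_that("zero-spread criteria flag nothing", {
  set.seed(14)
  S <- matrix(rnorm(4 * 800), 800, 4)
  M <- matrix(rep(rnorm(4), 4), 4, 4)  # identical maps: kurtosis spread is 0
  sc <- score_components(S, mixing = M, fs = 128)
  expect_true(all(sc$z_spatial_kurtosis == 0))
})

test_that("a planted blink source is recovered from a determined mixture", {
  # clean = mixing of (nch - 1) independent sources; blink adds the nch-th
  set.seed(20)
  hits <- 0; restored <- 0; runs <- 15
  n <- 3840; nch <- 16
  shape <- ordlag:::blink_shape(128)
  for (r in 1:runs) {
    S <- matrix(rnorm((nch - 1) * n), n, nch - 1)
    A <- matrix(rnorm((nch - 1) * nch), nch, nch - 1)
    clean <- A %*% t(S)  # nch x n
    blink <- rep(0, n)
    for (bt in sample(200:3500, 5)) {
      idx <- seq(bt, length.out = length(shape))
      blink[idx] <- blink[idx] + shape
    }
    gain <- c(3, 2.5, 2, rep(0.05, nch - 3)) * 8
    tr <- eeg_trial(clean + outer(gain, blink), 128,
                    standard_montage()$channel[1:nch],
                    eog = rbind(20 * blink, 16 * blink))
    dec <- eeg_ica(tr, seed = r)
    sc <- score_components(dec, eog = tr$eog)
    if (any(sc$rejected & sc$eog_corr > 0.5)) hits <- hits + 1
    rec <- remove_components_and_reconstruct(tr, dec, sc$rejected)
    cors <- vapply(seq_len(nch),
                   function(c) cor(rec$signal[c, ], clean[c, ]), numeric(1))
    if (min(cors) >= 0.95) restored <- restored + 1
  }
  expect_gte(hits / runs, 0.9)
  expect_gte(restored / runs, 0.9)
})

test_that("noisy-channel detection flags amplitude outliers only", {
  tr <- toy_trial(n_channels = 12, n = 2000, seed = 30)
  expect_length(detect_noisy_channels(tr), 0)

  bad <- tr
  bad$signal[5, ] <- 100 * rnorm(2000)
  expect_identical(detect_noisy_channels(bad), tr$channels[5])

  worse <- tr
  worse$signal[1:5, ] <- 100 * matrix(rnorm(5 * 2000), 5)
  expect_error(detect_noisy_channels(worse), "Quality failure")
})

test_that("interpolation reproduces a shared neighbour trace exactly", {
  tr <- toy_trial(n_channels = 8, n = 500, seed = 31)
  c0 <- sin(2 * pi * 3 * seq_len(500) / 128)
  tr$signal[2:8, ] <- matrix(rep(c0, 7), 7, byrow = TRUE)
  out <- interpolate_channels(tr, "Fp1")
  expect_equal(out$signal[1, ], c0, tolerance = 1e-12)
  # untouched channels stay untouched
  expect_equal(out$signal[3, ], tr$signal[3, ])
})

test_that("full preprocessing runs end to end in the documented order", {
  set.seed(33)
  cfg <- synthetic_config(n_channels = 8, duration = 10)
  tr <- generate_trial("calmness", cfg, seed = 50)
  res <- preprocess_trial(tr, seed = 1)
  expect_s3_class(res$trial, "eeg_trial")
  expect_equal(res$trial$fs, 128)
  # re-referencing happened before ICA: montage mean ~ 0 is preserved by
  # component arithmetic up to removed components
  expect_true(is.numeric(res$removed_components))
  expect_true(is.character(res$interpolated))
})
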