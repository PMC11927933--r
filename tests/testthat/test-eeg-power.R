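# Multitaper spectral estimation, band power, pooling, and smoothing.

test_that("DPSS tapers are orthonormal and correctly shaped", {
  v <- dpss_tapers(450, nw = 2, n_tapers = 3)
  expect_equal(dim(v), c(450, 3))
  expect_equal(crossprod(v), diag(3), tolerance = 1e-8)
  # first taper is bell-shaped and positive
  expect_true(all(v[, 1] > 0))
  expect_equal(which.max(v[, 1]), 225, tolerance = 2)
})

test_that("multitaper PSD locates a pure tone within the analysis bandwidth", {
  fs <- 250
  n <- 450                      # 1.8 s epoch
  t <- (0:(n - 1)) / fs
  bw <- 2 / (n / fs)            # NW / T ~ 1.11 Hz
  for (f0 in c(6, 10, 15.3)) {
    x <- sin(2 * pi * f0 * t + 0.3)
    psd <- multitaper_psd(x, fs)
    expect_lt(abs(psd$freq[which.max(psd$power)] - f0), bw)
    pg <- periodogram_oracle(x, fs)
    expect_lt(abs(pg$freq[which.max(pg$power)] - f0), bw)
  }
})

test_that("multitaper PSD is zero for a zero epoch and non-negative always", {
  psd0 <- multitaper_psd(numeric(450), 250)
  expect_true(all(psd0$power == 0))
  set.seed(1)
  psd <- multitaper_psd(rnorm(128), 100)
  expect_true(all(psd$power >= 0))
  expect_equal(range(psd$freq), c(0, 50))
})

test_that("multitaper spectrum of white noise is flat across bands", {
  set.seed(42)
  n_epochs <- 500
  d_alpha <- d_beta <- numeric(n_epochs)
  for (i in seq_len(n_epochs)) {
    psd <- multitaper_psd(rnorm(450), 250)
    d_alpha[i] <- mean(psd$power[psd$freq >= 8 & psd$freq <= 12])
    d_beta[i] <- mean(psd$power[psd$freq >= 13 & psd$freq <= 17])
  }
  diff_mean <- mean(d_alpha) - mean(d_beta)
  se <- sd(d_alpha - d_beta) / sqrt(n_epochs)
  expect_lt(abs(diff_mean), 3 * se)
})

test_that("band power normalizes by the global-spectrum mean", {
  flat <- list(freq = 1:40, power = rep(2.5, 40))
  expect_equal(band_power(flat, c(8, 12)), 1)
  expect_equal(band_power(flat, c(13, 17)), 1)

  # 40 global bins averaging 0.8, all power in 4 alpha bins of value 8
  toy <- list(freq = 1:40, power = c(rep(0, 8), rep(8, 4), rep(0, 28)))
  expect_equal(mean(toy$power), 0.8)
  expect_equal(band_power(toy, c(9, 12), global = c(1, 40)), 10)

  expect_error(band_power(list(freq = 1:40, power = rep(0, 40)), c(8, 12)),
               "zero")
  expect_error(band_power(flat, c(30, 60)), "Nyquist")
})

test_that("vectorized per-epoch band power equals the per-epoch reference", {
  cfg <- tiny_config(n_epochs = 40)
  lat <- simulate_latent_state(40, 0.02, 1.8, seed = 8)
  eeg <- simulate_eeg(lat, cfg, seed = 9)
  for (strip in c(FALSE, TRUE)) {
    e <- eeg
    if (strip) attr(e, "sample_major") <- NULL   # array-layout code path
    bp <- epoch_band_power(e, eeg_bands())
    for (ch in c(1, 4)) {
      for (ep in c(1, 17, 40)) {
        psd <- multitaper_psd(e$data[ch, ep, ], e$fs)
        for (b in names(eeg_bands())) {
          expect_equal(bp[ch, ep, b], band_power(psd, eeg_bands()[[b]]),
                       tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("normalized power is invariant to rescaling the raw signal", {
  cfg <- tiny_config(n_epochs = 40)
  lat <- simulate_latent_state(40, 0.02, 1.8, seed = 18)
  eeg <- simulate_eeg(lat, cfg, seed = 19)
  bp1 <- epoch_band_power(eeg, eeg_bands())
  eeg2 <- epoched_eeg(eeg$data * 37.5, eeg$fs, eeg$channels, eeg$tr)
  bp2 <- epoch_band_power(eeg2, eeg_bands())
  expect_equal(bp1, bp2, tolerance = 1e-12)
})

test_that("channel pooling averages the requested channels and flags absentees", {
  m <- matrix(rep(c(1, 3), each = 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("P4", "O2"), NULL))
  expect_equal(pool_channels(m, c("P4", "O2")), rep(2, 5))
  expect_equal(pool_channels(m, c("P4", "P4")), rep(1, 5))
  expect_error(pool_channels(m, c("P4", "Oz9")), "Oz9")
})

test_that("window smoothing is a normalized taper-weighted average", {
  scheme <- make_window_scheme(306)
  expect_equal(smooth_power_series(rep(3.2, 306), scheme), rep(3.2, 247),
               tolerance = 1e-12)
  expect_length(smooth_power_series(rnorm(306), scheme), 247)

  # unit impulse at the centre of the first window
  x <- numeric(306)
  centre <- 30                       # nearest index to (60 - 1) / 2 + 1
  x[centre] <- 1
  sm <- smooth_power_series(x, scheme)
  expect_equal(sm[1], scheme$taper[centre] / sum(scheme$taper),
               tolerance = 1e-12)
  expect_error(smooth_power_series(rnorm(100), scheme), "expects 306")
})

test_that("pooling and smoothing commute", {
  cfg <- tiny_config(n_epochs = 80)
  lat <- simulate_latent_state(80, 0.02, 1.8, seed = 28)
  eeg <- suppressWarnings(simulate_eeg(lat, cfg, seed = 29))
  scheme <- make_window_scheme(80, tr = 1.8)
  bp <- epoch_band_power(eeg, list(alpha = c(8, 12)))
  pool_then_smooth <- smooth_power_series(pool_channels(bp)[, 1], scheme)
  by_channel <- apply(bp[, , 1], 1, smooth_power_series, scheme = scheme)
  smooth_then_pool <- rowMeans(by_channel)
  expect_equal(pool_then_smooth, smooth_then_pool, tolerance = 1e-12)
})

test_that("epoched EEG container validates its geometry", {
  arr <- array(0, dim = c(2, 3, 144))
  expect_error(epoched_eeg(arr, 80, c("A", "B", "C"), 1.8), "channel")
  expect_error(epoched_eeg(arr, 80, c("A", "A"), 1.8), "unique")
  expect_error(epoched_eeg(arr, 100, c("A", "B"), 1.8), "round\\(fs")
  arr[1, 1, 1] <- NA
  expect_error(epoched_eeg(arr, 80, c("A", "B"), 1.8), "missing")
})
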