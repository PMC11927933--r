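# Latent-state generator and the EEG/BOLD study simulator.

test_that("latent state is standardized, slow, and seed-deterministic", {
  s1 <- simulate_latent_state(306, 0.02, 1.8, seed = 1)
  s2 <- simulate_latent_state(306, 0.02, 1.8, seed = 1)
  expect_identical(s1, s2)
  expect_equal(mean(s1), 0, tolerance = 1e-12)
  expect_equal(sd(s1), 1, tolerance = 1e-12)

  # spectral power concentrated below the cutoff (periodogram oracle)
  for (seed in c(2, 17, 99)) {
    s <- simulate_latent_state(306, 0.02, 1.8, seed = seed)
    pg <- periodogram_oracle(s, fs = 1 / 1.8)
    frac <- sum(pg$power[pg$freq <= 0.02]) / sum(pg$power)
    expect_gt(frac, 0.9)
  }
})

test_that("latent state rejects empty input and bad cutoffs", {
  expect_error(simulate_latent_state(0, 0.02, 1.8), ">= 8")
  expect_error(simulate_latent_state(306, 0.5, 1.8), "Nyquist")
  expect_error(simulate_latent_state(10, 0.001, 1.8), "resolution")
})

test_that("simulated BOLD is seed-deterministic and rho tracks the latent linearly", {
  cfg <- tiny_config(base_correlation = 0, coupling_gain_bold = 0.2)
  lat <- simulate_latent_state(100, 0.02, 1.8, seed = 3)
  b1 <- simulate_bold(lat, cfg, "active", "post", seed = 4)
  b2 <- simulate_bold(lat, cfg, "active", "post", seed = 4)
  expect_identical(b1$ts$values, b2$ts$values)
  # unclipped modulation is an exact linear map of the latent state
  expect_equal(b1$truth$n_clipped, 0)
  expect_equal(cor(b1$truth$true_rho[, 1], lat), 1, tolerance = 1e-12)
  expect_true(all(abs(b1$truth$true_rho) < 1))
})

test_that("extreme modulation is clipped with a warning and recorded", {
  cfg <- tiny_config(coupling_gain_bold = 2)
  lat <- simulate_latent_state(100, 0.02, 1.8, seed = 5)
  expect_warning(b <- simulate_bold(lat, cfg, "active", "post", seed = 6),
                 "clipped")
  expect_gt(b$truth$n_clipped, 0)
  expect_true(all(abs(b$truth$true_rho) <= 0.99))
})

test_that("with zero effect the windowed FC is uncoupled from the latent state", {
  cfg <- tiny_config(n_epochs = 306)
  scheme <- make_window_scheme(306, tr = 1.8)
  set.seed(11)
  seeds <- matrix(sample.int(1e7, 2 * 150), ncol = 2)
  r <- vapply(seq_len(150), function(i) {
    lat <- simulate_latent_state(306, 0.02, 1.8, seeds[i, 1])
    b <- simulate_bold(lat, cfg, "active", "pre", seeds[i, 2])  # multiplier 0
    fc <- fc_timeseries(b$ts, scheme, pairs = rbind(c("vPCC", "lAG")))
    cor(fc$values[, 1], smooth_power_series(lat, scheme))
  }, 1)
  # the smoothed series leave few effective dof, so individual r values are
  # wide; the mean over seeds must still be within ~3 standard errors of 0
  expect_lt(abs(mean(r)), 3.5 * sd(r) / sqrt(length(r)))
})

test_that("alpha power tracks the latent state if and only if gamma > 0", {
  set.seed(21)
  seeds <- matrix(sample.int(1e7, 2 * 100), ncol = 2)
  mean_r <- function(gamma, env_sd) {
    cfg <- tiny_config(coupling_gain_alpha = gamma, rhythm_env_sd = env_sd)
    mean(vapply(seq_len(100), function(i) {
      lat <- simulate_latent_state(100, 0.02, 1.8, seeds[i, 1])
      eeg <- suppressWarnings(simulate_eeg(lat, cfg, seed = seeds[i, 2]))
      p <- pool_channels(epoch_band_power(eeg, list(alpha = c(8, 12))))
      cor(p[, 1], lat)
    }, 1))
  }
  # without the slow background envelopes the per-epoch noise is white and the
  # zero-gamma mean correlation is tightly bounded
  expect_lt(abs(mean_r(0, env_sd = 0)), 0.03)
  expect_gt(mean_r(0.5, env_sd = 0.3), 0.5)
})

test_that("noise-free constant-gain EEG has constant alpha power up to phase effects", {
  cfg <- tiny_config(coupling_gain_alpha = 0, pink_sd = 0, theta_amp = 0,
                     beta_amp = 0)
  lat <- simulate_latent_state(100, 0.02, 1.8, seed = 31)
  eeg <- simulate_eeg(lat, cfg, seed = 32)
  p <- pool_channels(epoch_band_power(eeg, list(alpha = c(8, 12))))[, 1]
  expect_lt(sd(p) / mean(p), 0.05)
})

test_that("amplitude flooring warns when gamma drives the gain negative", {
  cfg <- tiny_config(coupling_gain_alpha = 3)
  lat <- simulate_latent_state(100, 0.02, 1.8, seed = 41)
  expect_warning(simulate_eeg(lat, cfg, seed = 42), "floor")
})

test_that("study design matches the two-group two-session layout", {
  des <- study_design(sim_config())
  expect_equal(nrow(des), 64)  # 16 active + 16 sham subjects, 2 sessions each
  expect_equal(sum(des$group == "active" & des$session == "post"), 16)
  expect_equal(sum(des$group == "sham"), 32)

  st <- suppressWarnings(simulate_study(tiny_config(seed = 7)))
  expect_equal(length(st$sessions), 8)  # 2 per group x 2 sessions
  expect_s3_class(st$sessions[[1]]$bold, "roi_timeseries")
  expect_s3_class(st$sessions[[1]]$eeg, "epoched_eeg")
})

test_that("a fixed seed reproduces the study bundle bit for bit", {
  cfg <- tiny_config(n_subjects_per_group = 1, seed = 13)
  s1 <- suppressWarnings(simulate_study(cfg))
  s2 <- suppressWarnings(simulate_study(cfg))
  expect_identical(s1$design, s2$design)
  for (k in names(s1$sessions)) {
    expect_identical(s1$sessions[[k]]$bold$values, s2$sessions[[k]]$bold$values)
    expect_identical(s1$sessions[[k]]$eeg$data, s2$sessions[[k]]$eeg$data)
  }
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(eeg_fs = 83), "integer number of samples")
  expect_error(sim_config(base_correlation = 1), "-1, 1")
  expect_error(sim_config(target_pairs = list(c("vPCC", "nope"))), "unknown ROI")
  expect_error(sim_config(channels = c("P4", "O2")), "occipitoparietal")
  expect_error(sim_config(latent_cutoff_hz = 0.3), "Nyquist")
})
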