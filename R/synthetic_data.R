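#' Simulation configuration
#'
#' Parameters of the latent-state study generator. A single slow latent state
#' `s(t)` (one per session) drives both the instantaneous BOLD correlation of
#' the target ROI pairs, `rho(t) = base + m * beta * s(t)`, and the epoch-wise
#' alpha amplitude, `a(t) = a0 * (1 + gamma * s(t))`, where `m` is the
#' group-by-session multiplier. Coupling between windowed connectivity and
#' alpha power therefore appears exactly where `m * beta * gamma != 0`.
#'
#' The EEG background is 1/f (pink) noise plus theta and low-beta rhythms
#' whose amplitudes fluctuate slowly and independently of the latent state, so
#' the global-spectrum normalization and the frequency-specificity of the
#' analysis are exercised non-trivially.
#'
#' @param n_subjects_per_group Subjects per group (active, sham).
#' @param n_epochs Epochs (TRs) per session.
#' @param tr Repetition time in seconds.
#' @param eeg_fs EEG sampling rate in Hz; `eeg_fs * tr` must be an integer.
#' @param roi_networks Named character vector mapping ROI labels to networks.
#' @param base_correlation Baseline pairwise BOLD correlation, in (-1, 1).
#' @param coupling_gain_bold Latent-to-connectivity gain `beta`.
#' @param coupling_gain_alpha Latent-to-alpha-amplitude gain `gamma`.
#' @param target_pairs List of ROI pairs whose connectivity tracks the latent
#'   state.
#' @param session_effects List `list(active = c(pre=, post=), sham = ...)` of
#'   multipliers applied to `beta` per group and session.
#' @param noise_sd BOLD measurement noise SD added after correlation mixing.
#' @param latent_cutoff_hz Low-pass cutoff of the latent state (and of the
#'   rhythm envelopes), in Hz.
#' @param alpha_amp Alpha sinusoid base amplitude `a0` (microvolts).
#' @param alpha_floor Amplitude floor as a fraction of `alpha_amp`.
#' @param pink_sd Pink-noise SD per sample (microvolts).
#' @param theta_amp,beta_amp Amplitudes of the background theta and low-beta
#'   rhythms (microvolts).
#' @param rhythm_freqs Frequencies (Hz) of the alpha, theta and beta
#'   sinusoids.
#' @param rhythm_env_sd SD of the slow multiplicative envelope on the theta
#'   and beta rhythms.
#' @param channels EEG channel labels to synthesize; must include the pooled
#'   occipitoparietal set.
#' @param seed Base seed for [simulate_study()].
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_subjects_per_group = 16,
                       n_epochs = 306,
                       tr = 1.8,
                       eeg_fs = 250,
                       roi_networks = default_roi_networks(),
                       base_correlation = 0.3,
                       coupling_gain_bold = 0.4,
                       coupling_gain_alpha = 0.5,
                       target_pairs = list(c("vPCC", "lAG"), c("vPCC", "rAG")),
                       session_effects = list(active = c(pre = 0, post = 1),
                                              sham = c(pre = 0, post = -0.25)),
                       noise_sd = 0.3,
                       latent_cutoff_hz = 0.02,
                       alpha_amp = 4,
                       alpha_floor = 0.05,
                       pink_sd = 10,
                       theta_amp = 10,
                       beta_amp = 8,
                       rhythm_freqs = c(alpha = 10, theta = 5.5, beta = 15),
                       rhythm_env_sd = 0.3,
                       channels = c(alpha_channels(), "O1", "P3"),
                       seed = 1) {
  cfg <- list(n_subjects_per_group = n_subjects_per_group,
              n_epochs = n_epochs, tr = tr, eeg_fs = eeg_fs,
              roi_networks = roi_networks,
              base_correlation = base_correlation,
              coupling_gain_bold = coupling_gain_bold,
              coupling_gain_alpha = coupling_gain_alpha,
              target_pairs = target_pairs,
              session_effects = session_effects,
              noise_sd = noise_sd,
              latent_cutoff_hz = latent_cutoff_hz,
              alpha_amp = alpha_amp, alpha_floor = alpha_floor,
              pink_sd = pink_sd, theta_amp = theta_amp, beta_amp = beta_amp,
              rhythm_freqs = rhythm_freqs, rhythm_env_sd = rhythm_env_sd,
              channels = channels, seed = seed)
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg A `sim_config` candidate list.
#' @export
validate_sim_config <- function(cfg) {
  # normalize containers that may arrive as plain lists (e.g. from YAML)
  cfg$roi_networks <- unlist(cfg$roi_networks)
  cfg$target_pairs <- lapply(cfg$target_pairs, unlist)
  cfg$session_effects <- lapply(cfg$session_effects, unlist)
  cfg$rhythm_freqs <- unlist(cfg$rhythm_freqs)
  cfg$channels <- unlist(cfg$channels)
  stopifnot(cfg$n_subjects_per_group >= 1, cfg$n_epochs >= 8, cfg$tr > 0)
  if (abs(cfg$eeg_fs * cfg$tr - round(cfg$eeg_fs * cfg$tr)) > 1e-9) {
    stop("`eeg_fs * tr` must be an integer number of samples per epoch",
         call. = FALSE)
  }
  if (abs(cfg$base_correlation) >= 1) {
    stop("`base_correlation` must lie in (-1, 1)", call. = FALSE)
  }
  if (cfg$latent_cutoff_hz >= 1 / (2 * cfg$tr)) {
    stop("`latent_cutoff_hz` must be below the epoch-rate Nyquist frequency ",
         signif(1 / (2 * cfg$tr), 4), " Hz", call. = FALSE)
  }
  rois <- names(cfg$roi_networks)
  for (p in cfg$target_pairs) {
    if (!all(p %in% rois)) {
      stop("target pair ", paste(p, collapse = "-"),
           " refers to unknown ROI(s)", call. = FALSE)
    }
  }
  if (!all(c("active", "sham") %in% names(cfg$session_effects))) {
    stop("`session_effects` must name both groups", call. = FALSE)
  }
  for (g in c("active", "sham")) {
    if (!all(c("pre", "post") %in% names(cfg$session_effects[[g]]))) {
      stop("`session_effects$", g, "` must name both sessions", call. = FALSE)
    }
  }
  missing <- setdiff(alpha_channels(), cfg$channels)
  if (length(missing)) {
    stop("`channels` must include the pooled occipitoparietal set; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate the slow latent state of a session
#'
#' Low-pass filtered Gaussian white noise, re-standardized to mean 0 and SD 1.
#' Filtering is exact in the frequency domain: all Fourier coefficients above
#' `cutoff_hz` (and the DC term) are zeroed, so essentially all spectral power
#' lies below the cutoff.
#'
#' @param n_epochs Number of epochs (>= 8).
#' @param cutoff_hz Low-pass cutoff in Hz; must be below the epoch-rate
#'   Nyquist `1 / (2 tr)` and at or above the frequency resolution
#'   `1 / (n_epochs * tr)`.
#' @param tr Epoch duration (TR) in seconds.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n_epochs`, mean 0, SD 1.
#' @export
simulate_latent_state <- function(n_epochs, cutoff_hz = 0.02, tr = 1.8,
                                  seed = NULL) {
  if (length(n_epochs) != 1 || n_epochs < 8 || n_epochs != round(n_epochs)) {
    stop("`n_epochs` must be a single integer >= 8", call. = FALSE)
  }
  if (cutoff_hz >= 1 / (2 * tr)) {
    stop("`cutoff_hz` (", cutoff_hz, " Hz) is at or above the epoch-rate ",
         "Nyquist frequency ", signif(1 / (2 * tr), 4), " Hz", call. = FALSE)
  }
  if (cutoff_hz < 1 / (n_epochs * tr)) {
    stop("`cutoff_hz` is below the frequency resolution ",
         signif(1 / (n_epochs * tr), 4), " Hz; no fluctuation survives",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_epochs)
  j <- 0:(n - 1)
  f <- ifelse(j <= n / 2, j, j - n) / (n * tr)
  keep <- abs(f) <= cutoff_hz & j != 0
  co <- stats::fft(stats::rnorm(n))
  co[!keep] <- 0
  s <- Re(stats::fft(co, inverse = TRUE)) / n
  as.numeric((s - mean(s)) / stats::sd(s))
}

# equicorrelation matrix with per-pair overrides; ia/ib are column indices of
# the target pairs
.corr_matrix <- function(p, base, ia, ib, rho) {
  R <- matrix(base, p, p)
  diag(R) <- 1
  if (length(ia)) {
    R[cbind(ia, ib)] <- rho
    R[cbind(ib, ia)] <- rho
  }
  R
}

# Cholesky factor with a nearest-PSD fallback (eigenvalue clipping followed by
# diagonal renormalization)
.safe_chol <- function(R) {
  U <- tryCatch(chol(R), error = function(e) NULL)
  if (!is.null(U)) return(U)
  ev <- eigen(R, symmetric = TRUE)
  lam <- pmax(ev$values, 1e-6)
  R2 <- ev$vectors %*% (lam * t(ev$vectors))
  d <- 1 / sqrt(diag(R2))
  R2 <- R2 * tcrossprod(d)
  chol(R2)
}

#' Simulate a session of ROI BOLD timeseries
#'
#' Draws, for each TR, a correlated Gaussian vector across the ROIs whose
#' instantaneous correlation matrix has the configured base correlation
#' everywhere and `rho(t) = base + m * beta * s(t)` on the target pairs
#' (`m` = the group/session multiplier). Mixing uses a per-TR Cholesky factor
#' of the (clipped, PSD-safe) correlation matrix; measurement noise is added
#' and the result is band-limited to 0.01-0.08 Hz.
#'
#' @param latent Latent state series from [simulate_latent_state()].
#' @param config A [sim_config()].
#' @param group `"active"` or `"sham"`.
#' @param session `"pre"` or `"post"`.
#' @param seed Optional integer seed.
#' @return List with `ts` (a [roi_timeseries]) and `truth` (latent state,
#'   per-epoch target-pair correlations after clipping, clip count, effect
#'   size and its sign).
#' @export
simulate_bold <- function(latent, config, group = "active", session = "pre",
                          seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (length(latent) != config$n_epochs) {
    stop("`latent` must have length n_epochs = ", config$n_epochs,
         call. = FALSE)
  }
  if (!group %in% names(config$session_effects)) {
    stop("unknown group \"", group, "\"", call. = FALSE)
  }
  m <- config$session_effects[[group]][[session]]
  if (is.null(m) || is.na(m)) {
    stop("no session effect configured for ", group, "/", session,
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  eff <- config$coupling_gain_bold * m
  labels <- names(config$roi_networks)
  p <- length(labels)
  n <- config$n_epochs
  ia <- vapply(config$target_pairs, function(q) match(q[1], labels), 1L)
  ib <- vapply(config$target_pairs, function(q) match(q[2], labels), 1L)
  rho_raw <- outer(latent, rep(eff, length(ia))) + config$base_correlation
  rho <- rho_raw
  rho[rho > 0.99] <- 0.99
  rho[rho < -0.99] <- -0.99
  n_clipped <- sum(rho != rho_raw)
  if (n_clipped > 0) {
    warning(n_clipped, " instantaneous correlation value(s) clipped to |0.99|",
            call. = FALSE)
  }
  Z <- matrix(stats::rnorm(n * p), n, p)
  if (eff == 0) {
    U <- .safe_chol(.corr_matrix(p, config$base_correlation, ia, ib, rho[1, ]))
    Y <- Z %*% U
  } else {
    R0 <- .corr_matrix(p, config$base_correlation, integer(), integer(),
                       numeric())
    Y <- cpp_tv_chol_mix(R0, as.integer(ia), as.integer(ib), rho, Z)
  }
  if (config$noise_sd > 0) {
    Y <- Y + config$noise_sd * stats::rnorm(n * p)
  }
  colnames(Y) <- labels
  ts <- roi_timeseries(Y, networks = config$roi_networks, tr = config$tr)
  ts <- bandpass_filter(ts, 0.01, 0.08)
  colnames(rho) <- vapply(config$target_pairs, paste, "", collapse = "~")
  list(ts = ts,
       truth = list(latent = latent, true_rho = rho, n_clipped = n_clipped,
                    effect = eff, coupling_sign = sign(eff)))
}

# cached pink-noise synthesis bases (cos and sin, samples x n_harmonics),
# scaled so the synthesized series has unit variance per sample
.pink_basis <- function(n, fs) {
  key <- sprintf("pink_%d_%g", n, fs)
  .cache_get(key, function() {
    jmax <- ceiling(n / 2) - 1L
    j <- seq_len(jmax)
    g <- 1 / sqrt(j * fs / n)
    t <- 0:(n - 1)
    ang <- 2 * pi * outer(t, j) / n
    gs <- g / sqrt(sum(g^2))
    list(C = cos(ang) * rep(gs, each = n), S = sin(ang) * rep(gs, each = n))
  })
}

#' Simulate a session of epoched EEG
#'
#' Each epoch of each pooled occipitoparietal channel carries a 10 Hz alpha
#' sinusoid with amplitude `a0 * (1 + gamma * s(t))`, clipped at a small
#' positive floor, with an independent random phase per channel and epoch. All
#' channels additionally carry 1/f (pink) background noise and theta and
#' low-beta rhythms whose amplitudes follow slow envelopes independent of the
#' latent state.
#'
#' @inheritParams simulate_bold
#' @return An [epoched_eeg] with a `sim_truth` attribute (per-epoch alpha
#'   amplitude and the number of floor-clipped epochs).
#' @export
simulate_eeg <- function(latent, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (length(latent) != config$n_epochs) {
    stop("`latent` must have length n_epochs = ", config$n_epochs,
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  nep <- config$n_epochs
  fs <- config$eeg_fs
  N <- round(fs * config$tr)
  channels <- config$channels
  nch <- length(channels)
  cols <- nch * nep
  gamma <- config$coupling_gain_alpha

  raw_gain <- 1 + gamma * latent
  low <- raw_gain < config$alpha_floor
  clipped <- sum(low)
  if (clipped > 0) {
    warning("alpha amplitude floor-clipped in ", clipped,
            " epoch(s); |gamma * s| reached 1", call. = FALSE)
    raw_gain[low] <- config$alpha_floor
  }
  amp <- config$alpha_amp * raw_gain

  # slow amplitude envelopes of the background rhythms, independent of s(t)
  sub_seeds <- sample.int(.Machine$integer.max - 1, 2)
  env <- function(sd_env, sd_seed) {
    if (config$rhythm_env_sd == 0) return(rep(1, nep))
    u <- 1 + sd_env * simulate_latent_state(nep, config$latent_cutoff_hz,
                                            config$tr, sd_seed)
    u[u < 0.1] <- 0.1
    u
  }
  env_theta <- env(config$rhythm_env_sd, sub_seeds[1])
  env_beta <- env(config$rhythm_env_sd, sub_seeds[2])

  # columns ordered channel-fastest within epoch
  ch_of <- rep(seq_len(nch), nep)
  ep_of <- rep(seq_len(nep), each = nch)
  posterior <- channels %in% alpha_channels()

  # random-phase 1/f surrogate background: every harmonic has deterministic
  # amplitude g_j and an independent uniform phase per channel and epoch
  # (Gaussian-like by aggregation across harmonics)
  B <- .pink_basis(N, fs)
  tsec <- (0:(N - 1)) / fs
  M1 <- matrix(0, N, 6)
  for (i in 1:3) {
    f <- config$rhythm_freqs[[c("alpha", "theta", "beta")[i]]]
    M1[, 2 * i - 1] <- sin(2 * pi * f * tsec)
    M1[, 2 * i] <- cos(2 * pi * f * tsec)
  }
  AMP <- rbind(
    alpha = amp[ep_of] * posterior[ch_of],
    theta = config$theta_amp * env_theta[ep_of],
    beta = config$beta_amp * env_beta[ep_of]
  )
  X <- cpp_eeg_signal_matrix(B$C, B$S, config$pink_sd, M1, AMP)
  arr <- cpp_to_epoch_array(X, nch, nep)
  dimnames(arr) <- list(channels, NULL, NULL)
  eeg <- epoched_eeg(arr, fs = fs, channels = channels, tr = config$tr)
  # sample-major copy of the data, reused by the spectral kernels
  attr(eeg, "sample_major") <- X
  attr(eeg, "sim_truth") <- list(alpha_amp = amp, n_floor_clipped = clipped)
  eeg
}

# simulate one subject-session (shared by simulate_study and run_study)
.simulate_session <- function(config, group, session, seeds) {
  latent <- simulate_latent_state(config$n_epochs, config$latent_cutoff_hz,
                                  config$tr, seeds[1])
  bold <- simulate_bold(latent, config, group, session, seeds[2])
  eeg <- simulate_eeg(latent, config, seeds[3])
  truth <- bold$truth
  truth$alpha_amp <- attr(eeg, "sim_truth")$alpha_amp
  truth$n_floor_clipped <- attr(eeg, "sim_truth")$n_floor_clipped
  list(bold = bold$ts, eeg = eeg, truth = truth)
}

# deterministic per-session seed table for a study
.study_seeds <- function(config) {
  set.seed(config$seed)
  nsub <- 2 * config$n_subjects_per_group
  matrix(sample.int(.Machine$integer.max - 1, nsub * 2 * 3),
         nrow = nsub * 2, ncol = 3)
}

#' Study design table
#'
#' @param config A [sim_config()].
#' @return Tibble with one row per subject and session (`subject`, `group`,
#'   `session`).
#' @export
study_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nsub <- 2 * config$n_subjects_per_group
  subjects <- sprintf("sub-%02d", seq_len(nsub))
  groups <- rep(c("active", "sham"), each = config$n_subjects_per_group)
  tibble::tibble(
    subject = rep(subjects, each = 2),
    group = rep(groups, each = 2),
    session = rep(c("pre", "post"), nsub)
  )
}

#' Simulate a complete two-group, two-session study
#'
#' Generates, for every subject and session, the latent state, the BOLD ROI
#' timeseries and the epoched EEG, with the configured group-by-session
#' coupling multipliers (by default: coupling present only in active-post,
#' with a slight negative drift in sham-post). All randomness derives from
#' `config$seed`, so a fixed seed reproduces the bundle bit for bit.
#'
#' Note the full default study holds roughly half a gigabyte of EEG; use
#' [run_study()] to analyze sessions without materializing them all.
#'
#' @param config A [sim_config()].
#' @return A `sim_study`: list with `design` (tibble), `sessions` (named list
#'   `"<subject>_<session>"` of `bold`, `eeg`, `truth`), and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  design <- study_design(config)
  seeds <- .study_seeds(config)
  sessions <- vector("list", nrow(design))
  names(sessions) <- paste(design$subject, design$session, sep = "_")
  for (i in seq_len(nrow(design))) {
    sessions[[i]] <- .simulate_session(config, design$group[i],
                                       design$session[i], seeds[i, ])
  }
  structure(list(design = design, sessions = sessions, config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("Simulated study: %d subjects x 2 sessions (%d epochs, TR %g s)\n",
              2 * x$config$n_subjects_per_group, x$config$n_epochs,
              x$config$tr))
  invisible(x)
}
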