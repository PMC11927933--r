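# Independent oracles and small fixtures shared across the suite.

# Brute-force Benjamini-Hochberg step-up: adjusted p_(i) = min over j >= i of
# p_(j) * m / j, capped at 1, mapped back to the input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Textbook pooled-variance two-sample t statistic.
pooled_t_oracle <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), nx + ny - 2))
}

# Least-squares amplitude of a sinusoid of known frequency in a series.
fit_sinusoid_amp <- function(y, freq_hz, tr) {
  t <- (seq_along(y) - 1) * tr
  X <- cbind(sin(2 * pi * freq_hz * t), cos(2 * pi * freq_hz * t))
  sqrt(sum(qr.solve(X, y)^2))
}

# Raw FFT periodogram (one-sided) of a demeaned series.
periodogram_oracle <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  nf <- floor(n / 2) + 1
  list(freq = (seq_len(nf) - 1) * fs / n,
       power = Mod(fft(x)[seq_len(nf)])^2)
}

# Small, fast simulation configuration for Monte-Carlo unit tests.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects_per_group = 2, n_epochs = 100, eeg_fs = 80,
         channels = alpha_channels()),
    list(...)
  )
  do.call(sim_config, args)
}

# Simulate one session without clipping warnings.
quiet_session <- function(config, group, session, seeds) {
  withCallingHandlers(
    dyncouple:::.simulate_session(config, group, session, seeds),
    warning = function(w) {
      if (grepl("clipped", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  )
}

# A small deterministic coupling table with complete pre/post records.
toy_coupling <- function(z_pre, z_post, groups) {
  n <- length(z_pre)
  subjects <- sprintf("s%02d", seq_len(n))
  tibble::tibble(
    subject = rep(subjects, 2),
    group = rep(groups, 2),
    session = rep(c("pre", "post"), each = n),
    band = "alpha", roi_a = "vPCC", roi_b = "lAG", pair_set = "intra_dmn",
    lag = 0L, r = tanh(c(z_pre, z_post)), z = c(z_pre, z_post),
    n_windows = 247L
  )
}
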