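#' Epoched EEG container
#'
#' Wraps a channels x epochs x samples array of EEG values (microvolts) with
#' its sampling rate and channel labels. Epochs are one TR long and centred on
#' the TR onsets, so epoch `e` is aligned with BOLD volume `e`.
#'
#' @param data Numeric array `[channel, epoch, sample]`.
#' @param fs Sampling rate in Hz.
#' @param channels Character vector of unique channel labels.
#' @param tr Repetition time in seconds; `round(fs * tr)` must equal the
#'   sample dimension.
#' @return An `epoched_eeg` object.
#' @export
epoched_eeg <- function(data, fs, channels, tr) {
  if (length(dim(data)) != 3) {
    stop("`data` must be a 3-d array [channel, epoch, sample]", call. = FALSE)
  }
  if (dim(data)[1] != length(channels)) {
    stop("channel dimension (", dim(data)[1], ") does not match the ",
         length(channels), " channel labels", call. = FALSE)
  }
  if (anyDuplicated(channels)) stop("channel labels must be unique", call. = FALSE)
  if (dim(data)[3] != round(fs * tr)) {
    stop("samples per epoch (", dim(data)[3], ") must equal round(fs * tr) = ",
         round(fs * tr), call. = FALSE)
  }
  if (anyNA(data)) stop("`data` contains missing values", call. = FALSE)
  if (is.null(dimnames(data)[[1]])) dimnames(data)[[1]] <- channels
  structure(list(data = data, fs = fs, channels = channels, tr = tr,
                 n_epochs = dim(data)[2], n_samples = dim(data)[3]),
            class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  cat(sprintf("Epoched EEG: %d channels x %d epochs x %d samples (fs %g Hz, TR %g s)\n",
              length(x$channels), x$n_epochs, x$n_samples, x$fs, x$tr))
  invisible(x)
}

#' Canonical band limits
#'
#' Alpha 8-12 Hz, theta 4-7 Hz, low beta 13-17 Hz. Band membership is
#' inclusive at both edges. The normalization reference is the global
#' spectrum, 1-40 Hz ([global_band()]).
#'
#' @return Named list of `c(lo, hi)` limits in Hz.
#' @export
eeg_bands <- function() {
  list(alpha = c(8, 12), theta = c(4, 7), beta = c(13, 17))
}

#' @rdname eeg_bands
#' @export
global_band <- function() c(1, 40)

#' Right occipitoparietal channel set pooled for alpha power
#' @return Character vector of channel labels.
#' @export
alpha_channels <- function() c("P4", "P6", "P8", "PO4", "PO8", "O2")

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `n_tapers` DPSS tapers for `n_samples` points at
#' time-bandwidth product `nw`, via the eigenvectors of the classical
#' symmetric tridiagonal matrix whose eigenvectors are the Slepian sequences.
#' Tapers are normalized to unit energy and cached per `(n, nw, k)`.
#'
#' @param n_samples Number of samples per epoch.
#' @param nw Time-bandwidth product (default 2, pairing with 3 tapers as
#'   `k = 2 nw - 1`).
#' @param n_tapers Number of tapers to return.
#' @return `n_samples` x `n_tapers` matrix, columns ordered by decreasing
#'   spectral concentration.
#' @export
dpss_tapers <- function(n_samples, nw = 2, n_tapers = 3) {
  stopifnot(n_samples >= 8, n_tapers >= 1, nw > 0)
  if (n_tapers > 2 * nw) {
    warning("n_tapers > 2*nw - 1: trailing tapers are poorly concentrated",
            call. = FALSE)
  }
  key <- sprintf("dpss_%d_%g_%d", n_samples, nw, n_tapers)
  .cache_get(key, function() {
    n <- n_samples
    w <- nw / n
    i <- 0:(n - 1)
    diag_main <- (((n - 1) - 2 * i) / 2)^2 * cos(2 * pi * w)
    off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
    M <- diag(diag_main)
    M[cbind(1:(n - 1), 2:n)] <- off
    M[cbind(2:n, 1:(n - 1))] <- off
    ev <- eigen(M, symmetric = TRUE)
    v <- ev$vectors[, seq_len(n_tapers), drop = FALSE]
    # polarity convention: symmetric tapers have positive mean, antisymmetric
    # ones a positive initial slope
    for (k in seq_len(n_tapers)) {
      s <- sum(v[, k])
      if (abs(s) < 1e-8) s <- v[2, k] - v[1, k]
      if (s < 0) v[, k] <- -v[, k]
    }
    v
  })
}

#' Multitaper power spectral density of one epoch
#'
#' Averages the eigenspectra of the epoch multiplied by `n_tapers` DPSS
#' tapers. The epoch mean is removed first; no further detrending is applied.
#' The spectrum is one-sided (interior bins doubled) on the grid
#' `f_j = j * fs / n`, `j = 0 .. floor(n/2)`. An all-zero epoch yields an
#' all-zero PSD.
#'
#' @param epoch Numeric vector of samples (length >= 8).
#' @param fs Sampling rate in Hz.
#' @param n_tapers Number of DPSS tapers (default 3).
#' @param nw Time-bandwidth product (default 2); the spectral bandwidth is
#'   about `nw / (n / fs)` Hz.
#' @return List with `freq` (Hz) and `power` (uV^2/Hz, non-negative).
#' @export
multitaper_psd <- function(epoch, fs, n_tapers = 3, nw = 2) {
  n <- length(epoch)
  if (n < 8) stop("epoch must have at least 8 samples", call. = FALSE)
  if (n_tapers < 1) stop("`n_tapers` must be >= 1", call. = FALSE)
  nf <- floor(n / 2) + 1L
  freq <- (seq_len(nf) - 1) * fs / n
  if (all(epoch == 0)) {
    return(list(freq = freq, power = numeric(nf)))
  }
  x <- epoch - mean(epoch)
  v <- dpss_tapers(n, nw = nw, n_tapers = n_tapers)
  acc <- numeric(nf)
  for (k in seq_len(n_tapers)) {
    X <- stats::fft(v[, k] * x)
    acc <- acc + Mod(X[seq_len(nf)])^2
  }
  p <- acc / (n_tapers * fs)
  p <- p * .onesided_scale(n, nf)
  list(freq = freq, power = p)
}

# doubling factors for a one-sided spectrum of an n-point real series
.onesided_scale <- function(n, nf) {
  s <- rep(2, nf)
  s[1] <- 1
  if (n %% 2 == 0) s[nf] <- 1
  s
}

#' Normalized band power from a PSD
#'
#' Mean PSD over the band's frequency bins (inclusive at both edges) divided
#' by the mean PSD over the global reference band, making the result
#' dimensionless and invariant to any rescaling of the raw signal.
#'
#' @param psd List with `freq` and `power`, as from [multitaper_psd()].
#' @param band `c(lo, hi)` in Hz with `0 < lo < hi <= max(freq)`.
#' @param global `c(lo, hi)` reference band (default 1-40 Hz).
#' @return Normalized band power (single non-negative number).
#' @export
band_power <- function(psd, band, global = global_band()) {
  for (b in list(band, global)) {
    if (length(b) != 2 || b[1] <= 0 || b[1] >= b[2]) {
      stop("bands must be c(lo, hi) with 0 < lo < hi", call. = FALSE)
    }
    if (b[2] > max(psd$freq) + 1e-9) {
      stop("band [", b[1], ", ", b[2], "] Hz exceeds the Nyquist frequency ",
           max(psd$freq), " Hz", call. = FALSE)
    }
  }
  in_band <- psd$freq >= band[1] & psd$freq <= band[2]
  in_global <- psd$freq >= global[1] & psd$freq <= global[2]
  if (!any(in_band)) stop("no frequency bins inside the band", call. = FALSE)
  g <- mean(psd$power[in_global])
  if (g <= 0) {
    stop("global ", global[1], "-", global[2],
         " Hz power is zero; cannot normalize", call. = FALSE)
  }
  mean(psd$power[in_band]) / g
}

# cos/sin DFT bases for a set of bins with the DPSS tapers absorbed into the
# rows, cached; element [[k]] holds the pair for taper k
.taper_trig_basis <- function(n, bins, nw, n_tapers) {
  key <- sprintf("trig_%d_%s_%g_%d", n, paste(range(bins), collapse = "_"),
                 nw, n_tapers)
  .cache_get(key, function() {
    ang <- 2 * pi * outer(bins, 0:(n - 1)) / n
    C <- cos(ang)
    S <- sin(ang)
    v <- dpss_tapers(n, nw = nw, n_tapers = n_tapers)
    lapply(seq_len(n_tapers), function(k) {
      list(C = C * rep(v[, k], each = nrow(C)),
           S = S * rep(v[, k], each = nrow(S)))
    })
  })
}

#' Per-epoch normalized band power for every channel
#'
#' Vectorized multitaper band-power estimation across all channels and epochs
#' of an [epoched_eeg] object. Identical, bin for bin, to calling
#' [multitaper_psd()] and [band_power()] on each epoch; the heavy lifting is a
#' dense cosine/sine transform restricted to the bins the bands need.
#'
#' @param eeg An [epoched_eeg] object.
#' @param bands Named list of `c(lo, hi)` band limits (default [eeg_bands()]).
#' @param channels Channels to include (default all).
#' @param global `c(lo, hi)` normalization band.
#' @param n_tapers,nw Multitaper parameters.
#' @return 3-d array `[channel, epoch, band]` of normalized band power.
#' @export
epoch_band_power <- function(eeg, bands = eeg_bands(), channels = NULL,
                             global = global_band(), n_tapers = 3, nw = 2) {
  stopifnot(inherits(eeg, "epoched_eeg"))
  if (is.null(channels)) channels <- eeg$channels
  missing <- setdiff(channels, eeg$channels)
  if (length(missing)) {
    stop("channel(s) not present: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- eeg$n_samples
  fs <- eeg$fs
  nyq <- fs / 2
  for (b in c(bands, list(global = global))) {
    if (b[1] <= 0 || b[1] >= b[2] || b[2] > nyq + 1e-9) {
      stop("band [", b[1], ", ", b[2], "] Hz is outside (0, fs/2]",
           call. = FALSE)
    }
  }
  nf <- floor(n / 2) + 1L
  freq <- (seq_len(nf) - 1) * fs / n
  allb <- c(bands, list(.global = global))
  sel <- vector("list", length(allb))
  names(sel) <- names(allb)
  for (i in seq_along(allb)) {
    sel[[i]] <- which(freq >= allb[[i]][1] & freq <= allb[[i]][2])
    if (length(sel[[i]]) == 0) {
      stop("a band contains no frequency bins at this epoch length",
           call. = FALSE)
    }
  }
  # When the global band covers most of the spectrum its summed power is
  # cheaper through Parseval: total tapered power minus the few complement
  # bins. Otherwise evaluate its bins directly.
  cmp <- setdiff(seq_len(nf), sel$.global)          # includes the DC bin
  use_parseval <- length(cmp) + 1L < length(sel$.global)
  bins <- if (use_parseval) {
    sort(unique(c(unlist(sel[names(bands)]), cmp)))
  } else {
    sort(unique(unlist(sel)))
  }
  basis <- .taper_trig_basis(n, bins - 1L, nw, n_tapers)  # 1-based bins
  scale <- .onesided_scale(n, nf)[bins]

  idx <- match(channels, eeg$channels)
  nch <- length(idx)
  nep <- eeg$n_epochs
  tap <- dpss_tapers(n, nw = nw, n_tapers = n_tapers)
  sm <- attr(eeg, "sample_major")
  if (!is.null(sm)) {
    # guard against a mutated copy of the data invalidating the cache
    probe <- c(eeg$data[1, 1, 1], eeg$data[nch, nep, n],
               eeg$data[1, (nep + 1) %/% 2, (n + 1) %/% 2])
    probe_sm <- c(sm[1, 1], sm[n, nch * nep],
                  sm[(n + 1) %/% 2, ((nep + 1) %/% 2 - 1) * nch + 1])
    if (!isTRUE(all.equal(probe, probe_sm))) sm <- NULL
  }
  sp <- if (!is.null(sm) && length(idx) == length(eeg$channels) &&
            all(idx == seq_along(idx))) {
    cpp_tapered_spectra_mat(sm, lapply(basis, `[[`, "C"),
                            lapply(basis, `[[`, "S"), tap, use_parseval)
  } else {
    cpp_tapered_spectra(eeg$data, as.integer(idx),
                        lapply(basis, `[[`, "C"),
                        lapply(basis, `[[`, "S"), tap, use_parseval)
  }
  P <- sp$P * (scale / (n_tapers * fs))    # one-sided PSD at the selected bins

  pos <- match(seq_len(nf), bins)          # freq bin -> row of P
  g <- if (use_parseval) {
    (as.numeric(sp$total) / (n_tapers * fs) -
       .colSums(P[pos[cmp], , drop = FALSE], length(cmp), ncol(P))) /
      length(sel$.global)
  } else {
    ix <- pos[sel$.global]
    .colSums(P[ix, , drop = FALSE], length(ix), ncol(P)) / length(ix)
  }
  if (any(g <= 0)) {
    bad <- which(g <= 0)[1]
    stop("global spectrum power is zero in channel ",
         channels[(bad - 1) %% nch + 1], ", epoch ",
         (bad - 1) %/% nch + 1, call. = FALSE)
  }
  out <- array(NA_real_, dim = c(nch, nep, length(bands)),
               dimnames = list(channels, NULL, names(bands)))
  for (i in seq_along(bands)) {
    ix <- pos[sel[[i]]]
    bmean <- .colSums(P[ix, , drop = FALSE], length(ix), ncol(P)) / length(ix)
    out[, , i] <- matrix(bmean / g, nrow = nch)
  }
  out
}

#' Pool normalized power across channels
#'
#' Arithmetic mean of per-epoch normalized power over the requested channels
#' (default: the right occipitoparietal set P4, P6, P8, PO4, PO8, O2).
#'
#' @param power Channels x epochs matrix with channel rownames, or the
#'   `[channel, epoch, band]` array from [epoch_band_power()].
#' @param channels Channels to pool; all must be present.
#' @return Per-epoch vector (matrix input) or epochs x band matrix (array
#'   input).
#' @export
pool_channels <- function(power, channels = alpha_channels()) {
  have <- if (is.array(power) && length(dim(power)) == 3) {
    dimnames(power)[[1]]
  } else {
    rownames(power)
  }
  missing <- setdiff(channels, have)
  if (length(missing)) {
    stop("channel(s) not present: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.array(power) && length(dim(power)) == 3) {
    sub <- power[channels, , , drop = FALSE]
    apply(sub, c(2, 3), mean)
  } else {
    colMeans(power[channels, , drop = FALSE])
  }
}

#' Smooth a per-epoch power series onto the window grid
#'
#' For each window of the scheme, the taper-weighted average of the epoch
#' power values inside that window (taper normalized to unit sum). This aligns
#' the EEG power timeseries with the sliding-window connectivity timeseries on
#' exactly the same window centres; no hemodynamic response convolution is
#' applied, preserving the power amplitudes.
#'
#' @param per_epoch_power Numeric vector, one value per epoch.
#' @param scheme A [make_window_scheme()] built for the same number of epochs.
#' @return Numeric vector with one value per window.
#' @export
smooth_power_series <- function(per_epoch_power, scheme) {
  stopifnot(inherits(scheme, "window_scheme"))
  if (length(per_epoch_power) != scheme$n_epochs) {
    stop("power series has ", length(per_epoch_power),
         " epochs but the scheme expects ", scheme$n_epochs, call. = FALSE)
  }
  as.numeric(.sliding_wsum(matrix(per_epoch_power, ncol = 1), scheme)) /
    sum(scheme$taper)
}

#' Window-aligned EEG band-power timeseries
#'
#' Convenience wrapper chaining [epoch_band_power()], [pool_channels()] and
#' [smooth_power_series()] for a set of bands.
#'
#' @inheritParams epoch_band_power
#' @param scheme A [make_window_scheme()] for the session.
#' @param channels Channels pooled for the power estimate.
#' @return List with `per_epoch` (epochs x band matrix) and `per_window`
#'   (windows x band matrix).
#' @export
power_timeseries <- function(eeg, scheme, bands = eeg_bands(),
                             channels = alpha_channels(),
                             global = global_band(), n_tapers = 3, nw = 2) {
  bp <- epoch_band_power(eeg, bands = bands, channels = channels,
                         global = global, n_tapers = n_tapers, nw = nw)
  per_epoch <- pool_channels(bp, channels)
  per_window <- apply(per_epoch, 2, smooth_power_series, scheme = scheme)
  if (is.null(dim(per_window))) {
    per_window <- matrix(per_window, ncol = ncol(per_epoch),
                         dimnames = list(NULL, colnames(per_epoch)))
  }
  list(per_epoch = per_epoch, per_window = per_window,
       channels = channels, bands = bands)
}
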