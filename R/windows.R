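#' Gaussian taper weights
#'
#' Discrete Gaussian taper used for the sliding-window analysis. The weight at
#' offset `i` from the window centre `c = (length - 1) / 2` is
#' `exp(-(i - c)^2 / (2 sigma^2))` with `sigma = fwhm / (2 sqrt(2 log 2))`, so
#' the continuous curve drops to one half of its peak at `fwhm / 2` epochs from
#' the centre.
#'
#' @param length_epochs Window length in epochs (>= 2).
#' @param fwhm_epochs Full width at half maximum of the Gaussian, in epochs.
#' @return Numeric vector of `length_epochs` weights, symmetric about the
#'   window centre with continuous peak value 1.
#' @examples
#' w <- gaussian_taper(60, 27.78)
#' all.equal(w, rev(w))
#' @export
gaussian_taper <- function(length_epochs, fwhm_epochs) {
  if (length(length_epochs) != 1L || !is.finite(length_epochs) ||
      length_epochs < 2 || length_epochs != round(length_epochs)) {
    stop("`length_epochs` must be a single integer >= 2", call. = FALSE)
  }
  if (length(fwhm_epochs) != 1L || !is.finite(fwhm_epochs) || fwhm_epochs <= 0) {
    stop("`fwhm_epochs` must be a single positive number", call. = FALSE)
  }
  centre <- (length_epochs - 1) / 2
  sigma <- fwhm_epochs / (2 * sqrt(2 * log(2)))
  exp(-((seq_len(length_epochs) - 1 - centre)^2) / (2 * sigma^2))
}

#' Sliding-window scheme
#'
#' Defines the tapered sliding-window grid shared by the connectivity and the
#' EEG power timeseries: window length and step in epochs (one epoch = one TR),
#' the Gaussian taper, and the resulting window start indices. With the
#' defaults (60-epoch window, 1-epoch step, TR 1.8 s) a 306-epoch session
#' yields 247 windows of 108 s duration overlapping by 106.2 s.
#'
#' @param n_epochs Number of epochs (TRs) in the session.
#' @param length_epochs Window length in epochs.
#' @param step_epochs Sliding increment in epochs.
#' @param fwhm_epochs Gaussian taper FWHM in epochs.
#' @param tr Repetition time in seconds.
#' @return A `window_scheme` object: list with elements `length_epochs`,
#'   `step_epochs`, `fwhm_epochs`, `tr`, `taper`, `starts`, `n_windows`,
#'   `n_epochs`, `duration_s`, `overlap_s`.
#' @examples
#' ws <- make_window_scheme(306)
#' ws$n_windows    # 247
#' ws$overlap_s    # 106.2
#' @export
make_window_scheme <- function(n_epochs, length_epochs = 60, step_epochs = 1,
                               fwhm_epochs = 27.78, tr = 1.8) {
  if (n_epochs < length_epochs) {
    stop("`n_epochs` (", n_epochs, ") is shorter than the window length (",
         length_epochs, ")", call. = FALSE)
  }
  if (step_epochs < 1 || step_epochs != round(step_epochs)) {
    stop("`step_epochs` must be a positive integer", call. = FALSE)
  }
  if (tr <= 0) stop("`tr` must be positive", call. = FALSE)
  starts <- seq.int(1L, n_epochs - length_epochs + 1L, by = step_epochs)
  structure(
    list(
      length_epochs = as.integer(length_epochs),
      step_epochs = as.integer(step_epochs),
      fwhm_epochs = fwhm_epochs,
      tr = tr,
      taper = gaussian_taper(length_epochs, fwhm_epochs),
      starts = starts,
      n_windows = length(starts),
      n_epochs = as.integer(n_epochs),
      duration_s = length_epochs * tr,
      overlap_s = (length_epochs - step_epochs) * tr
    ),
    class = "window_scheme"
  )
}

#' @export
print.window_scheme <- function(x, ...) {
  cat("Sliding-window scheme:\n")
  cat(sprintf("  %d windows of %d epochs (%.1f s) over %d epochs\n",
              x$n_windows, x$length_epochs, x$duration_s, x$n_epochs))
  cat(sprintf("  step %d epoch(s), overlap %.1f s, Gaussian FWHM %.2f epochs\n",
              x$step_epochs, x$overlap_s, x$fwhm_epochs))
  invisible(x)
}

#' Weighted Pearson correlation
#'
#' Pearson correlation with non-negative observation weights, used to estimate
#' functional connectivity inside each tapered window. With uniform weights it
#' reduces to the ordinary Pearson coefficient, and the result is invariant to
#' rescaling the weight vector.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param w Non-negative weights with positive sum, or `NULL` for uniform.
#' @return The weighted correlation coefficient in `[-1, 1]`.
#' @export
weighted_pearson <- function(x, y, w = NULL) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n) stop("`w` must match the data length", call. = FALSE)
  if (any(w < 0) || sum(w) <= 0) {
    stop("weights must be non-negative with a positive sum", call. = FALSE)
  }
  W <- sum(w)
  dx <- x - sum(w * x) / W
  dy <- y - sum(w * y) / W
  sxx <- sum(w * dx * dx)
  syy <- sum(w * dy * dy)
  if (sxx <= 0) stop("zero weighted variance in `x`", call. = FALSE)
  if (syy <= 0) stop("zero weighted variance in `y`", call. = FALSE)
  r <- sum(w * dx * dy) / sqrt(sxx * syy)
  min(1, max(-1, r))
}

# dense windows x epochs weight matrix of a scheme (cached): row i holds the
# taper at window i's position, zero elsewhere
.window_weights <- function(scheme) {
  key <- sprintf("ww_%d_%d_%d_%.10g_%.10g", scheme$n_epochs,
                 scheme$length_epochs, scheme$step_epochs,
                 sum(scheme$taper), sum(scheme$taper * seq_along(scheme$taper)))
  .cache_get(key, function() {
    W <- matrix(0, scheme$n_windows, scheme$n_epochs)
    off <- 0:(scheme$length_epochs - 1L)
    for (i in seq_len(scheme$n_windows)) {
      W[i, scheme$starts[i] + off] <- scheme$taper
    }
    W
  })
}

# Taper-weighted sliding sums of every column of M at the scheme's windows.
# Returns a matrix with one row per window.
.sliding_wsum <- function(M, scheme) {
  .window_weights(scheme) %*% M
}

.pair_key <- function(a, b) paste(a, b, sep = "~")

#' Sliding-window functional connectivity timeseries
#'
#' Computes, for each window of the scheme and each requested ROI pair, the
#' taper-weighted Pearson correlation of the two BOLD series restricted to the
#' window. Degenerate windows (zero weighted variance) become `NA` with a
#' warning; more than 5 percent missing windows is an error.
#'
#' @param ts A [roi_timeseries] (typically after [preprocess_bold()]).
#' @param scheme A [make_window_scheme()] object matching the series length.
#' @param pairs ROI pairs: `"dmn"` (all pairs among DMN hubs), `"extra_dmn"`
#'   (DMN hub x ECN/SN hub), `"all"`, or a two-column character matrix.
#' @param weighted Apply the Gaussian taper as observation weights (default).
#'   `FALSE` gives the plain correlation over each window.
#' @return An `fc_series` object: list with `values` (windows x pairs matrix of
#'   correlations), `pairs` (data frame with `roi_a`, `roi_b`), and `scheme`.
#' @export
fc_timeseries <- function(ts, scheme, pairs = "dmn", weighted = TRUE) {
  stopifnot(inherits(ts, "roi_timeseries"), inherits(scheme, "window_scheme"))
  X <- ts$values
  if (nrow(X) != scheme$n_epochs) {
    stop("scheme was built for ", scheme$n_epochs, " epochs but the series has ",
         nrow(X), call. = FALSE)
  }
  pr <- resolve_pairs(pairs, ts$roi_labels, ts$networks)
  if (nrow(pr) == 0) stop("no ROI pairs requested", call. = FALSE)
  used <- unique(c(pr$roi_a, pr$roi_b))
  X <- X[, used, drop = FALSE]
  # centre columns once for numerical stability of the moment sums
  X <- X - rep(.colMeans(X, nrow(X), ncol(X)), each = nrow(X))
  w <- if (weighted) scheme$taper else rep(1, scheme$length_epochs)
  sch <- scheme
  sch$taper <- w
  W <- sum(w)
  ia <- match(pr$roi_a, used)
  ib <- match(pr$roi_b, used)
  Sx <- .sliding_wsum(X, sch) / W
  Sxx <- .sliding_wsum(X * X, sch) / W
  Sxy <- .sliding_wsum(X[, ia, drop = FALSE] * X[, ib, drop = FALSE], sch) / W
  Vx <- pmax(Sxx - Sx * Sx, 0)
  cov <- Sxy - Sx[, ia, drop = FALSE] * Sx[, ib, drop = FALSE]
  den <- sqrt(Vx[, ia, drop = FALSE] * Vx[, ib, drop = FALSE])
  ok <- den > 0
  r <- matrix(NA_real_, nrow(cov), ncol(cov))
  r[ok] <- cov[ok] / den[ok]
  r[ok] <- pmin(1, pmax(-1, r[ok]))
  n_missing <- sum(!ok)
  if (n_missing > 0) {
    if (n_missing > 0.05 * length(r)) {
      stop(n_missing, " of ", length(r),
           " windows have degenerate (constant) signal", call. = FALSE)
    }
    warning(n_missing, " degenerate window(s) set to NA", call. = FALSE)
  }
  colnames(r) <- .pair_key(pr$roi_a, pr$roi_b)
  structure(
    list(values = r, pairs = pr, scheme = scheme, weighted = weighted,
         n_missing = n_missing),
    class = "fc_series"
  )
}

#' @export
print.fc_series <- function(x, ...) {
  cat(sprintf("FC timeseries: %d windows x %d ROI pairs (%s taper)\n",
              nrow(x$values), ncol(x$values),
              if (x$weighted) "Gaussian" else "uniform"))
  invisible(x)
}

#' Resolve ROI pair specifications
#'
#' @param pairs `"dmn"`, `"extra_dmn"`, `"dmn+extra"`, `"all"`, or a
#'   two-column matrix / list of length-2 character vectors.
#' @param roi_labels Available ROI labels.
#' @param networks Named character vector mapping ROI to network
#'   (`"DMN"`, `"ECN"`, `"SN"`).
#' @return Data frame with columns `roi_a`, `roi_b`, `set` (intra-DMN or not).
#' @export
resolve_pairs <- function(pairs, roi_labels, networks = NULL) {
  all_pairs <- function(labels) {
    if (length(labels) < 2) return(data.frame(roi_a = character(), roi_b = character()))
    cmb <- utils::combn(labels, 2)
    data.frame(roi_a = cmb[1, ], roi_b = cmb[2, ], stringsAsFactors = FALSE)
  }
  if (is.character(pairs) && length(pairs) == 1L) {
    if (pairs %in% c("dmn", "extra_dmn", "dmn+extra") && is.null(networks)) {
      stop("network membership is required to resolve \"", pairs, "\" pairs",
           call. = FALSE)
    }
    pr <- switch(pairs,
      all = all_pairs(roi_labels),
      dmn = all_pairs(roi_labels[networks[roi_labels] == "DMN"]),
      extra_dmn = {
        dmn <- roi_labels[networks[roi_labels] == "DMN"]
        oth <- roi_labels[networks[roi_labels] != "DMN"]
        expand.grid(roi_a = dmn, roi_b = oth, stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)
      },
      `dmn+extra` = rbind(
        resolve_pairs("dmn", roi_labels, networks)[, 1:2],
        resolve_pairs("extra_dmn", roi_labels, networks)[, 1:2]
      ),
      stop("unknown pair specification \"", pairs, "\"", call. = FALSE)
    )
  } else {
    if (is.list(pairs)) pairs <- do.call(rbind, pairs)
    pr <- data.frame(roi_a = pairs[, 1], roi_b = pairs[, 2],
                     stringsAsFactors = FALSE)
  }
  missing <- setdiff(unique(c(pr$roi_a, pr$roi_b)), roi_labels)
  if (length(missing)) {
    stop("unknown ROI label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(networks)) {
    pr$set <- ifelse(networks[pr$roi_a] == "DMN" & networks[pr$roi_b] == "DMN",
                     "intra_dmn",
                     ifelse(networks[pr$roi_a] == "DMN" | networks[pr$roi_b] == "DMN",
                            "extra_dmn", "other"))
  } else {
    pr$set <- NA_character_
  }
  rownames(pr) <- NULL
  pr
}

#' Fisher Z transform
#'
#' Variance-stabilizing transform `z = atanh(r)` of a correlation coefficient.
#' Coefficients with `|r| >= 1` are rejected rather than mapped to infinity.
#'
#' @param r Correlation coefficient(s) with `|r| < 1` (`NA` passed through).
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    stop("Fisher Z is undefined for |r| >= 1", call. = FALSE)
  }
  atanh(r)
}

#' Couple a connectivity timeseries with a power timeseries
#'
#' Pearson correlation between a window-aligned EEG power timeseries and an
#' fMRI functional-connectivity timeseries, optionally shifting the fMRI
#' series `lag_trs` windows later than the EEG series to acknowledge
#' hemodynamic sluggishness: `power[t]` is paired with `fc[t + lag]`. Windows
#' that are `NA` in either series are dropped pairwise. The correlation across
#' windows is unweighted; the Gaussian taper's job ends once the two series
#' are built.
#'
#' @param fc Numeric vector of per-window connectivity values (or a
#'   single-pair `fc_series`).
#' @param power Numeric vector of per-window power values.
#' @param lag_trs Non-negative lag in TRs (windows); negative lags are
#'   rejected.
#' @param min_overlap Minimum usable overlap after lagging and NA removal.
#' @return List with `r`, `z = atanh(r)`, `lag_trs`, and `n` (windows used).
#' @export
couple <- function(fc, power, lag_trs = 0, min_overlap = 10) {
  if (inherits(fc, "fc_series")) {
    if (ncol(fc$values) != 1L) {
      stop("`fc` must be a single pair; extract a column first", call. = FALSE)
    }
    fc <- as.numeric(fc$values[, 1])
  }
  if (length(fc) != length(power)) {
    stop("`fc` and `power` must be aligned on the same window grid",
         call. = FALSE)
  }
  if (lag_trs < 0 || lag_trs != round(lag_trs)) {
    stop("`lag_trs` must be a non-negative integer (the fMRI series is ",
         "shifted later than the EEG series)", call. = FALSE)
  }
  n <- length(fc)
  if (lag_trs >= n) stop("lag leaves no overlap", call. = FALSE)
  x <- power[seq_len(n - lag_trs)]
  y <- fc[(1 + lag_trs):n]
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < min_overlap) {
    stop("only ", sum(keep), " overlapping windows after lag ", lag_trs,
         "; need at least ", min_overlap, call. = FALSE)
  }
  r <- weighted_pearson(x[keep], y[keep])
  list(r = r, z = fisher_z(r), lag_trs = as.integer(lag_trs), n = sum(keep))
}

#' Adjusted coupling (intra-DMN minus mean extra-DMN)
#'
#' Subtracts the mean of the Fisher-Z coupling values for extra-DMN
#' connectivity from an intra-DMN coupling value, removing any global
#' association between band power and connectivity fluctuations.
#'
#' @param z_intra Fisher-Z coupling of an intra-DMN pair.
#' @param z_extra Non-empty vector of Fisher-Z couplings of extra-DMN pairs.
#' @return `z_intra - mean(z_extra)`.
#' @export
adjusted_coupling <- function(z_intra, z_extra) {
  if (length(z_extra) == 0) {
    stop("`z_extra` must contain at least one value", call. = FALSE)
  }
  z_intra - mean(z_extra)
}
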