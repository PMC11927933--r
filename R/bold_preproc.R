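#' ROI BOLD timeseries container
#'
#' TR-by-ROI matrix of BOLD values with ROI labels, the network each ROI
#' belongs to, and the TR duration.
#'
#' @param values Numeric matrix, one row per TR, one column per ROI.
#' @param roi_labels Unique ROI labels (default: column names of `values`).
#' @param networks Named character vector mapping each ROI label to
#'   `"DMN"`, `"ECN"` or `"SN"` (optional but required for network-aware pair
#'   selection).
#' @param tr Repetition time in seconds.
#' @return A `roi_timeseries` object.
#' @export
roi_timeseries <- function(values, roi_labels = colnames(values),
                           networks = NULL, tr = 1.8) {
  values <- as.matrix(values)
  if (is.null(roi_labels)) {
    stop("`roi_labels` are required (or set column names on `values`)",
         call. = FALSE)
  }
  if (length(roi_labels) != ncol(values)) {
    stop("number of labels (", length(roi_labels),
         ") does not match the number of ROI columns (", ncol(values), ")",
         call. = FALSE)
  }
  if (anyDuplicated(roi_labels)) stop("ROI labels must be unique", call. = FALSE)
  if (anyNA(values)) stop("BOLD values contain missing data", call. = FALSE)
  if (tr <= 0) stop("`tr` must be positive", call. = FALSE)
  if (!is.null(networks)) {
    missing <- setdiff(roi_labels, names(networks))
    if (length(missing)) {
      stop("no network membership for: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    networks <- networks[roi_labels]
  }
  colnames(values) <- roi_labels
  structure(list(values = values, roi_labels = roi_labels,
                 networks = networks, tr = tr, n_tr = nrow(values)),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI timeseries: %d TRs x %d ROIs (TR %g s)\n",
              x$n_tr, length(x$roi_labels), x$tr))
  invisible(x)
}

#' Hub ROIs of the three intrinsic connectivity networks
#'
#' Default 12-ROI set: DMN hubs mPFC, vPCC, dPCC, lAG, rAG; ECN hubs l/r
#' dlPFC and l/r PPC; SN hubs dACC and l/r AI.
#'
#' @return Named character vector mapping ROI label to network.
#' @export
default_roi_networks <- function() {
  c(mPFC = "DMN", vPCC = "DMN", dPCC = "DMN", lAG = "DMN", rAG = "DMN",
    ldlPFC = "ECN", rdlPFC = "ECN", lPPC = "ECN", rPPC = "ECN",
    dACC = "SN", lAI = "SN", rAI = "SN")
}

#' Centre and scale each ROI series
#'
#' Standardizes each ROI series to mean 0 and unit standard deviation (the
#' "whitening" here is per-series variance normalization, not temporal
#' prewhitening).
#'
#' @param ts A [roi_timeseries].
#' @return The standardized [roi_timeseries].
#' @export
center_and_scale <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (ts$n_tr < 2) stop("need at least 2 TRs", call. = FALSE)
  n <- ts$n_tr
  cm <- .colMeans(ts$values, n, ncol(ts$values))
  ctr <- ts$values - rep(cm, each = n)
  sds <- sqrt(.colSums(ctr * ctr, n, ncol(ctr)) / (n - 1))
  if (any(sds == 0)) {
    stop("constant (zero-variance) ROI series: ",
         paste(ts$roi_labels[sds == 0], collapse = ", "), call. = FALSE)
  }
  ts$values <- ctr * rep(1 / sds, each = n)
  ts
}

# zero-phase (forward-backward) filtering of every column, with odd reflection
# padding at both ends to suppress edge transients
.filtfilt_padded <- function(b, a, X) {
  X <- as.matrix(X)
  pad <- min(nrow(X) - 1, 15 * (max(length(b), length(a)) - 1))
  cpp_filtfilt(b, a, X, as.integer(pad))
}

#' Temporal bandpass filter
#'
#' Zero-phase (forward-backward) Butterworth bandpass of each ROI series,
#' default passband 0.01-0.08 Hz. Passband sinusoids are preserved to within a
#' few percent; stopband sinusoids are strongly attenuated. The filter order
#' refers to the underlying one-pass Butterworth design; the forward-backward
#' application squares its magnitude response.
#'
#' @param ts A [roi_timeseries].
#' @param lo,hi Passband edges in Hz; `hi` must be below the Nyquist frequency
#'   `1 / (2 tr)`.
#' @param order Butterworth design order (default 4).
#' @return The filtered [roi_timeseries].
#' @export
bandpass_filter <- function(ts, lo = 0.01, hi = 0.08, order = 4) {
  stopifnot(inherits(ts, "roi_timeseries"))
  fs <- 1 / ts$tr
  if (lo <= 0 || lo >= hi) stop("need 0 < lo < hi", call. = FALSE)
  if (hi >= fs / 2) {
    stop("`hi` (", hi, " Hz) must be below the Nyquist frequency ",
         signif(fs / 2, 4), " Hz", call. = FALSE)
  }
  bf <- .cache_get(sprintf("butter_%d_%.8g_%.8g_%.8g", order, lo, hi, fs),
                   function() signal::butter(order, c(lo, hi) / (fs / 2),
                                             type = "pass"))
  out <- .filtfilt_padded(bf$b, bf$a, ts$values)
  colnames(out) <- ts$roi_labels
  ts$values <- out
  ts
}

#' Friston 24-parameter motion regressor set
#'
#' Expands six rigid-body motion parameters into the standard 24-column
#' nuisance set: the current parameters, the previous scan's parameters, and
#' the squares of both. The first row of the lagged blocks is zero-filled
#' (there is no previous scan at t = 1).
#'
#' @param motion6 TR x 6 matrix (translations in mm, rotations in rad).
#' @return TR x 24 numeric matrix.
#' @export
build_friston24 <- function(motion6) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6) {
    stop("`motion6` must have exactly 6 columns, got ", ncol(motion6),
         call. = FALSE)
  }
  if (nrow(motion6) < 2) stop("need at least 2 TRs", call. = FALSE)
  lag1 <- rbind(0, motion6[-nrow(motion6), , drop = FALSE])
  out <- cbind(motion6, lag1, motion6^2, lag1^2)
  colnames(out) <- c(paste0("m", 1:6), paste0("m", 1:6, "_lag"),
                     paste0("m", 1:6, "_sq"), paste0("m", 1:6, "_lag_sq"))
  out
}

#' Regress nuisance variables out of each ROI series
#'
#' Ordinary least squares per ROI with an intercept; returns the residuals,
#' which are orthogonal to every regressor column.
#'
#' @param ts A [roi_timeseries].
#' @param regressors TR x k numeric matrix (an intercept is added
#'   internally), or `NULL` for intercept-only (mean centring).
#' @return The residual [roi_timeseries].
#' @export
nuisance_regress <- function(ts, regressors = NULL) {
  stopifnot(inherits(ts, "roi_timeseries"))
  n <- ts$n_tr
  if (is.null(regressors)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  } else {
    regressors <- as.matrix(regressors)
    if (nrow(regressors) != n) {
      stop("regressors have ", nrow(regressors), " rows; expected ", n,
           call. = FALSE)
    }
    if (ncol(regressors) >= n) {
      stop("more regressors than observations", call. = FALSE)
    }
    if (is.null(colnames(regressors))) {
      colnames(regressors) <- paste0("x", seq_len(ncol(regressors)))
    }
    X <- cbind(intercept = 1, regressors)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  ts$values <- qr.resid(qx, ts$values)
  ts
}

#' Minimal ROI-level BOLD cleanup pipeline
#'
#' Chains the three post-extraction cleanup steps: per-ROI standardization,
#' temporal bandpass, and nuisance regression (24-parameter motion set when
#' six motion columns are supplied; intercept-only otherwise). The order is
#' configurable and recorded in the `provenance` attribute of the result.
#'
#' @param ts A [roi_timeseries].
#' @param confounds Optional TR x 6 motion matrix (expanded via
#'   [build_friston24()]) or a ready-made regressor matrix.
#' @param lo,hi Bandpass edges in Hz.
#' @param filter_order Butterworth design order.
#' @param steps Character vector: order of `"center"`, `"bandpass"`,
#'   `"regress"`.
#' @return The cleaned [roi_timeseries] with a `provenance` attribute.
#' @export
preprocess_bold <- function(ts, confounds = NULL, lo = 0.01, hi = 0.08,
                            filter_order = 4,
                            steps = c("center", "bandpass", "regress")) {
  stopifnot(inherits(ts, "roi_timeseries"))
  bad <- setdiff(steps, c("center", "bandpass", "regress"))
  if (length(bad)) stop("unknown step(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  reg <- confounds
  if (!is.null(reg) && ncol(as.matrix(reg)) == 6) reg <- build_friston24(reg)
  for (s in steps) {
    ts <- switch(s,
      center = center_and_scale(ts),
      bandpass = bandpass_filter(ts, lo = lo, hi = hi, order = filter_order),
      regress = nuisance_regress(ts, reg)
    )
  }
  attr(ts, "provenance") <- list(steps = steps, lo = lo, hi = hi,
                                 filter_order = filter_order,
                                 n_confounds = if (is.null(reg)) 0 else ncol(reg))
  ts
}
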