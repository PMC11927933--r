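#' Couple every FC pair with every band's power timeseries
#'
#' Runs the core dynamic analysis for one session: cleans the BOLD series,
#' builds the tapered sliding-window FC timeseries for the requested pairs,
#' builds the window-aligned normalized band-power timeseries, and correlates
#' the two at each requested lag (fMRI shifted later than EEG).
#'
#' @param bold A [roi_timeseries] (raw; cleaned internally via
#'   [preprocess_bold()]).
#' @param eeg An [epoched_eeg] for the same session.
#' @param scheme Optional [make_window_scheme()]; defaults to the 60-epoch /
#'   1-epoch-step / FWHM 27.78 scheme for the session length.
#' @param bands Named list of band limits (default [eeg_bands()]).
#' @param channels Channels pooled for power (default [alpha_channels()]).
#' @param pairs Pair specification passed to [fc_timeseries()].
#' @param lags Integer vector of non-negative lags in TRs (default 0).
#' @param confounds Optional confounds for [preprocess_bold()].
#' @param weighted Taper-weighted windowed correlation (default) or plain.
#' @return Tibble with one row per band x pair x lag: `band`, `roi_a`,
#'   `roi_b`, `pair_set`, `lag`, `r`, `z`, `n_windows`.
#' @export
analyze_session <- function(bold, eeg, scheme = NULL, bands = eeg_bands(),
                            channels = alpha_channels(), pairs = "dmn",
                            lags = 0, confounds = NULL, weighted = TRUE) {
  stopifnot(inherits(bold, "roi_timeseries"), inherits(eeg, "epoched_eeg"))
  if (eeg$n_epochs != bold$n_tr) {
    stop("EEG has ", eeg$n_epochs, " epochs but BOLD has ", bold$n_tr,
         " TRs; epochs must be aligned one per TR", call. = FALSE)
  }
  if (any(lags < 0)) stop("negative lags are rejected", call. = FALSE)
  if (is.null(scheme)) scheme <- make_window_scheme(bold$n_tr, tr = bold$tr)
  clean <- preprocess_bold(bold, confounds = confounds)
  fc <- fc_timeseries(clean, scheme, pairs = pairs, weighted = weighted)
  pow <- power_timeseries(eeg, scheme, bands = bands, channels = channels)
  n_w <- nrow(fc$values)
  out <- vector("list", length(bands) * length(lags))
  k <- 0
  for (band in names(bands)) {
    pvec <- pow$per_window[, band]
    for (lag in lags) {
      if (lag >= n_w) stop("lag ", lag, " leaves no overlap", call. = FALSE)
      x <- pvec[seq_len(n_w - lag)]
      Y <- fc$values[(1 + lag):n_w, , drop = FALSE]
      if (anyNA(Y)) {
        r <- vapply(seq_len(ncol(Y)), function(j) {
          keep <- is.finite(Y[, j])
          if (sum(keep) < 10) {
            stop("fewer than 10 usable windows for pair ",
                 colnames(Y)[j], call. = FALSE)
          }
          stats::cor(x[keep], Y[keep, j])
        }, 1)
      } else {
        r <- as.numeric(stats::cor(x, Y))
      }
      r <- pmin(1 - 1e-12, pmax(-1 + 1e-12, r))
      k <- k + 1
      np <- nrow(fc$pairs)
      out[[k]] <- tibble::new_tibble(list(
        band = rep(band, np),
        roi_a = fc$pairs$roi_a, roi_b = fc$pairs$roi_b,
        pair_set = fc$pairs$set,
        lag = rep(as.integer(lag), np),
        r = r, z = atanh(r),
        n_windows = rep(n_w - as.integer(lag), np)
      ), nrow = np)
    }
  }
  do.call(rbind, out)
}

#' Analyze every session of a study
#'
#' Applies [analyze_session()] to each subject-session of a materialized
#' [simulate_study()] bundle (or any list with the same shape) and binds the
#' coupling records with the design table.
#'
#' @param study A `sim_study` (or list with `design`, `sessions`, `config`).
#' @inheritParams analyze_session
#' @return List with `coupling` (tibble of per-session coupling records) and
#'   `design`.
#' @export
analyze_study <- function(study, bands = eeg_bands(),
                          channels = alpha_channels(), pairs = "dmn",
                          lags = 0, weighted = TRUE) {
  design <- study$design
  res <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    ses <- study$sessions[[paste(design$subject[i], design$session[i],
                                 sep = "_")]]
    rec <- analyze_session(ses$bold, ses$eeg, bands = bands,
                           channels = channels, pairs = pairs, lags = lags,
                           weighted = weighted)
    rec$subject <- design$subject[i]
    rec$group <- design$group[i]
    rec$session <- design$session[i]
    res[[i]] <- rec
  }
  coupling <- do.call(rbind, res)
  coupling <- coupling[, c("subject", "group", "session", "band", "roi_a",
                           "roi_b", "pair_set", "lag", "r", "z", "n_windows")]
  list(coupling = coupling, design = unique(design[, c("subject", "group")]))
}

#' Simulate and analyze a study session by session
#'
#' Streaming equivalent of [simulate_study()] followed by [analyze_study()]:
#' each session is generated, analyzed, and discarded, so memory stays flat.
#' Simulation warnings about correlation clipping or amplitude flooring are
#' collected into counts instead of being raised individually.
#'
#' @param config A [sim_config()].
#' @inheritParams analyze_session
#' @return List with `coupling`, `design`, and `sim_log` (clip counts).
#' @export
run_study <- function(config = sim_config(), bands = eeg_bands(),
                      channels = alpha_channels(), pairs = "dmn", lags = 0,
                      weighted = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  design <- study_design(config)
  seeds <- .study_seeds(config)
  n_rho_clipped <- 0
  n_floor_clipped <- 0
  res <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    ses <- withCallingHandlers(
      .simulate_session(config, design$group[i], design$session[i], seeds[i, ]),
      warning = function(w) {
        if (grepl("clipped", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    n_rho_clipped <- n_rho_clipped + ses$truth$n_clipped
    n_floor_clipped <- n_floor_clipped + ses$truth$n_floor_clipped
    rec <- analyze_session(ses$bold, ses$eeg, bands = bands,
                           channels = channels, pairs = pairs, lags = lags,
                           weighted = weighted)
    rec$subject <- design$subject[i]
    rec$group <- design$group[i]
    rec$session <- design$session[i]
    res[[i]] <- rec
  }
  coupling <- do.call(rbind, res)
  coupling <- coupling[, c("subject", "group", "session", "band", "roi_a",
                           "roi_b", "pair_set", "lag", "r", "z", "n_windows")]
  list(coupling = coupling,
       design = unique(design[, c("subject", "group")]),
       sim_log = list(n_rho_clipped = n_rho_clipped,
                      n_floor_clipped = n_floor_clipped))
}

#' Adjusted (intra-minus-extra) coupling records
#'
#' For each subject, session, band and lag, subtracts the mean Fisher-Z
#' coupling of the extra-DMN pairs (DMN hub x ECN/SN hub) from each intra-DMN
#' pair's coupling, per [adjusted_coupling()]. The input must contain both
#' pair sets (use `pairs = "dmn+extra"` when analyzing).
#'
#' @param coupling Coupling tibble from [analyze_study()] / [run_study()].
#' @return Tibble shaped like the intra-DMN rows of `coupling` with `z`
#'   replaced by the adjusted value (`r` dropped).
#' @export
adjust_coupling_records <- function(coupling) {
  if (!all(c("intra_dmn", "extra_dmn") %in% coupling$pair_set)) {
    stop("need both intra-DMN and extra-DMN records; analyze with ",
         "pairs = \"dmn+extra\"", call. = FALSE)
  }
  key <- interaction(coupling$subject, coupling$session, coupling$band,
                     coupling$lag, drop = TRUE)
  out <- vector("list", nlevels(key))
  for (i in seq_len(nlevels(key))) {
    sub <- coupling[key == levels(key)[i], ]
    intra <- sub[sub$pair_set == "intra_dmn", ]
    intra$z <- adjusted_coupling(intra$z, sub$z[sub$pair_set == "extra_dmn"])
    intra$r <- NA_real_
    out[[i]] <- intra
  }
  do.call(rbind, out)
}
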