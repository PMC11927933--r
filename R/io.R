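#' @name dyncouple-io
#' @title Tab-separated table formats
#'
#' @description All result tables use tab-separated UTF-8 text with a header
#' row, `.` as the decimal mark, and numbers written with 15 significant
#' digits so write/read round-trips are lossless at double precision.
NULL

.fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- "NA"
  out
}

.split_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1) stop("file ", path, " is empty", call. = FALSE)
  strsplit(lines, "\t", fixed = TRUE)
}

.parse_num <- function(x, path, line) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !(x %in% c("NA", "NaN")))
  if (length(bad)) {
    stop("non-numeric cell \"", x[bad[1]], "\" in ", path, " at line ", line,
         call. = FALSE)
  }
  v
}

#' Write / read ROI timeseries tables
#'
#' One column per ROI, one row per TR; the header row carries the ROI labels.
#' TR duration and network membership are metadata supplied at read time.
#'
#' @param ts A [roi_timeseries].
#' @param path File path.
#' @return `write_roi_tsv` returns `path` invisibly; `read_roi_tsv` returns a
#'   [roi_timeseries].
#' @export
write_roi_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(ts$roi_labels, collapse = "\t"), con)
  body <- apply(ts$values, 1, function(r) paste(.fmt_num(r), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_roi_tsv
#' @param tr Repetition time in seconds.
#' @param networks Optional named network map passed to [roi_timeseries()].
#' @export
read_roi_tsv <- function(path, tr = 1.8, networks = NULL) {
  rows <- .split_tsv(path)
  header <- rows[[1]]
  if (any(!is.na(suppressWarnings(as.numeric(header))))) {
    stop("missing header row in ", path, " (first line looks numeric)",
         call. = FALSE)
  }
  p <- length(header)
  body <- rows[-1]
  if (length(body) == 0) stop("no data rows in ", path, call. = FALSE)
  vals <- matrix(NA_real_, length(body), p)
  for (i in seq_along(body)) {
    if (length(body[[i]]) != p) {
      stop("ragged row in ", path, " at line ", i + 1, ": expected ", p,
           " fields, found ", length(body[[i]]), call. = FALSE)
    }
    vals[i, ] <- .parse_num(body[[i]], path, i + 1)
  }
  colnames(vals) <- header
  roi_timeseries(vals, networks = networks, tr = tr)
}

# generic data-frame TSV helpers -------------------------------------------

.write_df_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) .fmt_num(col) else as.character(col)
  })
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

.read_df_tsv <- function(path, numeric_cols) {
  rows <- .split_tsv(path)
  header <- rows[[1]]
  body <- rows[-1]
  out <- vector("list", length(header))
  names(out) <- header
  cells <- matrix(NA_character_, length(body), length(header))
  for (i in seq_along(body)) {
    if (length(body[[i]]) != length(header)) {
      stop("ragged row in ", path, " at line ", i + 1, call. = FALSE)
    }
    cells[i, ] <- body[[i]]
  }
  for (j in seq_along(header)) {
    out[[j]] <- if (header[j] %in% numeric_cols) {
      .parse_num(cells[, j], path, NA)
    } else {
      cells[, j]
    }
  }
  tibble::as_tibble(out)
}

#' Write / read coupling record tables
#'
#' Per subject, session, band, ROI pair and lag: the coupling Pearson r and
#' its Fisher-Z value.
#'
#' @param coupling Coupling tibble from [analyze_study()] / [run_study()].
#' @param path File path.
#' @export
write_coupling_tsv <- function(coupling, path) .write_df_tsv(coupling, path)

#' @rdname write_coupling_tsv
#' @export
read_coupling_tsv <- function(path) {
  out <- .read_df_tsv(path, numeric_cols = c("lag", "r", "z", "n_windows"))
  out$lag <- as.integer(out$lag)
  out
}

#' Write / read the study design table
#'
#' @param design Tibble with `subject`, `group` (and optionally `session`).
#' @param path File path.
#' @export
write_design_tsv <- function(design, path) .write_df_tsv(design, path)

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) .read_df_tsv(path, numeric_cols = character())

#' Write / read epoched EEG as a flat binary array with a JSON sidecar
#'
#' The samples are stored as little-endian doubles in the column-major order
#' of the `[channel, epoch, sample]` array; `<path>.json` records the
#' geometry, sampling rate, TR and channel labels.
#'
#' @param eeg An [epoched_eeg].
#' @param path Path of the binary file (sidecar written next to it).
#' @export
write_eeg_bin <- function(eeg, path) {
  stopifnot(inherits(eeg, "epoched_eeg"))
  con <- file(path, open = "wb")
  writeBin(as.numeric(eeg$data), con, size = 8, endian = "little")
  close(con)
  meta <- list(format = "dyncouple-eeg-1",
               dims = c("channel", "epoch", "sample"),
               n_channels = length(eeg$channels), n_epochs = eeg$n_epochs,
               n_samples = eeg$n_samples, fs = eeg$fs, tr = eeg$tr,
               channels = eeg$channels, dtype = "float64le",
               order = "column-major")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_eeg_bin
#' @export
read_eeg_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_epochs * meta$n_samples
  con <- file(path, open = "rb")
  vals <- readBin(con, "double", n = n, size = 8, endian = "little")
  close(con)
  if (length(vals) != n) {
    stop("binary file ", path, " is truncated: expected ", n, " doubles",
         call. = FALSE)
  }
  epoched_eeg(array(vals, dim = c(meta$n_channels, meta$n_epochs,
                                  meta$n_samples)),
              fs = meta$fs, channels = meta$channels, tr = meta$tr)
}

# run configuration ---------------------------------------------------------

#' Default run configuration
#'
#' Every default equals the study's stated analysis value: alpha 8-12 Hz,
#' theta 4-7 Hz, low beta 13-17 Hz, global 1-40 Hz, 60-epoch window with FWHM
#' 27.78 epochs sliding by 1 TR, TR 1.8 s, bandpass 0.01-0.08 Hz, lags 0-5
#' TRs available with 0 as the headline, FDR level 0.05.
#'
#' @return Nested list with `simulation`, `analysis`, and `seed` blocks.
#' @export
default_run_config <- function() {
  list(
    simulation = unclass(sim_config()),
    analysis = list(
      bands = eeg_bands(),
      global_band = global_band(),
      channels = alpha_channels(),
      window_length = 60,
      window_step = 1,
      window_fwhm = 27.78,
      lags = 0,
      bandpass_lo = 0.01,
      bandpass_hi = 0.08,
      filter_order = 4,
      fdr_q = 0.05,
      pairs = "dmn",
      weighted = TRUE
    ),
    seed = 1
  )
}

#' Load / save a run configuration
#'
#' YAML round-trip of the [default_run_config()] structure. Values omitted
#' from the file keep their defaults; unknown keys are rejected with the
#' offending name.
#'
#' @param path YAML file path.
#' @return A validated run configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- default_run_config()
  merge_block <- function(base, upd, where) {
    unknown <- setdiff(names(upd), names(base))
    if (length(unknown)) {
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    utils::modifyList(base, upd)
  }
  unknown_top <- setdiff(names(user), names(cfg))
  if (length(unknown_top)) {
    stop("unknown config key(s): ", paste(unknown_top, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(user$simulation)) {
    cfg$simulation <- merge_block(cfg$simulation, user$simulation, "simulation")
  }
  if (!is.null(user$analysis)) {
    cfg$analysis <- merge_block(cfg$analysis, user$analysis, "analysis")
  }
  if (!is.null(user$seed)) cfg$seed <- user$seed
  validate_run_config(cfg)
}

#' @rdname load_config
#' @param config A run configuration list.
#' @export
save_config <- function(config, path) {
  # named atomic vectors must become YAML maps or their names are lost
  yamlify <- function(x) {
    if (is.list(x)) {
      lapply(x, yamlify)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  yaml::write_yaml(yamlify(config), path, precision = 15)
  invisible(path)
}

#' @rdname load_config
#' @export
validate_run_config <- function(config) {
  a <- config$analysis
  if (a$window_length < 2) {
    stop("config analysis$window_length must be >= 2", call. = FALSE)
  }
  if (a$window_step < 1) {
    stop("config analysis$window_step must be >= 1", call. = FALSE)
  }
  if (a$window_fwhm <= 0) {
    stop("config analysis$window_fwhm must be positive", call. = FALSE)
  }
  if (a$bandpass_lo <= 0 || a$bandpass_lo >= a$bandpass_hi) {
    stop("config bandpass limits must satisfy 0 < lo < hi", call. = FALSE)
  }
  if (any(a$lags < 0)) stop("config analysis$lags must be >= 0", call. = FALSE)
  if (a$fdr_q <= 0 || a$fdr_q > 1) {
    stop("config analysis$fdr_q must lie in (0, 1]", call. = FALSE)
  }
  for (b in a$bands) {
    if (length(b) != 2 || b[1] <= 0 || b[1] >= b[2]) {
      stop("config band limits must be c(lo, hi) with 0 < lo < hi",
           call. = FALSE)
    }
  }
  sim <- config$simulation
  sim$seed <- config$seed
  config$simulation <- validate_sim_config(sim)
  config
}

#' Run the complete pipeline from a configuration
#'
#' Simulates the study session by session, runs the dynamic coupling analysis
#' and the group statistics, and writes the result tables: `design.tsv`,
#' `coupling.tsv`, `contrasts.tsv`, one coupling-change matrix per band, and
#' `provenance.json`. With a fixed configuration and seed the result tables
#' are byte-identical across runs.
#'
#' @param config Run configuration from [load_config()] /
#'   [default_run_config()] (validated internally).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the list of written files.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  config <- validate_run_config(config)
  a <- config$analysis
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  st <- run_study(config$simulation, bands = a$bands, channels = a$channels,
                  pairs = a$pairs, lags = a$lags, weighted = a$weighted)
  contrasts <- group_contrasts(st$coupling, q = a$fdr_q)
  files <- c(design = file.path(out_dir, "design.tsv"),
             coupling = file.path(out_dir, "coupling.tsv"),
             contrasts = file.path(out_dir, "contrasts.tsv"))
  write_design_tsv(st$design, files[["design"]])
  write_coupling_tsv(st$coupling, files[["coupling"]])
  .write_df_tsv(contrasts, files[["contrasts"]])
  for (band in names(a$bands)) {
    f <- file.path(out_dir, sprintf("change_matrix_%s.tsv", band))
    M <- coupling_change_matrix(st$coupling, band = band, lag = a$lags[1])
    df <- data.frame(roi = rownames(M), as.data.frame(M),
                     check.names = FALSE)
    .write_df_tsv(df, f)
    files[[paste0("change_matrix_", band)]] <- f
  }
  prov <- list(package = "dyncouple",
               version = as.character(utils::packageVersion("dyncouple")),
               timestamp = format(Sys.time(), tz = "UTC"),
               seed = config$seed,
               config = config[c("simulation", "analysis")],
               sim_log = st$sim_log,
               outputs = as.list(files))
  prov$config$simulation <- unclass(prov$config$simulation)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files[["provenance"]] <- file.path(out_dir, "provenance.json")
  invisible(files)
}

#' Write a materialized simulated study to disk
#'
#' One ROI-timeseries TSV and one EEG binary container per subject-session,
#' plus the design table and the per-session latent-state truth.
#'
#' @param study A [simulate_study()] bundle.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_design_tsv(study$design, file.path(dir, "design.tsv"))
  for (key in names(study$sessions)) {
    ses <- study$sessions[[key]]
    write_roi_tsv(ses$bold, file.path(dir, paste0(key, "_bold.tsv")))
    write_eeg_bin(ses$eeg, file.path(dir, paste0(key, "_eeg.bin")))
    truth <- tibble::tibble(epoch = seq_along(ses$truth$latent),
                            latent = ses$truth$latent,
                            alpha_amp = ses$truth$alpha_amp)
    rho <- ses$truth$true_rho
    for (j in seq_len(ncol(rho))) {
      truth[[paste0("rho_", colnames(rho)[j])]] <- rho[, j]
    }
    .write_df_tsv(truth, file.path(dir, paste0(key, "_truth.tsv")))
  }
  invisible(dir)
}
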