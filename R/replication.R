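#' Zero-effect version of a simulation configuration
#'
#' Sets every group-by-session coupling multiplier to zero, so the two groups
#' share an identical generative configuration and no session carries any
#' latent-state coupling between connectivity and alpha amplitude.
#'
#' @param config A [sim_config()].
#' @return The modified configuration.
#' @export
null_config <- function(config = sim_config()) {
  config$session_effects <- list(active = c(pre = 0, post = 0),
                                 sham = c(pre = 0, post = 0))
  config
}

#' Configuration used by the replication suites
#'
#' The study conditions of the calibration and recovery suites: 16 subjects
#' per group, 306 epochs at TR 1.8 s, EEG synthesized at 80 Hz on the six
#' pooled occipitoparietal channels (the band-power statistics depend on the
#' spectral resolution 1/TR, not on the sampling rate, so the leaner rate
#' changes nothing downstream while keeping 40 Hz inside the spectrum).
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
replication_config <- function(...) {
  sim_config(eeg_fs = 80, channels = alpha_channels(),
             base_correlation = 0.25, coupling_gain_bold = 0.5,
             noise_sd = 0.2, ...)
}

#' Null calibration of the double contrast
#'
#' Simulates `n_studies` complete zero-effect studies, runs the full pipeline
#' (EEG power, BOLD cleanup, windowed FC, coupling, group contrasts) on each,
#' and records the double-contrast p values across the DMN pairs. The
#' rejection rate of the target pair's raw p at level `alpha` estimates the
#' pipeline's false-positive rate, which should match `alpha`.
#'
#' @param n_studies Number of replicate studies.
#' @param config Base configuration (effects are zeroed internally).
#' @param seed Integer seed for the whole calibration.
#' @param alpha Nominal test level.
#' @param target Target ROI pair monitored for the headline rate.
#' @return List with `rejection_rate`, `n_studies`, `alpha`, `p_target`
#'   (per-study raw p of the target pair), `t_target`, and `p_all` (studies x
#'   pairs matrix of raw p values).
#' @export
run_null_calibration <- function(n_studies = 500,
                                 config = replication_config(),
                                 seed = 1, alpha = 0.05,
                                 target = c("vPCC", "lAG")) {
  config <- null_config(config)
  set.seed(seed)
  study_seeds <- sample.int(.Machine$integer.max - 1, n_studies)
  p_all <- NULL
  t_target <- p_target <- numeric(n_studies)
  for (i in seq_len(n_studies)) {
    cfg <- config
    cfg$seed <- study_seeds[i]
    st <- run_study(cfg, bands = list(alpha = c(8, 12)))
    gc <- group_contrasts(st$coupling)
    if (is.null(p_all)) {
      p_all <- matrix(NA_real_, n_studies, nrow(gc),
                      dimnames = list(NULL, paste(gc$roi_a, gc$roi_b,
                                                  sep = "~")))
    }
    p_all[i, ] <- gc$p_double
    k <- which(gc$roi_a == target[1] & gc$roi_b == target[2])
    p_target[i] <- gc$p_double[k]
    t_target[i] <- gc$t_double[k]
  }
  list(rejection_rate = mean(p_target <= alpha), n_studies = n_studies,
       alpha = alpha, p_target = p_target, t_target = t_target,
       p_all = p_all)
}

#' Parameter recovery and specificity across replicate studies
#'
#' Simulates `n_studies` studies with the configured injected effect
#' (active-post coupling increase on the target pairs, sham-post drift) and
#' summarizes, per study: whether each target pair survives BH-FDR across the
#' 10 DMN pairs in the alpha band, the signs of the group mean changes, and
#' the FDR survival of the control bands (theta, beta) and of the non-target
#' DMN pairs.
#'
#' @inheritParams run_null_calibration
#' @param config Configuration with the injected effect.
#' @return List of per-study tibble `studies` plus summary rates.
#' @export
run_recovery <- function(n_studies = 100, config = replication_config(),
                         seed = 2) {
  set.seed(seed)
  study_seeds <- sample.int(.Machine$integer.max - 1, n_studies)
  targets <- vapply(config$target_pairs, paste, "", collapse = "~")
  rows <- vector("list", n_studies)
  for (i in seq_len(n_studies)) {
    cfg <- config
    cfg$seed <- study_seeds[i]
    st <- run_study(cfg)
    gc <- group_contrasts(st$coupling)
    key <- paste(gc$roi_a, gc$roi_b, sep = "~")
    is_t <- key %in% targets
    al <- gc$band == "alpha"
    rows[[i]] <- tibble::tibble(
      study = i,
      target_survive_lAG = gc$significant[al & key == targets[1]],
      target_survive_rAG = gc$significant[al & key == targets[2]],
      t_target = gc$t_double[al & key == targets[1]],
      mean_dz_active = gc$mean_dz_active[al & key == targets[1]],
      mean_dz_sham = gc$mean_dz_sham[al & key == targets[1]],
      nontarget_alpha_rejections = sum(gc$significant[al & !is_t]),
      theta_target_rejections = sum(gc$significant[gc$band == "theta" & is_t]),
      beta_target_rejections = sum(gc$significant[gc$band == "beta" & is_t]),
      theta_all_rejections = sum(gc$significant[gc$band == "theta"]),
      beta_all_rejections = sum(gc$significant[gc$band == "beta"])
    )
  }
  studies <- do.call(rbind, rows)
  list(
    studies = studies,
    survival_rate_lAG = mean(studies$target_survive_lAG),
    survival_rate_rAG = mean(studies$target_survive_rAG),
    mean_t_target = mean(studies$t_target),
    active_increase_rate = mean(studies$mean_dz_active > 0),
    sham_decrease_rate = mean(studies$mean_dz_sham < 0),
    nontarget_alpha_rate = mean(studies$nontarget_alpha_rejections > 0),
    theta_target_rate = mean(studies$theta_target_rejections > 0),
    beta_target_rate = mean(studies$beta_target_rejections > 0)
  )
}

#' Mean estimated coupling over a grid of injected effect sizes
#'
#' Simulates independent active-post sessions at each latent-to-connectivity
#' gain in `betas` and returns the mean estimated coupling r of the first
#' target pair at each level, to verify sign and monotonicity of the
#' end-to-end estimate.
#'
#' @param betas Vector of `coupling_gain_bold` values.
#' @param n_sessions Sessions simulated per level.
#' @param config Base configuration.
#' @param seed Integer seed.
#' @return List with `betas`, `mean_r` (per level), and the per-session `r`
#'   matrix.
#' @export
run_effect_grid <- function(betas = c(0.1, 0.3, 0.5), n_sessions = 100,
                            config = replication_config(), seed = 3) {
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1,
                             3 * n_sessions * length(betas)),
                  ncol = 3)
  target <- config$target_pairs[[1]]
  R <- matrix(NA_real_, n_sessions, length(betas))
  row <- 0
  for (j in seq_along(betas)) {
    cfg <- config
    cfg$coupling_gain_bold <- betas[j]
    for (i in seq_len(n_sessions)) {
      row <- row + 1
      ses <- withCallingHandlers(
        .simulate_session(cfg, "active", "post", seeds[row, ]),
        warning = function(w) {
          if (grepl("clipped", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }
      )
      rec <- analyze_session(ses$bold, ses$eeg,
                             bands = list(alpha = c(8, 12)),
                             pairs = rbind(target))
      R[i, j] <- rec$r[1]
    }
  }
  list(betas = betas, mean_r = colMeans(R), r = R)
}
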