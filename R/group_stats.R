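#' Per-subject change in Fisher-Z coupling
#'
#' Joins each subject's pre- and post-stimulation coupling records and returns
#' the change `dz = z_post - z_pre` per subject, pair, band and lag. Every
#' subject must contribute exactly one pre and one post record per cell.
#'
#' @param coupling Coupling tibble from [analyze_study()] / [run_study()]
#'   (columns `subject`, `group`, `session`, `band`, `roi_a`, `roi_b`, `lag`,
#'   `z`).
#' @return Tibble with `subject`, `group`, `band`, `roi_a`, `roi_b`, `lag`,
#'   `dz`.
#' @export
delta_z <- function(coupling) {
  need <- c("subject", "group", "session", "band", "roi_a", "roi_b", "lag", "z")
  missing <- setdiff(need, names(coupling))
  if (length(missing)) {
    stop("coupling table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pre <- coupling[coupling$session == "pre", ]
  post <- coupling[coupling$session == "post", ]
  key <- function(d) paste(d$subject, d$band, d$roi_a, d$roi_b, d$lag, sep = "\r")
  kpre <- key(pre)
  kpost <- key(post)
  if (anyDuplicated(kpre) || anyDuplicated(kpost)) {
    stop("duplicate session records for the same subject/pair/band/lag",
         call. = FALSE)
  }
  idx <- match(kpre, kpost)
  if (anyNA(idx) || length(kpre) != length(kpost)) {
    bad <- unique(c(pre$subject[is.na(idx)],
                    post$subject[!(kpost %in% kpre)]))
    stop("incomplete pre/post records for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    subject = pre$subject, group = pre$group, band = pre$band,
    roi_a = pre$roi_a, roi_b = pre$roi_b, lag = pre$lag,
    dz = post$z[idx] - pre$z
  )
}

#' Two-sample double contrast
#'
#' Post-minus-pre change compared between the active and sham groups: a
#' pooled-variance Student two-sample t test (active minus sham) with a Welch
#' fallback when the variance-homogeneity check fails.
#'
#' @param delta_active,delta_sham Per-subject `dz` values (length >= 2 each).
#' @param var_equal `TRUE` forces pooled, `FALSE` forces Welch, `NA` (default)
#'   picks pooled unless the Levene-type homogeneity check rejects at 0.05.
#' @return List with `t`, `p` (two-tailed), `df`, `method`, and the
#'   `homogeneity_p` diagnostic (NA when not assessed).
#' @export
double_contrast <- function(delta_active, delta_sham, var_equal = NA) {
  if (length(delta_active) < 2 || length(delta_sham) < 2) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  if (stats::var(delta_active) == 0 && stats::var(delta_sham) == 0) {
    stop("zero variance in both groups; t test undefined", call. = FALSE)
  }
  hom_p <- NA_real_
  if (is.na(var_equal)) {
    hom_p <- tryCatch(.levene_p(delta_active, delta_sham),
                      error = function(e) NA_real_)
    var_equal <- is.na(hom_p) || hom_p >= 0.05
  }
  tt <- stats::t.test(delta_active, delta_sham, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       method = if (var_equal) "pooled" else "welch", homogeneity_p = hom_p)
}

.levene_p <- function(a, b) {
  values <- c(a, b)
  grp <- factor(rep(c("a", "b"), c(length(a), length(b))))
  lt <- car::leveneTest(values, grp, center = stats::median)
  lt[["Pr(>F)"]][1]
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjusted p values (`p.adjust(method = "BH")`) and the rejection
#' mask at level `q`.
#'
#' @param p_values Vector of raw p values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `p_adjusted` and logical `reject`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, reject = adj <= q)
}

#' One-sample follow-up contrast
#'
#' One-sample t test of a group's per-subject changes against zero, with a
#' one-tailed p value in the stated direction. Used to unpack significant
#' double contrasts; by the gatekeeping convention it is only run for pairs
#' that survived the FDR-corrected double contrast.
#'
#' @param delta_group Per-subject `dz` values (length >= 2, non-constant).
#' @param direction `"increase"` (mean > 0) or `"decrease"` (mean < 0).
#' @return List with `t`, `p` (one-tailed), `df`, `direction`.
#' @export
followup_simple <- function(delta_group, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (length(delta_group) < 2) stop("need at least 2 subjects", call. = FALSE)
  if (stats::var(delta_group) == 0) {
    stop("zero variance; t test undefined", call. = FALSE)
  }
  tt <- stats::t.test(delta_group, mu = 0,
                      alternative = if (direction == "increase") "greater" else "less")
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       direction = direction)
}

#' Normality and homogeneity diagnostics
#'
#' Shapiro-Wilk normality check per group and a Levene-type (median-centred)
#' variance-homogeneity check. Diagnostics only: they flag, never block.
#'
#' @param delta_active,delta_sham Per-subject `dz` values (>= 3 each to
#'   assess).
#' @param alpha Flagging level (default 0.05).
#' @return List with `normality_p` (named, per group), `homogeneity_p`,
#'   logical flags `normality_ok`, `homogeneity_ok`, and `assessable`.
#' @export
assumption_checks <- function(delta_active, delta_sham, alpha = 0.05) {
  assessable <- length(delta_active) >= 3 && length(delta_sham) >= 3 &&
    stats::var(delta_active) > 0 && stats::var(delta_sham) > 0
  if (!assessable) {
    return(list(normality_p = c(active = NA_real_, sham = NA_real_),
                homogeneity_p = NA_real_, normality_ok = NA,
                homogeneity_ok = NA, assessable = FALSE))
  }
  np <- c(active = stats::shapiro.test(delta_active)$p.value,
          sham = stats::shapiro.test(delta_sham)$p.value)
  hp <- .levene_p(delta_active, delta_sham)
  list(normality_p = np, homogeneity_p = hp,
       normality_ok = all(np >= alpha), homogeneity_ok = hp >= alpha,
       assessable = TRUE)
}

#' Family-wise double contrasts with FDR correction and follow-ups
#'
#' For each band and lag, runs the Post-Pre (Active-Sham) double contrast on
#' every ROI pair of the family, corrects the family's p values with
#' Benjamini-Hochberg FDR, and unpacks each surviving pair with one-tailed
#' within-group follow-up t tests whose directions are read from the sign of
#' each group's mean change (recorded in the output). The correction family
#' is the set of pairs within one band and lag, not pooled across bands or
#' lags; follow-ups are left uncorrected by the gatekeeping convention.
#'
#' @param coupling Coupling tibble (or pre-computed `dz` tibble from
#'   [delta_z()]).
#' @param q FDR level (default 0.05).
#' @param family Restrict to a pair set: `"intra_dmn"`, `"extra_dmn"`,
#'   `"other"`, or `NULL` to use every pair present.
#' @return Tibble with one row per band x lag x pair: double-contrast `t`,
#'   raw and FDR-adjusted p, significance, per-group mean changes, follow-up
#'   statistics (NA unless the double contrast survived), and assumption
#'   diagnostics.
#' @export
group_contrasts <- function(coupling, q = 0.05, family = "intra_dmn") {
  dz <- if ("dz" %in% names(coupling)) coupling else delta_z(coupling)
  if (!is.null(family) && "pair_set" %in% names(coupling)) {
    keep_pairs <- unique(coupling[coupling$pair_set %in% family,
                                  c("roi_a", "roi_b")])
    dz <- dz[paste(dz$roi_a, dz$roi_b) %in%
               paste(keep_pairs$roi_a, keep_pairs$roi_b), ]
  }
  if (nrow(dz) == 0) stop("no records in the requested family", call. = FALSE)
  out <- list()
  for (band in unique(dz$band)) {
    for (lag in unique(dz$lag)) {
      sub <- dz[dz$band == band & dz$lag == lag, ]
      pairs <- unique(sub[, c("roi_a", "roi_b")])
      rows <- vector("list", nrow(pairs))
      for (i in seq_len(nrow(pairs))) {
        cell <- sub[sub$roi_a == pairs$roi_a[i] & sub$roi_b == pairs$roi_b[i], ]
        da <- cell$dz[cell$group == "active"]
        ds <- cell$dz[cell$group == "sham"]
        chk <- assumption_checks(da, ds)
        dc <- double_contrast(da, ds,
                              var_equal = if (isFALSE(chk$homogeneity_ok)) FALSE else TRUE)
        rows[[i]] <- tibble::tibble(
          band = band, lag = lag,
          roi_a = pairs$roi_a[i], roi_b = pairs$roi_b[i],
          t_double = dc$t, p_double = dc$p, df = dc$df, method = dc$method,
          mean_dz_active = mean(da), mean_dz_sham = mean(ds),
          n_active = length(da), n_sham = length(ds),
          normality_p_active = chk$normality_p[["active"]],
          normality_p_sham = chk$normality_p[["sham"]],
          homogeneity_p = chk$homogeneity_p,
          assumptions_assessable = chk$assessable
        )
      }
      fam <- do.call(rbind, rows)
      corr <- fdr_bh(fam$p_double, q = q)
      fam$p_fdr <- corr$p_adjusted
      fam$significant <- corr$reject
      fam$dir_active <- ifelse(fam$mean_dz_active >= 0, "increase", "decrease")
      fam$dir_sham <- ifelse(fam$mean_dz_sham >= 0, "increase", "decrease")
      fam$t_active <- NA_real_
      fam$p_active_1t <- NA_real_
      fam$t_sham <- NA_real_
      fam$p_sham_1t <- NA_real_
      for (i in which(fam$significant)) {
        cell <- sub[sub$roi_a == fam$roi_a[i] & sub$roi_b == fam$roi_b[i], ]
        fa <- followup_simple(cell$dz[cell$group == "active"], fam$dir_active[i])
        fs <- followup_simple(cell$dz[cell$group == "sham"], fam$dir_sham[i])
        fam$t_active[i] <- fa$t
        fam$p_active_1t[i] <- fa$p
        fam$t_sham[i] <- fs$t
        fam$p_sham_1t[i] <- fs$p
      }
      out[[length(out) + 1]] <- fam
    }
  }
  do.call(rbind, out)
}

#' Post-minus-pre coupling-change matrix per group
#'
#' Mean change in Fisher-Z coupling per group, arranged as an ROI x ROI
#' matrix (active group in the upper triangle, sham in the lower), mirroring
#' the usual group-change connectivity matrix display.
#'
#' @param coupling Coupling tibble.
#' @param band Band to display.
#' @param lag Lag to display.
#' @return Square matrix with ROI dimnames; `NA` where a pair was not
#'   analyzed.
#' @export
coupling_change_matrix <- function(coupling, band = "alpha", lag = 0) {
  dz <- delta_z(coupling[coupling$band == band & coupling$lag == lag, ])
  rois <- sort(unique(c(dz$roi_a, dz$roi_b)))
  M <- matrix(NA_real_, length(rois), length(rois),
              dimnames = list(rois, rois))
  agg <- stats::aggregate(dz ~ roi_a + roi_b + group, data = dz, FUN = mean)
  for (i in seq_len(nrow(agg))) {
    a <- agg$roi_a[i]
    b <- agg$roi_b[i]
    if (agg$group[i] == "active") M[a, b] <- agg$dz[i] else M[b, a] <- agg$dz[i]
  }
  M
}
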