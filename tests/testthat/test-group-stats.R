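# Double contrasts, FDR, follow-ups, assumption diagnostics.

test_that("delta_z pairs each subject's sessions and flags incompleteness", {
  cp <- toy_coupling(z_pre = c(0.4, 0.1, -0.2, 0.3),
                     z_post = c(0.9, 0.1, 0.0, 0.5),
                     groups = c("active", "active", "sham", "sham"))
  dz <- delta_z(cp)
  expect_equal(nrow(dz), 4)
  expect_equal(dz$dz[dz$subject == "s01"], 0.5)
  expect_equal(dz$dz[dz$subject == "s02"], 0)

  broken <- cp[!(cp$subject == "s03" & cp$session == "post"), ]
  expect_error(delta_z(broken), "s03")
})

test_that("the double contrast matches the pooled-t formula and its symmetries", {
  a <- c(0.2, 0.4, 0.3)
  s <- c(-0.1, 0.0, -0.2)
  dc <- double_contrast(a, s, var_equal = TRUE)
  oracle <- pooled_t_oracle(a, s)
  expect_equal(dc$t, oracle$t, tolerance = 1e-12)
  expect_equal(dc$p, oracle$p, tolerance = 1e-12)
  expect_equal(dc$df, 4)

  swapped <- double_contrast(s, a, var_equal = TRUE)
  expect_equal(swapped$t, -dc$t, tolerance = 1e-12)
  expect_equal(swapped$p, dc$p, tolerance = 1e-12)

  same <- double_contrast(c(1, 2, 3), c(1, 2, 3), var_equal = TRUE)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(double_contrast(rep(1, 4), rep(1, 4)), "zero variance")
  expect_error(double_contrast(1, c(1, 2)), "at least 2")
})

test_that("the Welch fallback engages when variances are wildly unequal", {
  set.seed(1)
  a <- rnorm(16, sd = 10)
  s <- rnorm(16, sd = 0.1)
  dc <- double_contrast(a, s)
  expect_equal(dc$method, "welch")
  expect_lt(dc$homogeneity_p, 0.05)
  dc2 <- double_contrast(rnorm(16), rnorm(16))
  expect_equal(dc2$method, "pooled")
})

test_that("BH adjustment matches the brute-force step-up on fixed and random inputs", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r$p_adjusted, rep(0.04, 4))
  expect_true(all(r$reject))
  expect_equal(fdr_bh(0.03)$p_adjusted, 0.03)
  expect_equal(fdr_bh(rep(0.2, 6))$p_adjusted, rep(0.2, 6))

  set.seed(2)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    adj <- fdr_bh(p)$p_adjusted
    expect_equal(adj, bh_stepup_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    # monotone in the raw p values
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    perm <- sample(length(p))
    expect_equal(fdr_bh(p[perm])$p_adjusted, adj[perm], tolerance = 1e-12)
  }
  expect_error(fdr_bh(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("one-tailed follow-ups point in the requested direction", {
  set.seed(3)
  up <- 0.3 + rnorm(16, sd = 0.01)
  f <- followup_simple(up, "increase")
  expect_gt(f$t, 10)
  expect_lt(f$p, 1e-8)
  expect_equal(f$p, pt(f$t, df = 15, lower.tail = FALSE), tolerance = 1e-12)

  sym <- c(-0.4, -0.2, -0.1, 0.1, 0.2, 0.4)
  expect_equal(followup_simple(sym, "increase")$p, 0.5, tolerance = 1e-6)
  expect_gt(followup_simple(up, "decrease")$p, 0.5)
  expect_error(followup_simple(rep(0.2, 5), "increase"), "zero variance")
})

test_that("assumption diagnostics are calibrated on normal data and catch violations", {
  set.seed(4)
  normal_pass <- vapply(1:100, function(i) {
    chk <- assumption_checks(rnorm(16), rnorm(16))
    chk$normality_ok && chk$homogeneity_ok
  }, TRUE)
  expect_gte(mean(normal_pass), 0.8)

  hetero_fail <- vapply(1:100, function(i) {
    !assumption_checks(rnorm(16, sd = 10), rnorm(16, sd = 1))$homogeneity_ok
  }, TRUE)
  expect_gte(mean(hetero_fail), 0.9)

  flat <- assumption_checks(rep(1, 5), rep(1, 5))
  expect_false(flat$assessable)
})

test_that("group contrasts apply FDR per family and gatekeep the follow-ups", {
  set.seed(5)
  n <- 16
  pairs <- list(c("vPCC", "lAG"), c("vPCC", "rAG"), c("mPFC", "dPCC"))
  rows <- list()
  for (i in seq_along(pairs)) {
    shift <- if (i == 1) 0.8 else 0      # one pair carries a true effect
    z_pre <- rnorm(2 * n, sd = 0.2)
    z_post <- z_pre + rnorm(2 * n, sd = 0.1) +
      shift * rep(c(1, 0), each = n)
    cp <- toy_coupling(z_pre, z_post, rep(c("active", "sham"), each = n))
    cp$roi_a <- pairs[[i]][1]
    cp$roi_b <- pairs[[i]][2]
    rows[[i]] <- cp
  }
  res <- group_contrasts(do.call(rbind, rows))
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_fdr >= res$p_double - 1e-15))
  hit <- res$roi_a == "vPCC" & res$roi_b == "lAG"
  expect_true(res$significant[hit])
  expect_equal(res$dir_active[hit], "increase")
  expect_false(is.na(res$t_active[hit]))
  expect_true(all(is.na(res$t_active[!res$significant])))
})

test_that("the coupling-change matrix separates the groups by triangle", {
  cp <- toy_coupling(z_pre = c(0.1, 0.2, 0.1, 0.3),
                     z_post = c(0.6, 0.7, 0.0, 0.1),
                     groups = c("active", "active", "sham", "sham"))
  M <- coupling_change_matrix(cp)
  expect_equal(M["vPCC", "lAG"], 0.5)     # active mean post - pre
  expect_equal(M["lAG", "vPCC"], -0.15)   # sham mean
})
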