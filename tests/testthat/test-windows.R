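# Gaussian taper, window scheme arithmetic, weighted correlation, windowed FC.

test_that("Gaussian taper follows the FWHM definition and is symmetric", {
  w <- gaussian_taper(60, 27.78)
  expect_length(w, 60)
  expect_equal(w, rev(w), tolerance = 1e-12)
  expect_lte(max(w), 1)
  expect_gt(max(w), 0.999)

  # the continuous curve drops to 1/2 at FWHM/2 from the centre; the discrete
  # weights bracket 0.5 there
  sigma <- 27.78 / (2 * sqrt(2 * log(2)))
  expect_equal(exp(-(27.78 / 2)^2 / (2 * sigma^2)), 0.5, tolerance = 1e-12)
  centre <- (60 - 1) / 2
  inner <- w[floor(centre + 13.89) + 1]    # just inside the half-width
  outer <- w[ceiling(centre + 13.89) + 1]  # just outside
  expect_gt(inner, 0.5)
  expect_lt(outer, 0.5)
  expect_lt(inner - outer, 0.06)           # the discrete weights bracket 0.5

  expect_true(all(abs(gaussian_taper(5, 1e9) - 1) < 1e-12))
  expect_error(gaussian_taper(60, 0), "positive")
  expect_error(gaussian_taper(1, 5), ">= 2")
})

test_that("window scheme arithmetic matches the closed forms", {
  ws <- make_window_scheme(306, 60, 1, 27.78, 1.8)
  expect_equal(ws$n_windows, 247)
  expect_equal(ws$duration_s, 108)
  expect_equal(ws$overlap_s, 106.2)
  expect_equal(make_window_scheme(60, 60, 1, 27.78, 1.8)$n_windows, 1)
  expect_error(make_window_scheme(50, 60), "shorter")

  set.seed(1)
  for (i in 1:25) {
    n <- sample(20:400, 1)
    L <- sample(5:min(n, 80), 1)
    s <- sample(1:5, 1)
    ws <- make_window_scheme(n, L, s, 10, 1.8)
    expect_equal(ws$n_windows, floor((n - L) / s) + 1)
    expect_equal(ws$overlap_s, (L - s) * 1.8)
    expect_equal(ws$duration_s, L * 1.8)
    expect_true(all(ws$starts + L - 1 <= n))
  }
})

test_that("weighted Pearson reduces to ordinary correlation and handles edge cases", {
  set.seed(2)
  for (i in 1:50) {
    x <- rnorm(30)
    y <- rnorm(30)
    expect_equal(weighted_pearson(x, y), cor(x, y), tolerance = 1e-12)
    w <- runif(30)
    expect_equal(weighted_pearson(x, y, w), weighted_pearson(x, y, w * 7.3),
                 tolerance = 1e-12)
  }
  x <- rnorm(20)
  w <- runif(20)
  expect_equal(weighted_pearson(x, 2 * x + 3, w), 1, tolerance = 1e-12)
  expect_equal(weighted_pearson(x, -x, w), -1, tolerance = 1e-12)
  expect_error(weighted_pearson(rep(1, 10), rnorm(10)), "variance in `x`")
  expect_error(weighted_pearson(rnorm(10), rnorm(10), rep(0, 10)), "positive sum")
  expect_error(weighted_pearson(rnorm(10), rnorm(9)), "equal length")
})

test_that("windowed FC matches a direct weighted-correlation loop", {
  set.seed(3)
  X <- matrix(rnorm(306 * 4), ncol = 4,
              dimnames = list(NULL, c("A", "B", "C", "D")))
  ts <- roi_timeseries(X, tr = 1.8)
  sch <- make_window_scheme(306)
  for (weighted in c(TRUE, FALSE)) {
    fc <- fc_timeseries(ts, sch, pairs = rbind(c("A", "B"), c("C", "D")),
                        weighted = weighted)
    w <- if (weighted) sch$taper else NULL
    ref <- vapply(sch$starts, function(s) {
      weighted_pearson(X[s:(s + 59), "A"], X[s:(s + 59), "B"], w)
    }, 1)
    expect_equal(fc$values[, "A~B"], ref, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(nrow(fc$values), 247)
  }
})

test_that("a duplicated ROI gives unit FC and constant signal is rejected", {
  set.seed(4)
  x <- rnorm(306)
  ts <- roi_timeseries(cbind(A = x, B = x, C = rnorm(306)), tr = 1.8)
  sch <- make_window_scheme(306)
  fc <- fc_timeseries(ts, sch, pairs = rbind(c("A", "B")))
  expect_true(all(abs(fc$values - 1) < 1e-12))

  ts2 <- roi_timeseries(cbind(A = rep(1, 306), B = rnorm(306)), tr = 1.8)
  expect_error(fc_timeseries(ts2, sch, pairs = rbind(c("A", "B"))),
               "degenerate")
})

test_that("windowed FC of independent noise is centred on zero", {
  set.seed(5)
  sch <- make_window_scheme(306)
  m <- vapply(1:40, function(i) {
    ts <- roi_timeseries(matrix(rnorm(306 * 2), ncol = 2,
                                dimnames = list(NULL, c("A", "B"))), tr = 1.8)
    mean(fc_timeseries(ts, sch, pairs = rbind(c("A", "B")))$values)
  }, 1)
  expect_lt(abs(mean(m)), 0.1)
})

test_that("pair specifications resolve against the network map", {
  nets <- default_roi_networks()
  labels <- names(nets)
  dmn <- resolve_pairs("dmn", labels, nets)
  expect_equal(nrow(dmn), 10)            # choose(5, 2) DMN hub pairs
  expect_true(all(dmn$set == "intra_dmn"))
  ex <- resolve_pairs("extra_dmn", labels, nets)
  expect_equal(nrow(ex), 5 * 7)
  expect_true(all(ex$set == "extra_dmn"))
  expect_equal(nrow(resolve_pairs("all", labels, nets)), choose(12, 2))
  expect_error(resolve_pairs(rbind(c("vPCC", "nope")), labels, nets), "nope")
})

test_that("Fisher Z is the inverse hyperbolic tangent with guarded domain", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  # odd symmetry
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  expect_error(fisher_z(1), ">= 1")
  expect_error(fisher_z(-1.2), ">= 1")
})

test_that("coupling recovers a known lag and rejects degenerate inputs", {
  set.seed(6)
  p <- as.numeric(stats::filter(rnorm(260), rep(1, 10), sides = 1))[10:256]
  fc <- c(rep(NA, 3), p)[1:247] + rnorm(247, sd = 1e-4)
  fc[1:3] <- rnorm(3)
  r_by_lag <- vapply(0:5, function(l) couple(fc, p, lag_trs = l)$r, 1)
  expect_equal(which.max(r_by_lag) - 1, 3)
  expect_gt(max(r_by_lag), 0.99)

  expect_error(couple(p, p, lag_trs = 0), ">= 1")       # r = 1 exactly
  expect_error(couple(p, p, lag_trs = -1), "non-negative")
  expect_error(couple(p[1:12], p[1:12], lag_trs = 5), "overlap")
})

test_that("null coupling between smoothed independent series matches the MC oracle", {
  # The 60-epoch Gaussian window leaves few effective degrees of freedom in a
  # 247-window series, so the null coupling is wide. The oracle here is plain
  # cor() between independently smoothed white-noise series; couple() must
  # reproduce its centre and spread.
  set.seed(7)
  sch <- make_window_scheme(306)
  smooth_white <- function() smooth_power_series(rnorm(306), sch)
  r_couple <- vapply(1:200, function(i) couple(smooth_white(), smooth_white())$r, 1)
  r_oracle <- vapply(1:200, function(i) cor(smooth_white(), smooth_white()), 1)
  expect_lt(abs(mean(r_couple)), 0.06)
  expect_lt(abs(sd(r_couple) - sd(r_oracle)), 0.2 * sd(r_oracle))
  expect_lt(quantile(abs(r_couple), 0.95), 0.7)
})

test_that("adjusted coupling subtracts the mean extra-DMN value", {
  expect_equal(adjusted_coupling(0.7, c(0, 0, 0)), 0.7)
  expect_equal(adjusted_coupling(0.8, c(0.2, 0.4)), 0.5)
  c0 <- adjusted_coupling(0.8, c(0.2, 0.4))
  expect_equal(adjusted_coupling(0.8 + 3, c(0.2, 0.4) + 3), c0)
  expect_error(adjusted_coupling(0.5, numeric(0)), "at least one")
})
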