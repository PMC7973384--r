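test_that("auto- and cross-correlation match the double-loop oracle to 1e-12", {
  set.seed(101)
  for (i in 1:15) {
    T_len <- sample(20:200, 1)
    x <- random_series(T_len, seed = 1000 + i)
    y <- random_series(T_len, seed = 2000 + i)
    n_lag <- sample(5:min(15, T_len - 2), 1)
    ac <- autocorrelation(x, max_lag = n_lag * 5)
    expect_lt(max(abs(ac$values - oracle_autocorr(x$probs, n_lag))), 1e-12)
    cc <- crosscorrelation(x, y, max_lag = n_lag * 5)
    expect_lt(max(abs(cc$values - oracle_crosscorr(x$probs, y$probs, n_lag))),
              1e-12)
  }
})

test_that("autocorrelation is exactly 1 at lag zero; constant series error", {
  for (i in 1:10) {
    x <- random_series(60, seed = 300 + i)
    expect_identical(autocorrelation(x, max_lag = 50)$values[1], 1)
  }
  const <- hypnodensity(diag(5)[rep(2, 30), ])
  expect_error(autocorrelation(const, max_lag = 50), "degenerate|variance")
  x <- random_series(30, seed = 1)
  expect_error(autocorrelation(x, max_lag = 200), "max_lag")
})

test_that("cross-correlation of a series with itself equals its autocorrelation", {
  x <- random_series(120, seed = 9)
  ac <- autocorrelation(x, max_lag = 100)
  cc <- crosscorrelation(x, x, max_lag = 100)
  expect_lt(max(abs(ac$values - cc$values)), 1e-12)
})

test_that("shifting a series by k frames moves the cross-correlation peak to lag k", {
  base <- random_series(80, seed = 55)
  for (k in c(3L, 7L)) {
    T_common <- 60L
    x <- hypnodensity(base$probs[1:T_common, ], step_seconds = 5)
    y <- hypnodensity(base$probs[(1 + k):(T_common + k), ], step_seconds = 5)
    # y lags x by k frames: x_t aligns with y_{t} shifted back, so the
    # argmax of r_yx sits at tau = k
    cc <- crosscorrelation(y, x, max_lag = 20 * 5)
    expect_equal(which.max(cc$values) - 1L, k)
  }
})

test_that("symmetric cross-correlation mirrors the swapped-argument curve", {
  x <- random_series(90, seed = 12)
  y <- random_series(90, seed = 13)
  sym <- crosscorrelation(x, y, max_lag = 60, symmetric = TRUE)
  fwd <- crosscorrelation(x, y, max_lag = 60)
  rev_ <- crosscorrelation(y, x, max_lag = 60)
  n <- length(fwd$values)
  expect_equal(sym$values[n:(2 * n - 1)], fwd$values)
  expect_equal(sym$values[n:1], rev_$values)
  expect_equal(sym$lags, c(-rev(fwd$lags[-1]), fwd$lags))
})

test_that("consistent stage relabeling leaves the correlation unchanged", {
  x <- random_series(100, seed = 21)
  y <- random_series(100, seed = 22)
  perm <- c(3, 1, 5, 2, 4)
  xp <- hypnodensity(x$probs[, perm], step_seconds = 5)
  yp <- hypnodensity(y$probs[, perm], step_seconds = 5)
  expect_equal(crosscorrelation(xp, yp, max_lag = 80)$values,
               crosscorrelation(x, y, max_lag = 80)$values, tolerance = 1e-12)
})

test_that("peak detection finds cosine maxima and reports no-cycle on monotone curves", {
  step <- 5
  lags <- seq(0, 3600, by = step)
  P <- 1200  # 20-min period
  curve <- structure(list(lags = lags, values = cos(2 * pi * lags / P),
                          kind = "auto", channel_x = "X", channel_y = "X",
                          T = length(lags), step_seconds = step),
                     class = "corr_curve")
  pe <- detect_local_maxima(curve, min_lag = P / 2, smooth_width = 60,
                            min_prominence = 0.1)
  expect_equal(pe$status, "ok")
  expect_true(all(abs(pe$maxima_lags - c(P, 2 * P)) <= step))
  expect_equal(pe$period_seconds, pe$maxima_lags[1])

  mono <- structure(list(lags = lags, values = exp(-lags / 500),
                         kind = "auto", channel_x = "X", channel_y = "X",
                         T = length(lags), step_seconds = step),
                    class = "corr_curve")
  pe2 <- detect_local_maxima(mono, min_lag = 60)
  expect_equal(pe2$status, "no cycle detected")
  expect_true(is.na(pe2$period_seconds))
  expect_error(detect_local_maxima(curve, min_lag = 0), "min_lag")
})

test_that("a synthetic 75-min night shows maxima near 75 and 150 min", {
  h <- simulate_hypnogram(cyclic_sleep_model(cycle_period = 75 * 60),
                          seed = 4)
  s <- simulate_noisy_hypnodensity(h, seed = 4)
  ac <- autocorrelation(s, max_lag = 240 * 60)
  pe <- detect_local_maxima(ac)
  expect_equal(pe$status, "ok")
  expect_lt(abs(pe$period_seconds - 75 * 60), 2 * s$step_seconds + 1e-9)
  expect_gte(length(pe$maxima_lags), 2L)
  expect_lt(abs(pe$maxima_lags[2] - 150 * 60), 3 * s$step_seconds + 1e-9)
})

test_that("channel correlation matrix has autocurves on the diagonal and peaks at zero lag", {
  h <- simulate_hypnogram(cyclic_sleep_model(total_duration = 4 * 3600),
                          seed = 6)
  chs <- simulate_multichannel(h, channels = c("C4", "F4", "O2"), seed = 6)
  m <- channel_correlation_summary(chs, max_lag = 3600)
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(m[["C4", "C4"]]$values,
               autocorrelation(chs$C4, max_lag = 3600)$values)
  for (i in 1:3) for (j in 1:3) {
    if (i != j) {
      expect_equal(m[[i, j]]$kind, "cross")
      expect_equal(which.max(m[[i, j]]$values), 1L)  # zero-lag peak
    }
  }
  # three identical channels: all nine curves identical with r(0) = 1
  same <- list(chs$C4,
               hypnodensity(chs$C4$probs, step_seconds = 5, channel = "b"),
               hypnodensity(chs$C4$probs, step_seconds = 5, channel = "c"))
  ms <- channel_correlation_summary(same, max_lag = 1800)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(ms[[i, j]]$values, ms[[1, 1]]$values, tolerance = 1e-12)
    expect_equal(ms[[i, j]]$values[1], 1)
  }
})

test_that("windowed period tracking is flat for stationary nights and rises with the period", {
  # stationary: 90-min cycles, three 160-min parts; dwell jitter off so the
  # only variation across parts is frame-level probability noise
  h <- simulate_hypnogram(cyclic_sleep_model(cycle_period = 90 * 60,
                                             dwell_jitter = 0,
                                             wake_insertion_rate = 0),
                          seed = 8)
  s <- simulate_noisy_hypnodensity(h, seed = 8)
  expect_warning(
    tr <- windowed_period_track(s, part_duration = 160 * 60,
                                max_lag = 120 * 60),
    "4 expected periods")
  expect_equal(nrow(tr), 3L)
  expect_true(all(tr$status == "ok"))
  expect_lte(diff(range(tr$period_seconds)), s$step_seconds * 2)

  # a single part spanning the record reproduces the global estimate
  one <- windowed_period_track(s, part_duration = 8 * 3600,
                               max_lag = 240 * 60, expected_period = 5400)
  glob <- detect_local_maxima(autocorrelation(s, max_lag = 240 * 60))
  expect_equal(one$period_seconds[1], glob$period_seconds)

  # piecewise-lengthening cycles: estimates must increase across parts
  mk <- function(P, seed) simulate_noisy_hypnodensity(
    simulate_hypnogram(cyclic_sleep_model(cycle_period = P * 60,
                                          total_duration = 160 * 60,
                                          dwell_jitter = 0.05,
                                          wake_insertion_rate = 0),
                       seed = seed), seed = seed)
  parts <- lapply(c(70, 90, 110), function(P) mk(P, seed = P))
  probs <- do.call(rbind, lapply(parts, function(p) p$probs))
  long <- hypnodensity(probs, step_seconds = 5, window_seconds = 30)
  expect_warning(
    tr2 <- windowed_period_track(long, part_duration = 160 * 60,
                                 max_lag = 130 * 60))
  expect_true(all(tr2$status == "ok"))
  expect_true(all(diff(tr2$period_seconds) > 0))
})
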