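test_that("noise-free simulation is exactly periodic and seed-reproducible", {
  m <- cyclic_sleep_model(cycle_period = 90 * 60, dwell_jitter = 0,
                          wake_insertion_rate = 0)
  h <- simulate_hypnogram(m, seed = 1)
  expect_length(h$stages, 8 * 120)           # 8 h of 30-s epochs
  expect_identical(h$stages[1:180], h$stages[181:360])  # 180-epoch period
  expect_identical(simulate_hypnogram(m, seed = 5)$stages,
                   simulate_hypnogram(m, seed = 5)$stages)
  expect_false(identical(
    simulate_hypnogram(cyclic_sleep_model(), seed = 1)$stages,
    simulate_hypnogram(cyclic_sleep_model(), seed = 2)$stages))
  expect_error(simulate_hypnogram(
    cyclic_sleep_model(total_duration = 60 * 60, cycle_period = 90 * 60)),
    "at least one cycle")
})

test_that("realized cycle lengths stay within 2% of the nominal period", {
  m <- cyclic_sleep_model(cycle_period = 90 * 60, wake_insertion_rate = 0)
  # cycle length read off as the spacing of template restarts (N1 onsets)
  lens <- unlist(lapply(1:50, function(s) {
    h <- simulate_hypnogram(m, seed = s)
    prev <- c(0L, h$stages[-length(h$stages)])
    restarts <- which(h$stages == 2L & prev == 5L)   # REM -> N1 boundary
    diff(restarts)
  }))
  expect_lt(abs(mean(lens) * 30 - 90 * 60), 0.02 * 90 * 60)
})

test_that("noisy hypnodensity rows live on the simplex with faithful argmax", {
  h <- simulate_hypnogram(cyclic_sleep_model(total_duration = 2 * 3600),
                          seed = 2)
  acc <- vapply(1:20, function(s) {
    hd <- simulate_noisy_hypnodensity(h, seed = s)
    expect_true(validate_series(hd)$ok)
    truth <- rep(h$stages, each = 6)
    mean(max.col(hd$probs, ties.method = "first") == truth)
  }, numeric(1))
  expect_gte(mean(acc), 0.9)

  # concentration -> infinity with an identity kernel: the one-hot limit
  sharp <- simulate_noisy_hypnodensity(
    h, noise_model(concentration = 1e7, confusion_kernel = diag(5)),
    seed = 1)
  onehot <- hypnogram_to_hypnodensity(h, step_seconds = 5)
  expect_lt(max(abs(sharp$probs - onehot$probs)), 1e-2)

  expect_error(noise_model(confusion_kernel = matrix(0, 5, 5)), "zero")
  expect_identical(simulate_noisy_hypnodensity(h, seed = 3)$probs,
                   simulate_noisy_hypnodensity(h, seed = 3)$probs)
})

test_that("multichannel simulation shares the clock but draws independent noise", {
  h <- simulate_hypnogram(cyclic_sleep_model(total_duration = 3 * 3600),
                          seed = 10)
  nm <- noise_model(channel_bias = list(C4 = c(3, 1, 1, 1, 1)))
  chs <- simulate_multichannel(h, nm, channels = c("C4", "F4"), seed = 10)
  expect_named(chs, c("C4", "F4"))
  # wake-inflating bias raises mean Wake probability on that channel
  expect_gt(mean(chs$C4$probs[, 1]), mean(chs$F4$probs[, 1]))
  # shared generative clock: cross-correlation peaks at zero lag
  cc <- crosscorrelation(chs$C4, chs$F4, max_lag = 3600)
  expect_equal(which.max(cc$values), 1L)
  expect_error(
    simulate_multichannel(h, noise_model(channel_bias = list(ZZ = rep(1, 5))),
                          channels = c("C4", "F4")),
    "unknown channel")
})

test_that("embedding generator controls class separation deterministically", {
  e <- simulate_embeddings(3, 50, 10, separation = 4, seed = 7)
  expect_equal(nrow(e$points), 150L)
  expect_equal(nlevels(e$labels), 3L)
  cents <- apply(e$points, 2, function(col) tapply(col, e$labels, mean))
  d12 <- sqrt(sum((cents[1, ] - cents[2, ])^2))
  d13 <- sqrt(sum((cents[1, ] - cents[3, ])^2))
  expect_lt(abs(d12 - 4), 0.8)
  expect_lt(abs(d13 - 4), 0.8)
  expect_identical(simulate_embeddings(2, 20, 5, 1, seed = 3)$points,
                   simulate_embeddings(2, 20, 5, 1, seed = 3)$points)
  expect_error(simulate_embeddings(6, 10, 5, 1), "n_classes <= dim")
})

test_that("stage-signatured EEG has the expected spectral peaks", {
  h <- hypnogram(rep(c("N3", "Wake"), each = 10))
  x <- simulate_stage_eeg(h, seed = 1)
  rate <- attr(x, "sample_rate")
  band_power <- function(seg, lo, hi) {
    sp <- stats::spec.pgram(stats::ts(seg, frequency = rate), plot = FALSE,
                            taper = 0)
    sum(sp$spec[sp$freq >= lo & sp$freq < hi])
  }
  n3 <- x[1:(10 * 30 * rate)]
  wk <- x[(10 * 30 * rate + 1):(20 * 30 * rate)]
  # N3: dominant power below 4 Hz
  expect_gt(band_power(n3, 0, 4), band_power(n3, 4, 32))
  # Wake: alpha band 8-12 Hz beats neighbouring bands of equal width
  expect_gt(band_power(wk, 8, 12), band_power(wk, 4, 8))
  expect_gt(band_power(wk, 8, 12), band_power(wk, 12, 16))
  expect_identical(simulate_stage_eeg(h, seed = 2),
                   simulate_stage_eeg(h, seed = 2))
})

test_that("end-to-end period recovery works for 75- and 100-min cycles", {
  for (P in c(75, 100)) {
    hits <- vapply(1:10, function(s) {
      h <- simulate_hypnogram(cyclic_sleep_model(cycle_period = P * 60),
                              seed = s)
      hd <- simulate_noisy_hypnodensity(h, seed = s)
      pe <- detect_local_maxima(autocorrelation(hd, max_lag = 240 * 60))
      pe$status == "ok" && abs(pe$period_seconds - P * 60) <= 5
    }, logical(1))
    expect_gte(mean(hits), 0.9)
  }
})
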