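test_that("validate_series accepts valid series and names the first violation", {
  ok <- hypnodensity(diag(5)[1:3, ])
  expect_true(validate_series(ok)$ok)

  bad <- ok
  bad$probs[1, ] <- c(0.2, 0.2, 0.2, 0.1, 0.1)  # sums to 0.8
  v <- validate_series(bad)
  expect_false(v$ok)
  expect_match(v$message, "row 1 sum 0.8")

  neg <- ok
  neg$probs[2, ] <- c(-0.1, 0.3, 0.3, 0.3, 0.2)
  expect_match(validate_series(neg)$message, "outside")

  untimely <- ok
  untimely$times <- c(15, 10, 20)
  expect_false(validate_series(untimely)$ok)

  gen <- simulate_noisy_hypnodensity(
    simulate_hypnogram(cyclic_sleep_model(), seed = 3), seed = 3)
  expect_true(validate_series(gen)$ok)
})

test_that("hypnogram <-> hypnodensity conversions follow the one-hot and argmax rules", {
  h <- hypnogram(c("Wake", "N2"))
  s <- hypnogram_to_hypnodensity(h, step_seconds = 30)
  expect_equal(unname(s$probs),
               rbind(c(1, 0, 0, 0, 0), c(0, 0, 1, 0, 0)))

  # one 30-s REM epoch tiles into six 5-s one-hot frames
  s6 <- hypnogram_to_hypnodensity(hypnogram("REM"), step_seconds = 5)
  expect_equal(nrow(s6$probs), 6L)
  expect_true(all(s6$probs[, 5] == 1))
  expect_equal(s6$times, 2.5 + (0:5) * 5)

  expect_error(hypnogram_to_hypnodensity(h, step_seconds = 7),
               "divide")

  # argmax collapse with lowest-index tie-break
  s <- hypnodensity(rbind(c(0.1, 0.1, 0.6, 0.1, 0.1),
                          c(0.5, 0.5, 0, 0, 0)))
  hh <- hypnodensity_to_hypnogram(s)
  expect_equal(stage_labels()[hh$stages], c("N2", "Wake"))
})

test_that("artifact epochs are dropped per the gap policy", {
  h <- hypnogram(c("Wake", "N2", "N3"), artifact = c(FALSE, TRUE, FALSE))
  expect_warning(s <- hypnogram_to_hypnodensity(h, step_seconds = 30),
                 "artifact")
  expect_equal(nrow(s$probs), 2L)
  expect_equal(unname(s$probs[, 1]), c(1, 0))   # Wake then N3
  expect_equal(unname(s$probs[, 4]), c(0, 1))
  expect_equal(diff(s$times), 30)               # contiguous time base

  segs <- hypnogram_to_hypnodensity(h, step_seconds = 30, gap = "split")
  expect_length(segs, 2L)
  expect_equal(segs[[2]]$times, 75)             # original timestamps kept
})

test_that("round-trip hypnogram -> hypnodensity -> hypnogram is the identity", {
  set.seed(42)
  for (i in 1:20) {
    h <- hypnogram(sample(1:5, 40, replace = TRUE))
    s <- hypnogram_to_hypnodensity(h, step_seconds = 5)
    back <- hypnodensity_to_hypnogram(s)
    expect_equal(rep(h$stages, each = 6), back$stages)
    # at equal resolution the round trip is exactly the identity
    s30 <- hypnogram_to_hypnodensity(h, step_seconds = 30)
    expect_identical(hypnodensity_to_hypnogram(s30)$stages, h$stages)
  }
})

test_that("sliding_window_times emits only fully contained window centers", {
  expect_equal(sliding_window_times(60, 30, 5), seq(15, 45, by = 5))
  expect_equal(sliding_window_times(30, 30, 5), 15)
  expect_length(sliding_window_times(29, 30, 5), 0L)
  # brute-force enumeration over a parameter grid
  for (rec in c(35, 60, 100, 3600)) for (st in c(5, 10, 30)) {
    centers <- sliding_window_times(rec, 30, st)
    k <- 0; expected <- c()
    while (30 + k * st <= rec + 1e-9) {
      expected <- c(expected, 15 + k * st); k <- k + 1
    }
    expect_equal(centers, expected)
    expect_length(centers, floor((rec - 30) / st) + 1)
  }
})

test_that("hypnodensity CSV I/O round-trips losslessly and rejects bad files", {
  s <- random_series(100, seed = 7)
  f <- tempfile(fileext = ".csv")
  write_hypnodensity_csv(s, f)
  s2 <- read_hypnodensity_csv(f)
  expect_lt(max(abs(s2$probs - s$probs)), 1e-12)
  expect_lt(max(abs(s2$times - s$times)), 1e-12)
  expect_equal(readLines(f, n = 1), "time_s,Wake,N1,N2,N3,REM")

  f4 <- tempfile(fileext = ".csv")
  writeLines(c("time_s,Wake,N1,N2,N3,REM", "2.5,0.5,0.5,0"), f4)
  expect_error(read_hypnodensity_csv(f4), "column count at line 2")

  fbad <- tempfile(fileext = ".csv")
  writeLines(c("# comment", "time_s,Wake,N1,N2,N3,REM",
               "2.5,0.2,0.2,0.2,0.2,0.2",
               "7.5,0.5,0.5,0.3,0.1,0.1"), fbad)
  expect_error(read_hypnodensity_csv(fbad), "line 4")
})

test_that("hypnogram TSV I/O round-trips including artifacts", {
  h <- hypnogram(c("Wake", "N1", "N2", "N3", "REM"),
                 artifact = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  f <- tempfile(fileext = ".tsv")
  write_hypnogram_tsv(h, f)
  h2 <- read_hypnogram_tsv(f)
  expect_identical(h2$stages, h$stages)
  expect_identical(h2$artifact, h$artifact)
  fbad <- tempfile(fileext = ".tsv")
  writeLines(c("epoch_index\tstage\tartifact", "0\tXX\t0"), fbad)
  expect_error(read_hypnogram_tsv(fbad), "unknown stage")
})

test_that("dataset split reproduces the 80/20 convention with round-half-down", {
  s <- train_test_split_datasets(68, 0.8, seed = 11)
  expect_length(s$train, 54L)
  expect_length(s$test, 14L)
  expect_setequal(c(s$train, s$test), 1:68)
  expect_length(intersect(s$train, s$test), 0L)

  expect_length(train_test_split_datasets(10, 0.8, seed = 1)$train, 8L)
  # exact half rounds down
  expect_length(train_test_split_datasets(5, 0.5, seed = 1)$train, 2L)

  expect_identical(train_test_split_datasets(30, 0.8, seed = 5),
                   train_test_split_datasets(30, 0.8, seed = 5))
  expect_error(train_test_split_datasets(10, 1.2, seed = 1), "between")
})
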