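#' Construct a hypnodensity series
#'
#' A hypnodensity series is a time-ordered sequence of probability
#' distributions over the five sleep stages: at each time step it records not
#' just the most probable stage (as a hypnogram does) but the full softmax-like
#' probability vector, capturing scoring uncertainty. Each row lives on the
#' 4-simplex: entries in \[0, 1\] summing to 1.
#'
#' Rows summarize an analysis window of `window_seconds` width; `times` holds
#' the window-center timestamps, spaced `step_seconds` apart.
#'
#' @param probs Numeric T x 5 matrix of stage probabilities, columns in
#'   canonical stage order (Wake, N1, N2, N3, REM).
#' @param times Window-center timestamps in seconds from record start;
#'   strictly increasing with constant step. Defaults to
#'   `window_seconds/2 + (0:(T-1)) * step_seconds`.
#' @param step_seconds Sampling step of the series in seconds; default 5.
#' @param window_seconds Width of the analysis window each row summarizes;
#'   default 30.
#' @param channel Free-text channel label (e.g. `"C4"`, `"F4"`, `"O2"`).
#' @param validate Check invariants on construction (default `TRUE`).
#' @return Object of class `"hypnodensity"`: list with `probs`, `times`,
#'   `step_seconds`, `window_seconds`, `channel`.
#' @examples
#' p <- matrix(0.2, nrow = 4, ncol = 5)
#' s <- hypnodensity(p)
#' print(s)
#' @export
hypnodensity <- function(probs, times = NULL, step_seconds = 5,
                         window_seconds = 30, channel = "EEG",
                         validate = TRUE) {
  probs <- as.matrix(probs)
  if (ncol(probs) != N_STAGES)
    stop("probs must have exactly 5 columns (Wake, N1, N2, N3, REM)",
         call. = FALSE)
  storage.mode(probs) <- "double"
  colnames(probs) <- stage_labels()
  if (is.null(times))
    times <- window_seconds / 2 + (seq_len(nrow(probs)) - 1) * step_seconds
  x <- structure(list(probs = probs, times = as.numeric(times),
                      step_seconds = as.numeric(step_seconds),
                      window_seconds = as.numeric(window_seconds),
                      channel = as.character(channel)),
                 class = "hypnodensity")
  if (validate) {
    v <- validate_series(x)
    if (!v$ok) stop("invalid hypnodensity series: ", v$message, call. = FALSE)
  }
  x
}

#' Validate a hypnodensity series
#'
#' Checks the series invariants without mutating it: probabilities in
#' \[0, 1\], each row summing to 1 within `tol`, timestamps matching the row
#' count, strictly increasing on a constant grid of `step_seconds`, and all
#' values finite.
#'
#' @param series A [hypnodensity()] object (or a bare list with the same
#'   fields).
#' @param tol Row-sum tolerance; default `1e-6`.
#' @return List with `ok` (logical) and `message` (empty string if `ok`,
#'   otherwise a description of the first violated invariant).
#' @examples
#' s <- hypnodensity(diag(5)[c(1, 3, 5), ])
#' validate_series(s)$ok
#' @export
validate_series <- function(series, tol = 1e-6) {
  fail <- function(msg) list(ok = FALSE, message = msg)
  p <- series$probs
  if (is.null(p) || !is.matrix(p) || ncol(p) != N_STAGES)
    return(fail("probs must be a matrix with 5 columns"))
  if (nrow(p) < 1L) return(fail("series has no rows"))
  if (any(!is.finite(p))) {
    i <- which(!is.finite(p), arr.ind = TRUE)[1L, 1L]
    return(fail(sprintf("row %d contains non-finite probability", i)))
  }
  if (any(p < 0) || any(p > 1)) {
    i <- which(p < 0 | p > 1, arr.ind = TRUE)[1L, 1L]
    return(fail(sprintf("row %d has probability outside [0,1]", i)))
  }
  rs <- rowSums(p)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad))
    return(fail(sprintf("row %d sum %.6g", bad[1L], rs[bad[1L]])))
  if (length(series$times) != nrow(p))
    return(fail("length(times) differs from number of rows"))
  if (nrow(p) > 1L) {
    d <- diff(series$times)
    if (any(d <= 0)) return(fail("times not strictly increasing"))
    if (any(abs(d - series$step_seconds) > 1e-9 * max(1, series$step_seconds)))
      return(fail("times not on a constant step_seconds grid"))
  }
  list(ok = TRUE, message = "")
}

#' @export
print.hypnodensity <- function(x, ...) {
  cat(sprintf(
    "Hypnodensity series [%s]: %d frames, step %g s, window %g s, %.2f h\n",
    x$channel, nrow(x$probs), x$step_seconds, x$window_seconds,
    (utils::tail(x$times, 1) - x$times[1] + x$step_seconds) / 3600))
  mp <- colMeans(x$probs)
  cat("Mean stage probabilities:\n")
  print(round(mp, 4))
  invisible(x)
}

#' Mean stage-probability vector of a series
#'
#' The per-stage mean over all frames; the centering vector used by the
#' hypnodensity correlation formulas.
#'
#' @param series A [hypnodensity()].
#' @return Named numeric vector of 5 stage-probability means.
#' @export
mean_probability_vector <- function(series) colMeans(series$probs)

#' Window-center timestamps of a sliding-window analysis
#'
#' A window of `window_seconds` slides along a record of `record_seconds` in
#' steps of `step_seconds`; each fully contained window is summarized at its
#' center. Centers therefore sit at `window_seconds/2 + k * step_seconds` for
#' `k = 0, 1, ...` while `window_seconds + k * step_seconds <= record_seconds`.
#' Partial windows are never emitted.
#'
#' @param record_seconds Record length in seconds.
#' @param window_seconds Window width in seconds; default 30.
#' @param step_seconds Step in seconds (> 0); default 5.
#' @return Numeric vector of window-center times; empty when the window does
#'   not fit in the record.
#' @examples
#' sliding_window_times(60, 30, 5)   # 15, 20, ..., 45
#' @export
sliding_window_times <- function(record_seconds, window_seconds = 30,
                                 step_seconds = 5) {
  if (step_seconds <= 0) stop("step_seconds must be > 0", call. = FALSE)
  if (window_seconds <= 0) stop("window_seconds must be > 0", call. = FALSE)
  if (window_seconds > record_seconds) return(numeric(0))
  k_max <- floor((record_seconds - window_seconds) / step_seconds + 1e-9)
  window_seconds / 2 + (0:k_max) * step_seconds
}

#' One-hot hypnodensity from a hypnogram
#'
#' Embeds a hypnogram into hypnodensity form: the record is tiled at
#' `step_seconds` resolution and each frame gets the one-hot probability
#' vector of the epoch covering its center (frame centers at
#' `step/2 + k*step`). This is the degenerate hypnodensity in which every
#' distribution is certain.
#'
#' Artifact epochs are dropped. With `gap = "concatenate"` (default) the
#' remaining frames are concatenated onto a fresh contiguous time base, with a
#' warning, so that lagged correlations see an unbroken index; with
#' `gap = "split"` a list of contiguous [hypnodensity()] segments is returned
#' instead.
#'
#' @param h A [hypnogram()].
#' @param step_seconds Output resolution in seconds; must divide
#'   `h$epoch_seconds`.
#' @param gap Artifact gap policy: `"concatenate"` or `"split"`.
#' @param channel Channel label for the output series.
#' @return A [hypnodensity()] (or a list of them when `gap = "split"` and
#'   artifacts split the record).
#' @examples
#' h <- hypnogram(c("Wake", "N2"))
#' hypnogram_to_hypnodensity(h, step_seconds = 30)$probs
#' @export
hypnogram_to_hypnodensity <- function(h, step_seconds = 5,
                                      gap = c("concatenate", "split"),
                                      channel = "hypnogram") {
  stopifnot(inherits(h, "hypnogram"))
  gap <- match.arg(gap)
  ratio <- h$epoch_seconds / step_seconds
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("step_seconds must divide epoch_seconds", call. = FALSE)
  ratio <- as.integer(round(ratio))
  frames_stage <- rep(h$stages, each = ratio)
  frames_epoch <- rep(seq_along(h$stages), each = ratio)
  keep <- !h$artifact[frames_epoch]

  as_series <- function(stage_idx, times) {
    p <- matrix(0, nrow = length(stage_idx), ncol = N_STAGES)
    p[cbind(seq_along(stage_idx), stage_idx)] <- 1
    hypnodensity(p, times = times, step_seconds = step_seconds,
                 window_seconds = step_seconds, channel = channel)
  }

  if (all(keep)) {
    times <- step_seconds / 2 + (seq_along(frames_stage) - 1) * step_seconds
    return(as_series(frames_stage, times))
  }
  if (gap == "concatenate") {
    warning("artifact epochs dropped; remaining frames concatenated onto a ",
            "contiguous time base", call. = FALSE)
    st <- frames_stage[keep]
    times <- step_seconds / 2 + (seq_along(st) - 1) * step_seconds
    return(as_series(st, times))
  }
  # split: one series per maximal run of kept frames, original time base
  runs <- rle(keep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segs <- which(runs$values)
  lapply(segs, function(j) {
    idx <- starts[j]:ends[j]
    as_series(frames_stage[idx],
              step_seconds / 2 + (idx - 1) * step_seconds)
  })
}

#' Collapse a hypnodensity series to a hypnogram
#'
#' Takes the per-frame argmax of the stage probabilities (ties broken in
#' favour of the lowest canonical stage index, i.e. Wake before N1 before N2
#' ...). The resulting hypnogram has one epoch per frame, of duration
#' `step_seconds`.
#'
#' @param series A valid [hypnodensity()].
#' @return A [hypnogram()] with `epoch_seconds = series$step_seconds`.
#' @examples
#' s <- hypnodensity(matrix(c(0.1, 0.1, 0.6, 0.1, 0.1), 1))
#' stage_labels()[hypnodensity_to_hypnogram(s)$stages]
#' @export
hypnodensity_to_hypnogram <- function(series) {
  stopifnot(inherits(series, "hypnodensity"))
  idx <- max.col(series$probs, ties.method = "first")
  hypnogram(idx, epoch_seconds = series$step_seconds)
}

#' Read / write hypnodensity series as CSV
#'
#' On-disk format: comma-separated columns `time_s,Wake,N1,N2,N3,REM`, UTF-8,
#' `.` decimal separator, `#` comment lines. Values round-trip at full double
#' precision. Reading validates the series and reports the (file) line number
#' of the first offending row.
#'
#' @param path File path.
#' @param series A [hypnodensity()] (write only).
#' @param step_seconds,window_seconds,channel Metadata attached on read;
#'   `step_seconds = NULL` (default) infers the step from the time column.
#' @return `read_hypnodensity_csv` returns a [hypnodensity()];
#'   `write_hypnodensity_csv` returns `path` invisibly.
#' @examples
#' s <- hypnodensity(diag(5))
#' f <- tempfile(fileext = ".csv")
#' write_hypnodensity_csv(s, f)
#' s2 <- read_hypnodensity_csv(f)
#' all.equal(s$probs, s2$probs)
#' @export
read_hypnodensity_csv <- function(path, step_seconds = NULL,
                                  window_seconds = 30, channel = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  data_lines <- lines[keep]
  lineno <- seq_along(lines)[keep]
  if (length(data_lines) < 2L)
    stop("hypnodensity file '", path, "' has no data rows", call. = FALSE)
  header <- strsplit(data_lines[[1L]], ",", fixed = TRUE)[[1L]]
  expected <- c("time_s", stage_labels())
  if (!identical(trimws(header), expected))
    stop("bad header at line ", lineno[1L], ": expected '",
         paste(expected, collapse = ","), "'", call. = FALSE)
  fields <- strsplit(data_lines[-1L], ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L))
    stop("wrong column count at line ", lineno[-1L][which(nf != 6L)[1L]],
         " (expected 6)", call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 6L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1L]
    stop("malformed numeric value at line ", lineno[-1L][bad], call. = FALSE)
  }
  times <- m[, 1L]
  if (any(diff(times) <= 0))
    stop("non-monotone time column at line ",
         lineno[-1L][which(diff(times) <= 0)[1L] + 1L], call. = FALSE)
  if (is.null(step_seconds))
    step_seconds <- if (length(times) > 1L) times[2L] - times[1L] else 5
  if (is.null(channel))
    channel <- sub("\\.csv$", "", basename(path))
  s <- hypnodensity(m[, -1L, drop = FALSE], times = times,
                    step_seconds = step_seconds,
                    window_seconds = window_seconds, channel = channel,
                    validate = FALSE)
  v <- validate_series(s)
  if (!v$ok) {
    # map "row i" in the message back to a file line number where possible
    i <- suppressWarnings(as.integer(sub("^row (\\d+).*", "\\1", v$message)))
    where <- if (!is.na(i)) paste0(" (line ", lineno[-1L][i], ")") else ""
    stop("validation error in '", path, "'", where, ": ", v$message,
         call. = FALSE)
  }
  s
}

#' @rdname read_hypnodensity_csv
#' @export
write_hypnodensity_csv <- function(series, path) {
  stopifnot(inherits(series, "hypnodensity"))
  rows <- apply(cbind(series$times, series$probs), 1L,
                function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(paste(c("time_s", stage_labels()), collapse = ","), rows), path)
  invisible(path)
}
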