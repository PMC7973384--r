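#' Vectorial auto- and cross-correlation of hypnodensity series
#'
#' The hypnodensity correlation generalizes the scalar lagged correlation to
#' 5-dimensional stage-probability vectors. With frames `x_t` (and `y_t`),
#' per-stage mean vectors `xbar` (and `ybar`) taken over all `T` frames, and
#' `.` the 5-dimensional dot product, the cross-correlation at lag `tau`
#' (in frames) is
#'
#' \deqn{r_{x,y}(\tau) = \frac{\frac{1}{T-\tau}\sum_{t=1}^{T-\tau}
#'   (x_t-\bar x)\cdot(y_{t+\tau}-\bar y)}
#'   {\sqrt{\frac{1}{T}\sum_t \lVert x_t-\bar x\rVert^2 \cdot
#'          \frac{1}{T}\sum_t \lVert y_t-\bar y\rVert^2}}}
#'
#' and the auto-correlation is the same with `y = x`, whose denominator is
#' `(1/T) sum ||x_t - xbar||^2`, so that `r(0) = 1` exactly.
#'
#' The normalization is deliberately asymmetric — `1/(T-tau)` in the
#' numerator against `1/T` in the denominators — and is kept verbatim, without
#' clamping, so `|r(tau)|` may slightly exceed 1 at large lags.
#'
#' Lags run over the non-negative multiples of the series step up to
#' `max_lag`; the reverse direction of the cross-correlation is obtained by
#' swapping arguments, or in one call with `symmetric = TRUE`, which returns
#' the curve on `[-max_lag, max_lag]` using `r_xy(-tau) = r_yx(tau)`.
#'
#' @param x,y [hypnodensity()] series; for cross-correlation both must share
#'   the same step, and are trimmed to their common (index) length.
#' @param max_lag Maximum lag in seconds; default half the record duration.
#' @param symmetric Cross-correlation only: also return negative lags.
#' @return Object of class `"corr_curve"`: list with `lags` (seconds),
#'   `values`, `kind` (`"auto"`/`"cross"`), `channel_x`, `channel_y`,
#'   `T` (frames used) and `step_seconds`.
#' @examples
#' s <- hypnodensity(diag(5)[rep(c(1, 3), 20), ])
#' ac <- autocorrelation(s, max_lag = 50)
#' ac$values[1]   # exactly 1 at lag 0
#' @export
autocorrelation <- function(x, max_lag = NULL) {
  curve_impl(x, x, max_lag, kind = "auto", symmetric = FALSE)
}

#' @rdname autocorrelation
#' @export
crosscorrelation <- function(x, y, max_lag = NULL, symmetric = FALSE) {
  curve_impl(x, y, max_lag, kind = "cross", symmetric = symmetric)
}

curve_impl <- function(x, y, max_lag, kind, symmetric) {
  stopifnot(inherits(x, "hypnodensity"), inherits(y, "hypnodensity"))
  vx <- validate_series(x)
  if (!vx$ok) stop("invalid series x: ", vx$message, call. = FALSE)
  auto <- kind == "auto"
  if (!auto) {
    vy <- validate_series(y)
    if (!vy$ok) stop("invalid series y: ", vy$message, call. = FALSE)
    if (abs(x$step_seconds - y$step_seconds) > 1e-9)
      stop("series have different step_seconds", call. = FALSE)
  }
  step <- x$step_seconds
  T_len <- min(nrow(x$probs), nrow(y$probs))
  if (T_len < 2L) stop("series too short for correlation", call. = FALSE)
  X <- x$probs[seq_len(T_len), , drop = FALSE]
  Y <- if (auto) X else y$probs[seq_len(T_len), , drop = FALSE]

  dur <- T_len * step
  if (is.null(max_lag)) max_lag <- dur / 2
  if (max_lag >= dur)
    stop("max_lag must be smaller than the series duration", call. = FALSE)
  n_lag <- floor(max_lag / step + 1e-9)

  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- if (auto) Xc else sweep(Y, 2L, colMeans(Y))
  var_x <- sum(Xc^2) / T_len
  var_y <- if (auto) var_x else sum(Yc^2) / T_len
  if (var_x <= 0 || var_y <= 0)
    stop("degenerate input: constant series has zero variance", call. = FALSE)
  denom <- if (auto) var_x else sqrt(var_x * var_y)

  corr_lags <- function(A, B) {
    # r(tau) for tau = 0..n_lag frames: numerator (1/(T-tau)) sum_t A_t . B_{t+tau}
    vapply(0:n_lag, function(tau) {
      n <- T_len - tau
      sum(A[seq_len(n), , drop = FALSE] *
            B[(tau + 1L):T_len, , drop = FALSE]) / n / denom
    }, numeric(1))
  }

  vals <- corr_lags(Xc, Yc)
  lags <- (0:n_lag) * step
  if (symmetric && !auto) {
    neg <- corr_lags(Yc, Xc)   # r_xy(-tau) = r_yx(tau)
    vals <- c(rev(neg[-1L]), vals)
    lags <- c(-rev(lags[-1L]), lags)
  }
  structure(list(lags = lags, values = vals, kind = kind,
                 channel_x = x$channel,
                 channel_y = if (auto) x$channel else y$channel,
                 T = T_len, step_seconds = step),
            class = "corr_curve")
}

#' @export
print.corr_curve <- function(x, ...) {
  cat(sprintf("%s-correlation curve %s%s: %d lags (0..%g min), T = %d\n",
              if (x$kind == "auto") "Auto" else "Cross",
              x$channel_x,
              if (x$kind == "cross") paste0(" x ", x$channel_y) else "",
              length(x$lags), max(x$lags) / 60, x$T))
  invisible(x)
}

#' Detect local maxima of a correlation curve and estimate the cycle period
#'
#' Repeating sleep cycles leave local side-maxima on the hypnodensity
#' auto-correlation at multiples of the cycle period; the lag of the first
#' admissible local maximum is the period estimate. The curve is smoothed
#' with a centered moving average of width `smooth_width`, interior local
#' maxima with prominence at least `min_prominence` and lag at least
#' `min_lag` are located on the smoothed curve, and each is then localized as
#' the argmax of the unsmoothed values within half a smoothing width of it —
#' detection is robust to frame-level noise while the reported lag lives on
#' the original, unsmoothed grid. `min_lag` must be positive so the trivial
#' global maximum at lag 0 is excluded.
#'
#' Prominence of a peak is its height above the higher of the two deepest
#' valleys separating it from a higher point (or the curve end) on each side.
#'
#' @param curve A `"corr_curve"` (typically from [autocorrelation()]).
#' @param min_lag Smallest admissible peak lag, seconds; default 30 min.
#' @param smooth_width Moving-average width, seconds; default 10 min.
#' @param min_prominence Minimum peak prominence; default 0.1. True
#'   cycle-period maxima on full-night autocorrelations show prominences of
#'   0.5 and above, while echo peaks caused by repeated stages inside one
#'   cycle (the template visits N2 twice) stay below 0.05; the default sits
#'   between the two regimes.
#' @return Object of class `"period_estimate"`: `period_seconds` (lag of the
#'   first maximum, `NA` if none), `maxima_lags`, `maxima_values` (r at those
#'   lags, unsmoothed), `status` (`"ok"` or `"no cycle detected"`), and
#'   `detector_params`.
#' @examples
#' s <- hypnodensity(diag(5)[rep(rep(c(2, 3, 4, 5), each = 90), 8), ])
#' pe <- detect_local_maxima(autocorrelation(s), min_lag = 600,
#'                           smooth_width = 60)
#' pe$period_seconds / 60   # minutes
#' @export
detect_local_maxima <- function(curve, min_lag = 1800, smooth_width = 600,
                                min_prominence = 0.1) {
  stopifnot(inherits(curve, "corr_curve"))
  if (min_lag <= 0) stop("min_lag must be > 0", call. = FALSE)
  pos <- curve$lags >= 0
  lags <- curve$lags[pos]
  vals <- curve$values[pos]
  step <- curve$step_seconds

  half <- max(0L, floor(smooth_width / step / 2))
  sm <- moving_average(vals, half)

  n <- length(sm)
  params <- list(smooth_width = smooth_width, min_lag = min_lag,
                 min_prominence = min_prominence)
  empty <- structure(list(period_seconds = NA_real_,
                          maxima_lags = numeric(0),
                          maxima_values = numeric(0),
                          status = "no cycle detected",
                          detector_params = params),
                     class = "period_estimate")
  if (n < 3L) return(empty)

  # interior local maxima on the smoothed curve (plateaus: take first index)
  cand <- which(diff(sign(diff(sm))) < 0) + 1L
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(i) peak_prominence(sm, i), numeric(1))
  keep <- lags[cand] >= min_lag & prom >= min_prominence
  cand <- cand[keep]
  if (!length(cand)) return(empty)

  # localize each detected peak on the unsmoothed curve: argmax of the raw
  # values within half a smoothing width of the smoothed maximum
  cand <- vapply(cand, function(i) {
    win <- max(1L, i - half):min(n, i + half)
    win[which.max(vals[win])]
  }, integer(1))
  cand <- sort(unique(cand))
  cand <- cand[lags[cand] >= min_lag]
  if (!length(cand)) return(empty)

  structure(list(period_seconds = lags[cand[1L]],
                 maxima_lags = lags[cand],
                 maxima_values = vals[cand],
                 status = "ok",
                 detector_params = params),
            class = "period_estimate")
}

moving_average <- function(v, half) {
  if (half == 0L) return(v)
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

peak_prominence <- function(v, i) {
  # height above the higher of the two key saddles flanking peak i
  n <- length(v)
  left_base <- {
    j <- i - 1L; m <- v[i]
    while (j >= 1L && v[j] <= v[i]) { m <- min(m, v[j]); j <- j - 1L }
    m
  }
  right_base <- {
    j <- i + 1L; m <- v[i]
    while (j <= n && v[j] <= v[i]) { m <- min(m, v[j]); j <- j + 1L }
    m
  }
  v[i] - max(left_base, right_base)
}

#' @export
print.period_estimate <- function(x, ...) {
  if (x$status != "ok") {
    cat("Period estimate: no cycle detected\n")
  } else {
    cat(sprintf("Estimated sleep-cycle period: %.1f min\n",
                x$period_seconds / 60))
    cat(sprintf("Local maxima at %s min (r = %s)\n",
                paste(sprintf("%.1f", x$maxima_lags / 60), collapse = ", "),
                paste(sprintf("%.3f", x$maxima_values), collapse = ", ")))
  }
  invisible(x)
}

#' All pairwise correlation curves for a set of channels
#'
#' Computes the full matrix of auto- (diagonal) and cross- (off-diagonal)
#' correlation curves for two or more channels recorded on a common time
#' base, e.g. the three EEG derivations of one night.
#'
#' @param channels List of [hypnodensity()] series (length >= 2) sharing
#'   `step_seconds`.
#' @param max_lag Maximum lag in seconds; default half the shortest record.
#' @return Object of class `"corr_matrix"`: an n x n list-matrix of
#'   `"corr_curve"` objects, dimnames = channel labels.
#' @examples
#' h <- simulate_hypnogram(cyclic_sleep_model(total_duration = 3 * 3600))
#' chs <- simulate_multichannel(h, channels = c("C4", "F4"), seed = 1)
#' m <- channel_correlation_summary(chs, max_lag = 1800)
#' m[["C4", "F4"]]
#' @export
channel_correlation_summary <- function(channels, max_lag = NULL) {
  if (!is.list(channels) || length(channels) < 2L)
    stop("need a list of at least 2 channels", call. = FALSE)
  labels <- vapply(channels, function(s) s$channel, character(1))
  n <- length(channels)
  if (is.null(max_lag)) {
    dur <- min(vapply(channels,
                      function(s) nrow(s$probs) * s$step_seconds, numeric(1)))
    max_lag <- dur / 2
  }
  out <- matrix(vector("list", n * n), n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[[i, j]] <- if (i == j) autocorrelation(channels[[i]], max_lag)
    else crosscorrelation(channels[[i]], channels[[j]], max_lag)
  }
  class(out) <- c("corr_matrix", class(out))
  out
}

#' Time-resolved period estimates over consecutive parts of a night
#'
#' Cuts the record into consecutive parts of `part_duration`, estimates the
#' cycle period within each part via [autocorrelation()] +
#' [detect_local_maxima()], and returns the sequence of estimates with part
#' midpoints — a simple probe for non-stationary period lengths across the
#' night.
#'
#' @param x A [hypnodensity()].
#' @param part_duration Part length in seconds. A warning is issued when it is
#'   shorter than `4 * expected_period` (too few cycles per part for a stable
#'   estimate).
#' @param max_lag Maximum lag per part, seconds; default half the part.
#' @param expected_period Expected cycle period used only for the length
#'   check; default 90 min.
#' @param ... Passed to [detect_local_maxima()].
#' @return Object of class `"period_track"`: data.frame with `part`,
#'   `midpoint_seconds`, `period_seconds`, `status`, plus the list of full
#'   `"period_estimate"` objects in attribute `"estimates"`.
#' @export
windowed_period_track <- function(x, part_duration, max_lag = NULL,
                                  expected_period = 5400, ...) {
  stopifnot(inherits(x, "hypnodensity"))
  dur <- nrow(x$probs) * x$step_seconds
  if (part_duration > dur)
    stop("part_duration exceeds the record length", call. = FALSE)
  if (part_duration < 4 * expected_period)
    warning("part_duration is below 4 expected periods; ",
            "estimates may be unstable", call. = FALSE)
  frames_per_part <- floor(part_duration / x$step_seconds)
  n_parts <- floor(nrow(x$probs) / frames_per_part)
  est <- vector("list", n_parts)
  mid <- numeric(n_parts)
  for (k in seq_len(n_parts)) {
    idx <- ((k - 1L) * frames_per_part + 1L):(k * frames_per_part)
    part <- hypnodensity(x$probs[idx, , drop = FALSE],
                         times = x$times[idx] - x$times[idx[1L]] +
                           x$step_seconds / 2,
                         step_seconds = x$step_seconds,
                         window_seconds = x$window_seconds,
                         channel = x$channel, validate = FALSE)
    ml <- if (is.null(max_lag)) part_duration / 2 else max_lag
    est[[k]] <- detect_local_maxima(autocorrelation(part, max_lag = ml), ...)
    mid[k] <- mean(x$times[idx])
  }
  out <- data.frame(part = seq_len(n_parts), midpoint_seconds = mid,
                    period_seconds = vapply(est, `[[`, numeric(1),
                                            "period_seconds"),
                    status = vapply(est, `[[`, character(1), "status"))
  attr(out, "estimates") <- est
  class(out) <- c("period_track", class(out))
  out
}
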