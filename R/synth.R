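#' Generative model of a cyclic night of sleep
#'
#' Parameter container for [simulate_hypnogram()]. A night is a train of
#' sleep cycles; within each cycle the stages follow a fixed template
#' (default N1 -> N2 -> N3 -> N2 -> REM) with given dwell-time fractions.
#' Dwell durations are jittered multiplicatively and then rescaled within
#' each cycle so every cycle's total length equals `cycle_period` exactly:
#' jitter redistributes time among stages inside a cycle while cycle onsets
#' stay strictly periodic, which is the regime in which autocorrelation-based
#' period estimation is well posed. Brief awakenings are inserted at
#' `wake_insertion_rate` per hour, each one epoch long.
#'
#' @param cycle_period Cycle length in seconds; default 90 min. Healthy adult
#'   cycles run roughly 75-110 min.
#' @param total_duration Night length in seconds; default 8 h.
#' @param stage_template Stage sequence within a cycle (labels or indices).
#' @param dwell_fractions Positive fractions summing to 1, one per template
#'   entry; default `c(0.1, 0.4, 0.25, 0.1, 0.15)`.
#' @param wake_insertion_rate Brief awakenings per hour; default 2.
#' @param dwell_jitter Standard deviation of the multiplicative (lognormal)
#'   dwell noise; default 0.05, i.e. stage-boundary jitter of a few epochs
#'   per cycle — enough to decorrelate the within-cycle fine structure while
#'   keeping the night's correlation peak on the lag-grid step that carries
#'   the true period, the regime in which 5-s-resolution period readout is
#'   meaningful. 0 gives an exactly periodic template.
#' @param epoch_seconds Scoring epoch; default 30 s.
#' @return Object of class `"cyclic_sleep_model"`.
#' @examples
#' m <- cyclic_sleep_model(cycle_period = 75 * 60)
#' h <- simulate_hypnogram(m, seed = 1)
#' @export
cyclic_sleep_model <- function(cycle_period = 90 * 60,
                               total_duration = 8 * 3600,
                               stage_template = c("N1", "N2", "N3", "N2",
                                                  "REM"),
                               dwell_fractions = c(0.10, 0.40, 0.25, 0.10,
                                                   0.15),
                               wake_insertion_rate = 2,
                               dwell_jitter = 0.05,
                               epoch_seconds = 30) {
  if (cycle_period <= 0) stop("cycle_period must be > 0", call. = FALSE)
  if (length(dwell_fractions) != length(stage_template))
    stop("one dwell fraction per template stage", call. = FALSE)
  if (any(dwell_fractions <= 0))
    stop("dwell fractions must be positive", call. = FALSE)
  if (abs(sum(dwell_fractions) - 1) > 1e-9)
    stop("dwell fractions must sum to 1", call. = FALSE)
  if (dwell_jitter < 0) stop("dwell_jitter must be >= 0", call. = FALSE)
  if (wake_insertion_rate < 0)
    stop("wake_insertion_rate must be >= 0", call. = FALSE)
  structure(list(cycle_period = cycle_period,
                 total_duration = total_duration,
                 stage_template = stage_index(stage_template),
                 dwell_fractions = dwell_fractions,
                 wake_insertion_rate = wake_insertion_rate,
                 dwell_jitter = dwell_jitter,
                 epoch_seconds = epoch_seconds),
            class = "cyclic_sleep_model")
}

#' Simulate a cyclic hypnogram
#'
#' Realizes a [cyclic_sleep_model()] as a 30-s-epoch stage sequence.
#' Deterministic for a fixed seed.
#'
#' @param model A [cyclic_sleep_model()].
#' @param seed Integer seed.
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(model, seed = 0L) {
  stopifnot(inherits(model, "cyclic_sleep_model"))
  if (model$total_duration < model$cycle_period)
    stop("total_duration must cover at least one cycle", call. = FALSE)
  local_rng(seed, {
    ep <- model$epoch_seconds
    epochs_per_cycle <- round(model$cycle_period / ep)
    n_epochs <- floor(model$total_duration / ep)
    n_cycles <- ceiling(n_epochs / epochs_per_cycle)
    stages <- integer(0)
    for (cy in seq_len(n_cycles)) {
      f <- model$dwell_fractions
      if (model$dwell_jitter > 0) {
        sdlog <- sqrt(log(1 + model$dwell_jitter^2))
        f <- f * stats::rlnorm(length(f), -sdlog^2 / 2, sdlog)
      }
      f <- f / sum(f)          # rescale: cycle length is exactly the period
      bounds <- round(cumsum(f) * epochs_per_cycle)
      counts <- diff(c(0L, bounds))
      stages <- c(stages, rep(model$stage_template, times = counts))
    }
    stages <- stages[seq_len(n_epochs)]
    n_wake <- stats::rpois(1L, model$wake_insertion_rate *
                             model$total_duration / 3600)
    if (n_wake > 0) {
      pos <- sample.int(n_epochs, min(n_wake, n_epochs))
      stages[pos] <- 1L        # Wake
    }
    hypnogram(stages, epoch_seconds = ep)
  })
}

#' Softmax-like probability noise model
#'
#' Parameters of the observation noise that turns a true stage sequence into
#' classifier-like stage probabilities. Per frame, the one-hot vector of the
#' true stage is blended through a 5 x 5 stage-confusion kernel (placing mass
#' on physiologically adjacent stages, e.g. N2 <-> N3 and N1 <-> REM),
#' multiplied by per-channel stage bias weights and renormalized, giving the
#' target mean vector; the emitted row is a Dirichlet draw with that mean and
#' sharpness `concentration`. Rows therefore live exactly on the probability
#' simplex, as softmax output does.
#'
#' @param concentration Dirichlet sharpness (> 0); larger means probability
#'   mass concentrates on the true stage. Default 30 keeps per-frame argmax
#'   fidelity >= 0.9 with the default kernel.
#' @param confusion_kernel 5 x 5 non-negative matrix, rows = true stage;
#'   rows are renormalized internally. Default is diagonally dominant with
#'   adjacent-stage mass.
#' @param channel_bias Named list mapping channel labels to positive
#'   stage-weight 5-vectors (multiplicative); unlisted channels are unbiased.
#' @return Object of class `"hd_noise_model"`.
#' @export
noise_model <- function(concentration = 30,
                        confusion_kernel = default_confusion_kernel(),
                        channel_bias = list()) {
  if (concentration <= 0) stop("concentration must be > 0", call. = FALSE)
  K <- as.matrix(confusion_kernel)
  if (!all(dim(K) == c(N_STAGES, N_STAGES)))
    stop("confusion_kernel must be 5 x 5", call. = FALSE)
  if (any(K < 0)) stop("confusion_kernel must be non-negative", call. = FALSE)
  if (any(rowSums(K) <= 0))
    stop("confusion_kernel has an all-zero row", call. = FALSE)
  K <- K / rowSums(K)
  if (!is.list(channel_bias))
    stop("channel_bias must be a named list", call. = FALSE)
  for (b in channel_bias)
    if (length(b) != N_STAGES || any(b <= 0))
      stop("each channel bias must be 5 positive weights", call. = FALSE)
  structure(list(concentration = concentration, confusion_kernel = K,
                 channel_bias = channel_bias),
            class = "hd_noise_model")
}

#' @rdname noise_model
#' @export
default_confusion_kernel <- function() {
  K <- matrix(c(
    0.88, 0.07, 0.02, 0.01, 0.02,   # Wake
    0.06, 0.81, 0.06, 0.01, 0.06,   # N1
    0.01, 0.05, 0.86, 0.06, 0.02,   # N2
    0.005, 0.005, 0.08, 0.90, 0.01, # N3
    0.02, 0.06, 0.02, 0.01, 0.89    # REM
  ), nrow = N_STAGES, byrow = TRUE,
  dimnames = list(stage_labels(), stage_labels()))
  K
}

# one Dirichlet draw per row of `alpha` (n x 5), via independent gammas
rdirichlet_rows <- function(alpha) {
  g <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow = nrow(alpha))
  # guard against all-zero rows from tiny shapes underflowing to 0
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, ] <- alpha[zero, , drop = FALSE]
  g / rowSums(g)
}

#' Simulate a noisy hypnodensity series from a hypnogram
#'
#' Tiles the (artifact-free) hypnogram at `step_seconds` resolution and emits
#' for each frame a softmax-like probability vector around the true stage,
#' per the given [noise_model()]. Deterministic for a fixed seed.
#'
#' @param h A [hypnogram()].
#' @param noise A [noise_model()].
#' @param step_seconds Frame step in seconds; default 5.
#' @param channel Channel label; its bias (if present in
#'   `noise$channel_bias`) is applied.
#' @param seed Integer seed.
#' @return A valid [hypnodensity()] with `window_seconds = 30`.
#' @export
simulate_noisy_hypnodensity <- function(h, noise = noise_model(),
                                        step_seconds = 5, channel = "EEG",
                                        seed = 0L) {
  stopifnot(inherits(h, "hypnogram"), inherits(noise, "hd_noise_model"))
  ratio <- h$epoch_seconds / step_seconds
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("step_seconds must divide epoch_seconds", call. = FALSE)
  stages <- rep(h$stages[!h$artifact], each = as.integer(round(ratio)))
  bias <- noise$channel_bias[[channel]]
  if (is.null(bias)) bias <- rep(1, N_STAGES)
  targets <- noise$confusion_kernel * rep(bias, each = N_STAGES)
  targets <- targets / rowSums(targets)
  m <- targets[stages, , drop = FALSE]
  probs <- local_rng(seed, rdirichlet_rows(noise$concentration * m))
  hypnodensity(probs,
               times = step_seconds / 2 +
                 (seq_along(stages) - 1) * step_seconds,
               step_seconds = step_seconds, window_seconds = 30,
               channel = channel)
}

#' Simulate multiple channels sharing one hypnogram
#'
#' All channels are driven by the same underlying stage sequence but draw
#' independent probability noise and apply their own stage biases — so any
#' pair of channels cross-correlates maximally at lag zero while still
#' differing frame by frame.
#'
#' @param h A [hypnogram()].
#' @param noise A [noise_model()]. Every name in `noise$channel_bias` must
#'   appear in `channels`.
#' @param channels Character vector of channel labels; default
#'   `c("C4", "F4", "O2")`.
#' @param step_seconds Frame step; default 5.
#' @param seed Integer seed; channel k uses `seed + k - 1`.
#' @return List of [hypnodensity()] series, one per channel.
#' @export
simulate_multichannel <- function(h, noise = noise_model(),
                                  channels = c("C4", "F4", "O2"),
                                  step_seconds = 5, seed = 0L) {
  if (length(channels) < 1L) stop("need at least one channel", call. = FALSE)
  unknown <- setdiff(names(noise$channel_bias), channels)
  if (length(unknown))
    stop("channel_bias refers to unknown channel(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  out <- lapply(seq_along(channels), function(k) {
    simulate_noisy_hypnodensity(h, noise, step_seconds = step_seconds,
                                channel = channels[k],
                                seed = as.integer(seed) + k - 1L)
  })
  names(out) <- channels
  out
}

#' Simulate labeled Gaussian cluster embeddings
#'
#' Draws `n_classes` isotropic unit-variance Gaussian clusters in `dim`
#' dimensions whose centroids sit at pairwise Euclidean distance
#' `separation` (scaled standard-simplex vertices), giving a controllable
#' separability test bed for [gdv()]: separation 0 means all classes share
#' one distribution.
#'
#' @param n_classes Number of classes (>= 2, and <= dim for exact pairwise
#'   centroid distances).
#' @param n_per_class Points per class.
#' @param dim Dimensionality.
#' @param separation Pairwise centroid distance (>= 0).
#' @param seed Integer seed.
#' @return A [labeled_embedding()] with integer class labels.
#' @export
simulate_embeddings <- function(n_classes = 2, n_per_class = 100, dim = 10,
                                separation = 0, seed = 0L) {
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  if (n_classes > dim)
    stop("need n_classes <= dim for equidistant centroids", call. = FALSE)
  if (separation < 0) stop("separation must be >= 0", call. = FALSE)
  # unit vectors e_i are sqrt(2) apart; scale to the requested separation
  centroids <- diag(dim)[seq_len(n_classes), , drop = FALSE] *
    separation / sqrt(2)
  local_rng(seed, {
    pts <- do.call(rbind, lapply(seq_len(n_classes), function(k) {
      matrix(stats::rnorm(n_per_class * dim), n_per_class, dim) +
        rep(centroids[k, ], each = n_per_class)
    }))
    labeled_embedding(pts, rep(seq_len(n_classes), each = n_per_class))
  })
}

# per-stage oscillation signatures: frequency (Hz), amplitude, burst?
stage_eeg_signatures <- function() {
  list(Wake = list(freq = 10,  amp = 1.6, burst = FALSE),  # alpha
       N1   = list(freq = 6.5, amp = 0.8, burst = FALSE),  # theta
       N2   = list(freq = 13,  amp = 1.2, burst = TRUE),   # spindle bursts
       N3   = list(freq = 1.5, amp = 2.5, burst = FALSE),  # slow oscillation
       REM  = list(freq = 5,   amp = 0.7, burst = FALSE))  # low theta
}

#' Simulate single-channel EEG with stage-specific spectral signatures
#'
#' A toy EEG generator: per 30-s epoch, broadband noise plus a
#' stage-specific oscillation following textbook sleep physiology — alpha
#' (10 Hz) in Wake, theta in N1/REM, spindle-band (13 Hz) bursts in N2 and
#' high-amplitude slow oscillations (< 4 Hz) in N3. Each epoch is normalized
#' to unit standard deviation. Deterministic per seed. Intended as classifier
#' training input, not as physiologically realistic EEG.
#'
#' @param h A [hypnogram()].
#' @param sample_rate Samples per second (>= 64); default 64.
#' @param noise_sd Broadband noise level; default 0.6.
#' @param seed Integer seed.
#' @return Numeric vector of length `n_epochs * epoch_seconds * sample_rate`,
#'   with attribute `"sample_rate"`.
#' @export
simulate_stage_eeg <- function(h, sample_rate = 64, noise_sd = 0.6,
                               seed = 0L) {
  stopifnot(inherits(h, "hypnogram"))
  if (sample_rate < 64) stop("sample_rate must be >= 64", call. = FALSE)
  sig <- stage_eeg_signatures()
  n_ep <- length(h$stages)
  spe <- as.integer(round(h$epoch_seconds * sample_rate))
  tt <- (seq_len(spe) - 1) / sample_rate
  local_rng(seed, {
    out <- numeric(n_ep * spe)
    for (i in seq_len(n_ep)) {
      s <- sig[[h$stages[i]]]
      phase <- stats::runif(1, 0, 2 * pi)
      osc <- s$amp * sin(2 * pi * s$freq * tt + phase)
      if (s$burst) {
        # slow on/off envelope emulating spindle trains
        env <- (1 + sin(2 * pi * 0.25 * tt + stats::runif(1, 0, 2 * pi))) / 2
        osc <- osc * env
      }
      x <- osc + stats::rnorm(spe, sd = noise_sd)
      out[((i - 1L) * spe + 1L):(i * spe)] <- x / stats::sd(x)
    }
    attr(out, "sample_rate") <- sample_rate
    out
  })
}
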