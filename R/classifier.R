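#' Network architecture specification
#'
#' Describes the sleep-stage classifier architecture: a stack of 1-D
#' convolutional layers with interleaved max-pooling, recurrent (bidirectional
#' LSTM) layers, and a fully connected softmax classification head over the
#' 5 stages. At full scale (`scale_factor = 1`) the census is 11 convolutional
#' layers, 9 max-pooling layers and 2 bidirectional LSTM layers; a
#' `scale_factor < 1` shrinks the depth proportionally (floors of 2/2/1) for
#' desk-scale experiments where the claims are structural, not performance.
#'
#' @param scale_factor Depth scaling in (0, 1]; default 1.
#' @param n_filters Filters per convolutional layer at reduced scale;
#'   default 4.
#' @param kernel_size Convolution kernel width in samples; default 9.
#' @param lstm_units Hidden units per LSTM direction; default 8.
#' @param pool_size Max-pooling factor; default 4.
#' @return Object of class `"network_spec"` with fields `n_conv_layers`,
#'   `n_pool_layers`, `n_lstm_layers`, `n_classes` (always 5) and the width
#'   parameters.
#' @examples
#' network_spec()$n_conv_layers             # 11 at full scale
#' network_spec(scale_factor = 0.2)$n_conv_layers
#' @export
network_spec <- function(scale_factor = 1, n_filters = 4, kernel_size = 9,
                         lstm_units = 8, pool_size = 4) {
  if (scale_factor <= 0 || scale_factor > 1)
    stop("scale_factor must be in (0, 1]", call. = FALSE)
  spec <- structure(list(
    n_conv_layers = max(2L, as.integer(round(11 * scale_factor))),
    n_pool_layers = max(2L, as.integer(round(9 * scale_factor))),
    n_lstm_layers = max(1L, as.integer(round(2 * scale_factor))),
    n_classes = 5L,
    scale_factor = scale_factor,
    n_filters = as.integer(n_filters),
    kernel_size = as.integer(kernel_size),
    lstm_units = as.integer(lstm_units),
    pool_size = as.integer(pool_size)), class = "network_spec")
  if (spec$n_pool_layers > spec$n_conv_layers)
    spec$n_pool_layers <- spec$n_conv_layers
  spec
}

#' Build the sequence classifier
#'
#' Instantiates a [network_spec()] as a runnable model mapping a 30-s
#' single-channel window to a 5-stage probability vector. The convolutional
#' and recurrent feature extractor uses fixed random (seeded) weights —
#' random 1-D convolution kernels act as a bank of band-mixing filters and a
#' bidirectional LSTM with random weights summarizes the pooled feature
#' sequence — and only the softmax classification head is fitted, by
#' multinomial logistic regression ([train_network()]). This
#' random-feature realization keeps the architecture (conv / pool / biLSTM /
#' softmax) while staying trainable in seconds on a single CPU.
#'
#' Pooling shortens the sequence by `pool_size` per pooling layer; the number
#' of pooling layers actually applied is capped so at least 4 time steps
#' reach the recurrent stage.
#'
#' @param spec A [network_spec()].
#' @param input_samples Window length in samples; default 1920 (30 s at
#'   64 Hz).
#' @param seed Seed for the random feature weights.
#' @return Object of class `"hypnonet"`: layer weights, an (untrained)
#'   random-initialized softmax head, and the spec. `layer_census()` reports
#'   the architecture counts.
#' @export
build_network <- function(spec = network_spec(scale_factor = 0.2),
                          input_samples = 1920, seed = 0L) {
  stopifnot(inherits(spec, "network_spec"))
  if (!requireNamespace("nnet", quietly = TRUE))
    stop("the classifier head needs the 'nnet' package", call. = FALSE)
  local_rng(seed, {
    layers <- list()
    len <- input_samples
    in_ch <- 1L
    pools_left <- spec$n_pool_layers
    for (i in seq_len(spec$n_conv_layers)) {
      W <- array(stats::rnorm(spec$kernel_size * in_ch * spec$n_filters,
                              sd = 1 / sqrt(spec$kernel_size * in_ch)),
                 dim = c(spec$kernel_size, in_ch, spec$n_filters))
      layers[[length(layers) + 1L]] <- list(type = "conv", W = W)
      len <- len - spec$kernel_size + 1L
      in_ch <- spec$n_filters
      if (pools_left > 0L && floor(len / spec$pool_size) >= 4L) {
        layers[[length(layers) + 1L]] <- list(type = "pool",
                                              size = spec$pool_size)
        len <- floor(len / spec$pool_size)
        pools_left <- pools_left - 1L
      }
    }
    lstm <- lapply(seq_len(spec$n_lstm_layers), function(i) {
      nin <- if (i == 1L) spec$n_filters else 2L * spec$lstm_units
      list(fwd = random_lstm_weights(nin, spec$lstm_units),
           bwd = random_lstm_weights(nin, spec$lstm_units))
    })
    n_feat <- 2L * spec$lstm_units + 2L * spec$n_filters  # lstm + pooled stats
    head <- list(W = matrix(stats::rnorm(5L * n_feat, sd = 0.1), 5L, n_feat),
                 b = stats::rnorm(5L, sd = 0.1))
    structure(list(spec = spec, layers = layers, lstm = lstm, head = head,
                   readout = NULL, input_samples = as.integer(input_samples),
                   n_features = n_feat, seed = as.integer(seed)),
              class = "hypnonet")
  })
}

random_lstm_weights <- function(n_in, n_units) {
  s <- 1 / sqrt(n_in + n_units)
  list(Wx = matrix(stats::rnorm(4L * n_units * n_in, sd = s),
                   4L * n_units, n_in),
       Wh = matrix(stats::rnorm(4L * n_units * n_units, sd = s),
                   4L * n_units, n_units),
       b = rep(0, 4L * n_units), n_units = n_units)
}

#' @export
print.hypnonet <- function(x, ...) {
  cen <- layer_census(x)
  cat(sprintf(
    "Sleep-stage network: %d conv, %d pool, %d biLSTM, 1 softmax (%s head)\n",
    cen["conv"], cen["pool"], cen["lstm"],
    if (is.null(x$readout)) "untrained" else "trained"))
  invisible(x)
}

#' Architecture census of a built network
#'
#' @param net A `"hypnonet"`.
#' @return Named integer vector: counts of `conv`, `pool`, `lstm`
#'   (bidirectional recurrent layers) and `softmax` layers as specified.
#' @export
layer_census <- function(net) {
  stopifnot(inherits(net, "hypnonet"))
  c(conv = net$spec$n_conv_layers, pool = net$spec$n_pool_layers,
    lstm = net$spec$n_lstm_layers, softmax = 1L)
}

# ---- forward pass -----------------------------------------------------------

conv1d_valid <- function(X, W) {
  # X: T x C_in, W: K x C_in x C_out -> (T-K+1) x C_out, ReLU
  K <- dim(W)[1L]; C_out <- dim(W)[3L]
  T_out <- nrow(X) - K + 1L
  out <- matrix(0, T_out, C_out)
  for (co in seq_len(C_out)) {
    acc <- numeric(T_out)
    for (ci in seq_len(ncol(X))) {
      w <- W[, ci, co]
      # valid 1-D convolution (correlation orientation)
      acc <- acc + as.numeric(stats::filter(X[, ci], rev(w),
                                            sides = 1))[K:nrow(X)]
    }
    out[, co] <- acc
  }
  out[out < 0] <- 0
  out
}

maxpool1d <- function(X, size) {
  T_out <- floor(nrow(X) / size)
  idx <- rep(seq_len(T_out), each = size)
  apply(X[seq_len(T_out * size), , drop = FALSE], 2L,
        function(col) tapply(col, idx, max))
}

lstm_forward <- function(X, w) {
  # X: T x n_in; returns T x n_units hidden sequence
  n <- w$n_units
  T_len <- nrow(X)
  H <- matrix(0, T_len, n)
  h <- numeric(n); cst <- numeric(n)
  pre_x <- X %*% t(w$Wx)    # T x 4n, precompute input part
  for (t in seq_len(T_len)) {
    z <- pre_x[t, ] + as.numeric(w$Wh %*% h) + w$b
    i <- stats::plogis(z[1:n]); f <- stats::plogis(z[(n + 1):(2 * n)])
    o <- stats::plogis(z[(2 * n + 1):(3 * n)])
    g <- tanh(z[(3 * n + 1):(4 * n)])
    cst <- f * cst + i * g
    h <- o * tanh(cst)
    H[t, ] <- h
  }
  H
}

bilstm_forward <- function(X, layer) {
  Hf <- lstm_forward(X, layer$fwd)
  Hb <- lstm_forward(X[rev(seq_len(nrow(X))), , drop = FALSE], layer$bwd)
  cbind(Hf, Hb[rev(seq_len(nrow(Hb))), , drop = FALSE])
}

# full feature extractor for one window; also returns per-layer taps
forward_features <- function(net, window, taps = FALSE) {
  X <- matrix(window, ncol = 1L)
  tap_list <- if (taps) list(input = as.numeric(window)) else NULL
  pool_i <- 0L
  for (ly in net$layers) {
    if (ly$type == "conv") {
      X <- conv1d_valid(X, ly$W)
    } else {
      X <- maxpool1d(X, ly$size)
      if (taps) {
        pool_i <- pool_i + 1L
        tap_list[[paste0("pool", pool_i)]] <- as.numeric(X)
      }
    }
  }
  pooled_stats <- c(colMeans(X), apply(X, 2L, stats::sd))
  H <- X
  for (ly in net$lstm) H <- bilstm_forward(H, ly)
  lstm_state <- H[nrow(H), ]
  if (taps) tap_list[["lstm"]] <- as.numeric(lstm_state)
  feat <- c(lstm_state, pooled_stats)
  list(features = feat, taps = tap_list)
}

features_matrix <- function(net, windows) {
  t(vapply(seq_len(nrow(windows)),
           function(i) forward_features(net, windows[i, ])$features,
           numeric(net$n_features)))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# class probabilities for a feature matrix, trained or untrained head
head_probs <- function(net, F_mat) {
  if (is.null(net$readout)) {
    softmax_rows(F_mat %*% t(net$head$W) +
                   rep(net$head$b, each = nrow(F_mat)))
  } else {
    p <- stats::predict(net$readout, data.frame(F_mat), type = "raw")
    p / rowSums(p)   # renormalize away predict()'s rounding
  }
}

#' Train the classification head
#'
#' Runs every training window through the fixed feature extractor and fits
#' the softmax classification layer by multinomial logistic regression
#' (`nnet` with zero hidden units, skip-layer connections and softmax
#' output).
#'
#' @param net A `"hypnonet"` from [build_network()].
#' @param windows Numeric matrix, one 30-s window per row
#'   (`net$input_samples` columns).
#' @param labels Stage per window (canonical indices or labels).
#' @param maxit Optimizer iteration cap; default 200.
#' @return The network with a fitted `readout`.
#' @export
train_network <- function(net, windows, labels, maxit = 200) {
  stopifnot(inherits(net, "hypnonet"))
  y <- factor(stage_labels()[stage_index(labels)], levels = stage_labels())
  F_mat <- features_matrix(net, windows)
  df <- data.frame(F_mat)
  fit <- nnet::nnet(df, nnet::class.ind(y), size = 0, skip = TRUE,
                    softmax = TRUE, maxit = maxit, trace = FALSE,
                    MaxNWts = 10000)
  net$readout <- fit
  net
}

#' Classify windows into stage probabilities
#'
#' @param net A `"hypnonet"` (trained or untrained; untrained uses the
#'   random-initialized head and still returns valid simplex rows).
#' @param windows Numeric matrix, one window per row.
#' @return N x 5 matrix of stage probabilities, rows summing to 1.
#' @export
classify_windows <- function(net, windows) {
  p <- head_probs(net, features_matrix(net, windows))
  colnames(p) <- stage_labels()
  p
}

#' Assemble training and test corpora from labeled recordings
#'
#' Multi-channel recordings are concatenated channel-wise into a single
#' channel of three times (for 3 channels) the duration, with the stage
#' labels repeated per channel — so one scorer's labels supervise every
#' derivation. Recordings are then split at the dataset level (80/20 by
#' default, via [train_test_split_datasets()]) and cut into non-overlapping
#' 30-s windows, `floor(duration / 30 s)` per recording.
#'
#' @param datasets List of recordings; each a list with `signal` (numeric
#'   vector, or list/matrix of per-channel vectors), `hypnogram` (a
#'   [hypnogram()]) and optional `sample_rate` (default 64).
#' @param train_fraction Fraction of datasets used for training; default 0.8.
#' @param seed Split seed.
#' @return List with `train` and `test`, each holding `windows` (matrix) and
#'   `labels` (canonical stage indices), plus the index split.
#' @export
prepare_training_data <- function(datasets, train_fraction = 0.8, seed = 0L) {
  if (!length(datasets)) stop("no datasets", call. = FALSE)
  split <- train_test_split_datasets(length(datasets), train_fraction, seed)
  cut_one <- function(d) {
    rate <- if (is.null(d$sample_rate)) 64 else d$sample_rate
    sigs <- d$signal
    if (is.matrix(sigs)) sigs <- lapply(seq_len(ncol(sigs)),
                                        function(j) sigs[, j])
    if (!is.list(sigs)) sigs <- list(sigs)
    h <- d$hypnogram
    spe <- as.integer(round(h$epoch_seconds * rate))
    n_ep <- length(h$stages)
    for (s in sigs)
      if (length(s) < n_ep * spe)
        stop("signal shorter than its hypnogram", call. = FALSE)
    # channel concatenation: one long single-channel stream, labels repeated
    sig <- unlist(lapply(sigs, function(s) s[seq_len(n_ep * spe)]))
    lab <- rep(h$stages, times = length(sigs))
    wps <- as.integer(round(30 * rate))
    n_win <- floor(length(sig) / wps)
    W <- matrix(sig[seq_len(n_win * wps)], nrow = n_win, byrow = TRUE)
    # label of the epoch containing each window start (30-s epochs: 1:1)
    wl <- lab[pmin(length(lab), floor((seq_len(n_win) - 1) * wps / spe) + 1L)]
    list(windows = W, labels = wl)
  }
  bind <- function(idx) {
    parts <- lapply(datasets[idx], cut_one)
    list(windows = do.call(rbind, lapply(parts, `[[`, "windows")),
         labels = unlist(lapply(parts, `[[`, "labels")))
  }
  list(train = bind(split$train), test = bind(split$test), split = split)
}

#' Hypnodensity prediction from a raw signal
#'
#' Slides a 30-s window along the signal in `step_seconds` steps, classifies
#' each window and assigns the probability vector to the window center,
#' yielding a valid [hypnodensity()] — the higher-temporal-resolution view of
#' the night that the correlation analysis consumes.
#'
#' @param net A `"hypnonet"`.
#' @param signal Numeric vector, at least 30 s long.
#' @param sample_rate Samples per second; default the `"sample_rate"`
#'   attribute of `signal`, else 64.
#' @param step_seconds Window step; default 5.
#' @param channel Channel label for the output series.
#' @return A [hypnodensity()] with `window_seconds = 30`.
#' @export
predict_hypnodensity <- function(net, signal, sample_rate = NULL,
                                 step_seconds = 5, channel = "pred") {
  stopifnot(inherits(net, "hypnonet"))
  if (is.null(sample_rate)) {
    sample_rate <- attr(signal, "sample_rate")
    if (is.null(sample_rate)) sample_rate <- 64
  }
  record_s <- length(signal) / sample_rate
  centers <- sliding_window_times(record_s, 30, step_seconds)
  if (!length(centers))
    stop("signal shorter than one 30-s window", call. = FALSE)
  wps <- as.integer(round(30 * sample_rate))
  starts <- as.integer(round((centers - 15) * sample_rate)) + 1L
  W <- t(vapply(starts, function(s0) signal[s0:(s0 + wps - 1L)],
                numeric(wps)))
  probs <- classify_windows(net, W)
  hypnodensity(probs, times = centers, step_seconds = step_seconds,
               window_seconds = 30, channel = channel)
}

#' Layer-wise embeddings of labeled windows
#'
#' Runs each window through the network and collects, per tapped layer, the
#' flattened activations as a [labeled_embedding()]: the raw input, the
#' output of every max-pooling layer, the final recurrent state, and the
#' softmax output. Feeding the resulting list to [gdv_profile()] yields the
#' separability-vs-depth profile.
#'
#' @param net A `"hypnonet"`.
#' @param windows Numeric matrix, one window per row.
#' @param labels Stage per window.
#' @return Ordered list of [labeled_embedding()]s (input, pool1..K, lstm,
#'   softmax).
#' @export
tap_layer_embeddings <- function(net, windows, labels) {
  stopifnot(inherits(net, "hypnonet"))
  y <- stage_index(labels)
  if (length(y) != nrow(windows))
    stop("one label per window required", call. = FALSE)
  res <- lapply(seq_len(nrow(windows)),
                function(i) forward_features(net, windows[i, ], taps = TRUE))
  tap_names <- names(res[[1L]]$taps)
  feats <- do.call(rbind, lapply(res, `[[`, "features"))
  out <- lapply(tap_names, function(nm) {
    labeled_embedding(do.call(rbind, lapply(res, function(r) r$taps[[nm]])),
                      stage_labels()[y], layer_name = nm)
  })
  probs <- head_probs(net, feats)
  out[[length(out) + 1L]] <- labeled_embedding(probs, stage_labels()[y],
                                               layer_name = "softmax")
  out
}
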