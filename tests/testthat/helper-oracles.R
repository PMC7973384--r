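# Independent brute-force oracles: direct double-loop transcriptions of the
# defining sums, kept free of any package internals so they can pin the
# vectorized implementations.

# random hypnodensity series: Dirichlet-ish simplex rows
random_series <- function(T_len, seed, step = 5, channel = "X") {
  set.seed(seed)
  p <- matrix(rexp(T_len * 5), T_len, 5)
  p <- p / rowSums(p)
  hypnodensity(p, step_seconds = step, channel = channel)
}

# Vectorial cross-correlation, naive loops: numerator (1/(T-tau)) sum of dot
# products of deviations, denominator sqrt of the two (1/T) mean squared norms.
oracle_crosscorr <- function(X, Y, n_lag) {
  T_len <- nrow(X)
  xb <- colMeans(X); yb <- colMeans(Y)
  vx <- 0; vy <- 0
  for (t in 1:T_len) {
    vx <- vx + sum((X[t, ] - xb)^2)
    vy <- vy + sum((Y[t, ] - yb)^2)
  }
  vx <- vx / T_len; vy <- vy / T_len
  r <- numeric(n_lag + 1)
  for (tau in 0:n_lag) {
    num <- 0
    for (t in 1:(T_len - tau))
      num <- num + sum((X[t, ] - xb) * (Y[t + tau, ] - yb))
    r[tau + 1] <- (num / (T_len - tau)) / sqrt(vx * vy)
  }
  r
}

oracle_autocorr <- function(X, n_lag) {
  T_len <- nrow(X)
  xb <- colMeans(X)
  v <- 0
  for (t in 1:T_len) v <- v + sum((X[t, ] - xb)^2)
  v <- v / T_len
  r <- numeric(n_lag + 1)
  for (tau in 0:n_lag) {
    num <- 0
    for (t in 1:(T_len - tau))
      num <- num + sum((X[t, ] - xb) * (X[t + tau, ] - xb))
    r[tau + 1] <- (num / (T_len - tau)) / v
  }
  r
}

# GDV by explicit pairwise loops: z-score (population SD) * 0.5, mean
# intra-class and inter-class Euclidean distances, D^(-1/2) scaling.
oracle_gdv <- function(points, labels, rescale = 0.5) {
  X <- as.matrix(points)
  n <- nrow(X); D <- ncol(X)
  for (d in 1:D) {
    mu <- mean(X[, d])
    sdd <- sqrt(mean((X[, d] - mu)^2))
    X[, d] <- rescale * (X[, d] - mu) / sdd
  }
  labels <- as.factor(labels)
  lv <- levels(labels)
  euclid <- function(a, b) sqrt(sum((a - b)^2))
  intra <- numeric(length(lv))
  for (li in seq_along(lv)) {
    idx <- which(labels == lv[li])
    s <- 0; cnt <- 0
    for (a in seq_along(idx)) for (b in seq_along(idx)) if (a < b) {
      s <- s + euclid(X[idx[a], ], X[idx[b], ]); cnt <- cnt + 1
    }
    intra[li] <- s / cnt
  }
  inter <- c()
  for (li in seq_along(lv)) for (mi in seq_along(lv)) if (li < mi) {
    ia <- which(labels == lv[li]); ib <- which(labels == lv[mi])
    s <- 0
    for (a in ia) for (b in ib) s <- s + euclid(X[a, ], X[b, ])
    inter <- c(inter, s / (length(ia) * length(ib)))
  }
  (mean(intra) - mean(inter)) / sqrt(D)
}
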