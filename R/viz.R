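#' Metric multidimensional scaling of a point cloud
#'
#' Projects N points from D dimensions into 2 (or 3) dimensions by metric
#' MDS on the Euclidean distance matrix (classical Torgerson scaling), the
#' standard way to look at high-dimensional embeddings such as network layer
#' activations. The procedure is deterministic; the `seed` argument is
#' recorded in the result so projections are fully reproducible and
#' self-documenting. Kruskal's stress-1 between input and projected distances
#' is reported.
#'
#' Only relative distances between projected points are meaningful; absolute
#' coordinates (including sign and rotation) carry no information. Plot
#' methods annotate this caveat.
#'
#' @param points Numeric N x D matrix (N >= 3), finite values, or a
#'   [labeled_embedding()] (labels are carried into the result for plotting).
#' @param out_dim 2 or 3.
#' @param seed Integer recorded in the result.
#' @return Object of class `"mds_projection"`: `coords` (N x out_dim),
#'   `stress` (>= 0), `seed`, and optional `labels`.
#' @examples
#' tri <- diag(3)  # equilateral triangle in 3-D
#' p <- mds_project(tri)
#' round(p$stress, 6)
#' @export
mds_project <- function(points, out_dim = 2, seed = 0L) {
  labels <- NULL
  if (inherits(points, "labeled_embedding")) {
    labels <- points$labels
    points <- points$points
  }
  points <- as.matrix(points)
  if (any(!is.finite(points)))
    stop("points must be finite", call. = FALSE)
  if (nrow(points) < 3L) stop("need at least 3 points", call. = FALSE)
  if (!out_dim %in% c(2L, 3L)) stop("out_dim must be 2 or 3", call. = FALSE)
  d_in <- stats::dist(points)
  coords <- stats::cmdscale(d_in, k = out_dim)
  if (ncol(coords) < out_dim)   # rank-deficient cloud: pad with zeros
    coords <- cbind(coords, matrix(0, nrow(coords), out_dim - ncol(coords)))
  d_out <- stats::dist(coords)
  stress <- sqrt(sum((d_in - d_out)^2) / sum(d_in^2))
  structure(list(coords = coords, stress = stress, seed = as.integer(seed),
                 labels = labels),
            class = "mds_projection")
}

#' @export
print.mds_projection <- function(x, ...) {
  cat(sprintf("MDS projection: %d points -> %d-D, stress-1 = %.4g (seed %d)\n",
              nrow(x$coords), ncol(x$coords), x$stress, x$seed))
  invisible(x)
}

# open a graphics device chosen by file extension; caller must dev.off()
open_device <- function(path, width = 8, height = 5) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150),
         svg = grDevices::svg(path, width = width, height = height),
         pdf = grDevices::pdf(path, width = width, height = height),
         stop("unsupported figure format '.", ext, "' (png/svg/pdf)",
              call. = FALSE))
}

#' Hypnodensity graph
#'
#' Draws the stacked-area hypnodensity graph: at every time point the five
#' stage probabilities are stacked (they sum to 1), so the band widths show
#' both the momentary stage and the classifier's uncertainty. One panel per
#' channel, shared time axis in hours.
#'
#' @param series A [hypnodensity()] or a list of them (one panel each).
#' @param path Output figure file (`.png`, `.svg` or `.pdf`).
#' @param col Stage colours; default [stage_colors()].
#' @return `path`, invisibly.
#' @export
plot_hypnodensity <- function(series, path, col = stage_colors()) {
  if (inherits(series, "hypnodensity")) series <- list(series)
  if (!length(series)) stop("no series to plot", call. = FALSE)
  for (s in series)
    if (!nrow(s$probs)) stop("empty series", call. = FALSE)
  open_device(path, width = 9, height = 2.2 * length(series) + 0.8)
  on.exit(grDevices::dev.off())
  old <- graphics::par(mfrow = c(length(series), 1L),
                       mar = c(3.5, 4, 1.5, 5), xpd = FALSE)
  on.exit(graphics::par(old), add = TRUE)
  for (s in series) {
    h <- s$times / 3600
    cum <- cbind(0, t(apply(s$probs, 1L, cumsum)))
    plot(NA, xlim = range(h), ylim = c(0, 1), xlab = "", ylab = "probability",
         main = s$channel, xaxs = "i", yaxs = "i")
    for (k in seq_len(N_STAGES)) {
      graphics::polygon(c(h, rev(h)), c(cum[, k], rev(cum[, k + 1L])),
                        col = col[k], border = NA)
    }
    graphics::mtext("time (h)", side = 1, line = 2.2, cex = 0.8)
    graphics::legend("topright", inset = c(-0.12, 0), legend = stage_labels(),
                     fill = col, bty = "n", cex = 0.8, xpd = TRUE)
  }
  invisible(path)
}

#' Correlation curves with detected maxima
#'
#' Plots one or more hypnodensity correlation curves against lag in minutes,
#' optionally marking detected local maxima and annotating the implied
#' sleep-cycle period. A full `"corr_matrix"` from
#' [channel_correlation_summary()] is laid out as a grid.
#'
#' @param curves A `"corr_curve"`, a list of them (overlaid), or a
#'   `"corr_matrix"` (grid layout).
#' @param path Output figure file (`.png`, `.svg` or `.pdf`).
#' @param maxima Optional `"period_estimate"` whose maxima are marked.
#' @return `path`, invisibly.
#' @export
plot_correlation <- function(curves, path, maxima = NULL) {
  if (inherits(curves, "corr_matrix")) {
    n <- nrow(curves)
    open_device(path, width = 3 * n, height = 2.5 * n)
    on.exit(grDevices::dev.off())
    old <- graphics::par(mfrow = c(n, n), mar = c(3.5, 3.5, 1.5, 0.5))
    on.exit(graphics::par(old), add = TRUE)
    for (i in seq_len(n)) for (j in seq_len(n))
      draw_curve(list(curves[[i, j]]), NULL)
    return(invisible(path))
  }
  if (inherits(curves, "corr_curve")) curves <- list(curves)
  open_device(path, width = 8, height = 4.5)
  on.exit(grDevices::dev.off())
  old <- graphics::par(mar = c(4, 4, 1.5, 0.5))
  on.exit(graphics::par(old), add = TRUE)
  draw_curve(curves, maxima)
  invisible(path)
}

draw_curve <- function(curves, maxima) {
  xlim <- range(unlist(lapply(curves, function(cv) cv$lags))) / 60
  ylim <- range(unlist(lapply(curves, function(cv) cv$values)))
  plot(NA, xlim = xlim, ylim = ylim, xlab = "lag (min)", ylab = "r",
       main = paste0(curves[[1L]]$channel_x,
                     if (curves[[1L]]$kind == "cross")
                       paste0(" x ", curves[[1L]]$channel_y) else ""))
  cols <- grDevices::hcl.colors(max(3L, length(curves)), "Dark 3")
  for (i in seq_along(curves))
    graphics::lines(curves[[i]]$lags / 60, curves[[i]]$values, col = cols[i])
  graphics::abline(h = 0, lty = 3, col = "grey")
  if (!is.null(maxima) && length(maxima$maxima_lags)) {
    graphics::points(maxima$maxima_lags / 60, maxima$maxima_values,
                     pch = 19, col = "black")
    graphics::mtext(sprintf("period ≈ %.0f min",
                            maxima$period_seconds / 60),
                    side = 3, adj = 1, cex = 0.9)
  }
}

#' GDV-versus-layer profile plot
#'
#' Line-and-dot plot of a [gdv_profile()]: layer names on the x-axis, GDV on
#' the y-axis, with reference lines at 0 (non-separable) and -1 (perfect
#' separation).
#'
#' @param profile A `"gdv_profile"`.
#' @param path Output figure file (`.png`, `.svg` or `.pdf`).
#' @return `path`, invisibly.
#' @export
plot_gdv_profile <- function(profile, path) {
  stopifnot(inherits(profile, "gdv_profile"))
  open_device(path, width = 7, height = 4.5)
  on.exit(grDevices::dev.off())
  old <- graphics::par(mar = c(6, 4, 1.5, 0.5))
  on.exit(graphics::par(old), add = TRUE)
  n <- length(profile$gdv_values)
  plot(seq_len(n), profile$gdv_values, type = "b", pch = 19, col = "red",
       xaxt = "n", xlab = "", ylab = "GDV",
       ylim = range(c(-1, 0, profile$gdv_values)))
  graphics::axis(1, at = seq_len(n), labels = profile$layer_names, las = 2,
                 cex.axis = 0.8)
  graphics::abline(h = 0, lty = 3)
  graphics::abline(h = -1, lty = 3)
  invisible(path)
}

#' @export
plot.mds_projection <- function(x, col = NULL, ...) {
  lab <- x$labels
  if (is.null(col))
    col <- if (is.null(lab)) "black"
    else grDevices::hcl.colors(nlevels(lab), "Dark 3")[as.integer(lab)]
  plot(x$coords[, 1L], x$coords[, 2L], col = col, pch = 19,
       xlab = "MDS 1", ylab = "MDS 2", ...)
  graphics::mtext("absolute coordinates scale relative distances only",
                  side = 3, cex = 0.7)
  if (!is.null(lab))
    graphics::legend("topright", legend = levels(lab), bty = "n", pch = 19,
                     col = grDevices::hcl.colors(nlevels(lab), "Dark 3"))
  invisible(x)
}

#' @export
plot.corr_curve <- function(x, ...) {
  plot(x$lags / 60, x$values, type = "l", xlab = "lag (min)", ylab = "r", ...)
  graphics::abline(h = 0, lty = 3, col = "grey")
  invisible(x)
}

#' @export
plot.period_track <- function(x, ...) {
  plot(x$midpoint_seconds / 3600, x$period_seconds / 60, type = "b", pch = 19,
       xlab = "time (h)", ylab = "period (min)", ...)
  invisible(x)
}
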