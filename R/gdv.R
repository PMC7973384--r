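#' Labeled embedding
#'
#' A point cloud with class labels: N points in D dimensions plus one class
#' label per point, e.g. layer activations of a network with the sleep stage
#' of each input, or any labeled feature matrix. Input container for [gdv()]
#' and [mds_project()].
#'
#' @param points Numeric N x D matrix; all values finite.
#' @param labels Class label per point (factor, character or integer).
#' @param layer_name Free-text name, used in GDV profiles.
#' @return Object of class `"labeled_embedding"`.
#' @export
labeled_embedding <- function(points, labels, layer_name = "") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (any(!is.finite(points)))
    stop("points must be finite", call. = FALSE)
  labels <- as.factor(labels)
  if (length(labels) != nrow(points))
    stop("labels length must equal number of points", call. = FALSE)
  structure(list(points = points, labels = labels,
                 layer_name = as.character(layer_name)),
            class = "labeled_embedding")
}

#' @export
print.labeled_embedding <- function(x, ...) {
  cat(sprintf("Labeled embedding%s: %d points, %d dims, %d classes\n",
              if (nzchar(x$layer_name)) paste0(" '", x$layer_name, "'") else "",
              nrow(x$points), ncol(x$points), nlevels(x$labels)))
  invisible(x)
}

#' Generalized discrimination value (GDV)
#'
#' A scale- and translation-invariant index of how well the classes of a
#' labeled point cloud separate: 0 for non-separable classes (identical
#' distributions) and -1 for perfectly separated classes. Computed as
#'
#' 1. z-score each dimension over all points and multiply by a rescaling
#'    factor (default 0.5);
#' 2. mean intra-class Euclidean distance `d(C_l)` per class (mean over all
#'    unordered point pairs within the class);
#' 3. mean inter-class distance `d(C_l, C_m)` per unordered class pair
#'    (mean over all cross pairs);
#' 4. `GDV = D^(-1/2) * [ mean_l d(C_l) - mean_{l<m} d(C_l, C_m) ]`.
#'
#' With the 0.5 factor, two point-like classes pushed infinitely far apart
#' reach exactly -1. Z-scoring uses the population standard deviation;
#' dimensions with zero variance carry no class information and are dropped
#' with a warning before scaling.
#'
#' @param embedding A [labeled_embedding()] with >= 2 classes and >= 2 points
#'   per class.
#' @param rescale Per-dimension factor applied after z-scoring; default 0.5.
#' @return A single numeric value; <= 0 in practice for separable data.
#' @examples
#' set.seed(1)
#' pts <- rbind(matrix(rnorm(100), 50), matrix(rnorm(100, mean = 4), 50))
#' gdv(labeled_embedding(pts, rep(c("a", "b"), each = 50)))
#' @export
gdv <- function(embedding, rescale = 0.5) {
  stopifnot(inherits(embedding, "labeled_embedding"))
  labels <- embedding$labels
  counts <- table(labels)
  if (length(counts) < 2L)
    stop("need at least 2 classes", call. = FALSE)
  if (any(counts < 2L))
    stop("every class needs at least 2 points", call. = FALSE)
  X <- embedding$points
  n <- nrow(X)
  mu <- colMeans(X)
  sd_pop <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  keep <- sd_pop > 0
  if (!any(keep))
    stop("degenerate input: all dimensions have zero variance", call. = FALSE)
  if (!all(keep))
    warning(sum(!keep), " zero-variance dimension(s) dropped before z-scoring",
            call. = FALSE)
  Z <- rescale * sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep]),
                       2L, sd_pop[keep], "/")
  D <- ncol(Z)

  dist_mat <- as.matrix(stats::dist(Z))
  lv <- levels(labels)
  L <- length(lv)
  idx <- split(seq_len(n), labels)

  intra <- vapply(idx, function(i) {
    d <- dist_mat[i, i]
    sum(d) / (length(i) * (length(i) - 1L))   # mean over unordered pairs
  }, numeric(1))

  inter <- c()
  for (l in seq_len(L - 1L)) for (m in (l + 1L):L) {
    inter <- c(inter, mean(dist_mat[idx[[l]], idx[[m]]]))
  }
  (mean(intra) - mean(inter)) / sqrt(D)
}

#' GDV profile across network layers
#'
#' Evaluates the GDV for the same labeled samples as seen at successive
#' processing layers, yielding a separability-vs-depth profile: layers that
#' disentangle the classes drive the GDV downward.
#'
#' @param embeddings Ordered list of [labeled_embedding()]s sharing the same
#'   label vector (the same samples through different layers).
#' @param ... Passed to [gdv()].
#' @return Object of class `"gdv_profile"`: list with `layer_names` and
#'   `gdv_values`.
#' @export
gdv_profile <- function(embeddings, ...) {
  if (!is.list(embeddings) || !length(embeddings))
    stop("embeddings must be a non-empty list", call. = FALSE)
  ref <- embeddings[[1L]]$labels
  for (e in embeddings) {
    if (!identical(as.character(e$labels), as.character(ref)))
      stop("all embeddings must carry identical label vectors", call. = FALSE)
  }
  names_ <- vapply(seq_along(embeddings), function(i) {
    nm <- embeddings[[i]]$layer_name
    if (nzchar(nm)) nm else paste0("layer", i)
  }, character(1))
  vals <- vapply(embeddings, gdv, numeric(1), ...)
  structure(list(layer_names = names_, gdv_values = unname(vals)),
            class = "gdv_profile")
}

#' @export
print.gdv_profile <- function(x, ...) {
  cat("GDV profile (0 = non-separable, -1 = perfect separation):\n")
  print(stats::setNames(round(x$gdv_values, 4), x$layer_names))
  invisible(x)
}
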