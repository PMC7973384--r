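#' Construct a hypnogram
#'
#' A hypnogram is the classical representation of a scored night: one sleep
#' stage per fixed-length epoch (30 s by convention), plus a per-epoch
#' artifact flag marking epochs that were removed from analysis.
#'
#' @param stages Stage sequence: canonical 1-based indices (1..5) or labels
#'   (`"Wake"`/`"W"`, `"N1"`, `"N2"`, `"N3"`, `"REM"`).
#' @param epoch_seconds Epoch duration in seconds (> 0); default 30.
#' @param artifact Logical vector, one flag per epoch (`TRUE` = artifact);
#'   defaults to all `FALSE`.
#' @return An object of class `"hypnogram"`: a list with integer `stages`,
#'   `epoch_seconds` and logical `artifact`.
#' @examples
#' h <- hypnogram(c("Wake", "N1", "N2", "N3", "REM"))
#' print(h)
#' @export
hypnogram <- function(stages, epoch_seconds = 30, artifact = NULL) {
  idx <- stage_index(stages)
  if (!is.numeric(epoch_seconds) || length(epoch_seconds) != 1L ||
      epoch_seconds <= 0)
    stop("epoch_seconds must be a single positive number", call. = FALSE)
  if (is.null(artifact)) artifact <- rep(FALSE, length(idx))
  artifact <- as.logical(artifact)
  if (length(artifact) != length(idx))
    stop("artifact mask length must equal number of epochs", call. = FALSE)
  if (anyNA(artifact)) stop("artifact mask must not contain NA", call. = FALSE)
  structure(list(stages = idx, epoch_seconds = as.numeric(epoch_seconds),
                 artifact = artifact),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  dur_h <- length(x$stages) * x$epoch_seconds / 3600
  cat(sprintf("Hypnogram: %d epochs of %g s (%.2f h), %d artifact epoch(s)\n",
              length(x$stages), x$epoch_seconds, dur_h, sum(x$artifact)))
  tab <- table(factor(stage_labels()[x$stages], levels = stage_labels()))
  print(tab)
  invisible(x)
}

#' @export
summary.hypnogram <- function(object, ...) {
  tab <- table(factor(stage_labels()[object$stages], levels = stage_labels()))
  structure(list(n_epochs = length(object$stages),
                 epoch_seconds = object$epoch_seconds,
                 stage_counts = tab,
                 n_artifact = sum(object$artifact)),
            class = "summary.hypnogram")
}

#' @export
print.summary.hypnogram <- function(x, ...) {
  cat(sprintf("%d epochs x %g s, %d artifacts\n",
              x$n_epochs, x$epoch_seconds, x$n_artifact))
  print(x$stage_counts)
  invisible(x)
}

#' Read / write a hypnogram as tab-separated text
#'
#' The on-disk format has columns `epoch_index` (0-based), `stage`
#' (one of `W`, `N1`, `N2`, `N3`, `REM`) and `artifact` (0/1). Lines starting
#' with `#` are comments.
#'
#' @param path File path.
#' @param h A [hypnogram()] (write only).
#' @param epoch_seconds Epoch duration to attach on read; default 30.
#' @return `read_hypnogram_tsv` returns a [hypnogram()];
#'   `write_hypnogram_tsv` returns `path` invisibly.
#' @export
read_hypnogram_tsv <- function(path, epoch_seconds = 30) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- seq_along(keep)[keep]
  if (length(lines) < 2L) stop("hypnogram file has no data rows", call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, c("epoch_index", "stage", "artifact")))
    stop("bad hypnogram header at line ", lineno[1L],
         ": expected 'epoch_index\tstage\tartifact'", call. = FALSE)
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L))
    stop("malformed hypnogram row at line ", lineno[-1L][which(nf != 3L)[1L]],
         call. = FALSE)
  m <- matrix(unlist(fields), ncol = 3L, byrow = TRUE)
  stages <- stage_index(sub("^W$", "Wake", m[, 2L]))
  art <- m[, 3L]
  if (!all(art %in% c("0", "1")))
    stop("artifact flag must be 0 or 1 (line ",
         lineno[-1L][which(!(art %in% c("0", "1")))[1L]], ")", call. = FALSE)
  hypnogram(stages, epoch_seconds = epoch_seconds, artifact = art == "1")
}

#' @rdname read_hypnogram_tsv
#' @export
write_hypnogram_tsv <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  lab <- c("W", "N1", "N2", "N3", "REM")[h$stages]
  lines <- c("epoch_index\tstage\tartifact",
             sprintf("%d\t%s\t%d", seq_along(h$stages) - 1L, lab,
                     as.integer(h$artifact)))
  writeLines(lines, path)
  invisible(path)
}

#' Deterministic dataset-level train/test split
#'
#' Randomly partitions `n_datasets` whole recordings into training and test
#' sets. The training size is `n_datasets * train_fraction` rounded half-down,
#' so 68 recordings at 80% give the conventional 54 training / 14 test split.
#'
#' @param n_datasets Number of datasets (>= 2).
#' @param train_fraction Fraction assigned to training, strictly in (0, 1).
#' @param seed Integer seed; the same seed always yields the same partition.
#' @return List with integer vectors `train` and `test` (1-based dataset
#'   indices); disjoint and jointly exhaustive.
#' @examples
#' s <- train_test_split_datasets(68, 0.8, seed = 1)
#' length(s$train); length(s$test)
#' @export
train_test_split_datasets <- function(n_datasets, train_fraction, seed = 0L) {
  if (!is.numeric(n_datasets) || n_datasets < 2)
    stop("n_datasets must be >= 2", call. = FALSE)
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be strictly between 0 and 1", call. = FALSE)
  n <- as.integer(n_datasets)
  # round half-down: exactly .5 goes to the smaller training set
  n_train <- as.integer(ceiling(n * train_fraction - 0.5))
  n_train <- max(1L, min(n - 1L, n_train))
  perm <- local_rng(seed, sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[(n_train + 1L):n]))
}

# Evaluate `expr` under a temporary, seeded RNG state, restoring the caller's
# RNG afterwards; keeps all package randomness free of global side effects.
local_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
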