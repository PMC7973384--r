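#' Canonical sleep-stage set
#'
#' The five AASM sleep stages in the fixed canonical order used everywhere in
#' this package: Wake, N1, N2, N3, REM, at indices 1..5 (0..4 zero-based).
#' All hypnodensity columns, hypnogram codes, file headers, plot legends and
#' correlation computations use this order, so that series from different
#' sources are directly comparable.
#'
#' @return Character vector of the five stage labels in canonical order.
#' @examples
#' stage_labels()
#' @export
stage_labels <- function() c("Wake", "N1", "N2", "N3", "REM")

#' Default stage colours for hypnodensity and correlation figures
#'
#' Wake is gold, the non-REM stages run light to dark blue with depth, and
#' REM is red. Arbitrary but fixed for cross-figure consistency; every plot
#' function accepts a `col` argument to override.
#'
#' @return Named character vector of colours, one per canonical stage.
#' @export
stage_colors <- function() {
  c(Wake = "#E6B800", N1 = "#9ECAE1", N2 = "#4292C6", N3 = "#08519C",
    REM = "#CB181D")
}

N_STAGES <- 5L

# Map a stage given as label ("Wake"/"W", "N1", ...) or 1-based index to the
# canonical 1-based index; errors on anything unknown.
stage_index <- function(stage) {
  if (is.numeric(stage)) {
    idx <- as.integer(stage)
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > N_STAGES))
      stop("stage index out of range 1..5", call. = FALSE)
    return(idx)
  }
  lab <- as.character(stage)
  lab[lab == "W"] <- "Wake"
  lab[lab == "R"] <- "REM"
  idx <- match(lab, stage_labels())
  if (any(is.na(idx)))
    stop("unknown stage label(s): ",
         paste(unique(lab[is.na(idx)]), collapse = ", "), call. = FALSE)
  idx
}
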