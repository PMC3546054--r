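# Pixels of a filled disc clipped to image bounds, in row-major order.
discPixels <- function(center, radius, dim) {
    r0 <- center[1]; c0 <- center[2]
    rows <- max(1L, ceiling(r0 - radius)):min(dim[1], floor(r0 + radius))
    px <- do.call(rbind, lapply(rows, function(r) {
        half <- sqrt(max(0, radius^2 - (r - r0)^2))
        cols <- max(1L, ceiling(c0 - half)):min(dim[2], floor(c0 + half))
        cols <- cols[(r - r0)^2 + (cols - c0)^2 <= radius^2]
        if (length(cols)) cbind(row = r, col = cols) else NULL
    }))
    if (is.null(px)) px <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
    px
}

# Sort pixel coordinates row-major (scan rows, then columns) — the
# deterministic tie-break order used throughout selection.
orderRowMajor <- function(px) px[order(px[, 1], px[, 2]), , drop = FALSE]

# Linear indices of (row, col) pixels in a matrix with nr rows.
pixelIndex <- function(px, nr) (px[, 2] - 1L) * nr + px[, 1]

#' Frame times of a trajectory set
#' @param x a [LocTrajectorySet-class].
#' @return numeric vector of frame times in seconds.
#' @export
frameTimes <- function(x) x$time

#' Localization values of a trajectory set
#' @param x a [LocTrajectorySet-class].
#' @return numeric matrix, cells x frames.
#' @export
locValues <- function(x) SummarizedExperiment::assay(x, "loc")

#' Cleaned binary state matrix of a trajectory set
#' @param x a [LocTrajectorySet-class] processed by [detectStates()].
#' @return integer matrix, cells x frames (1 = nuclear).
#' @export
stateMatrix <- function(x) {
    if (!"state" %in% SummarizedExperiment::assayNames(x))
        stop("no 'state' assay: run detectStates() first")
    SummarizedExperiment::assay(x, "state")
}

#' Ground-truth binary states of a simulated trajectory set
#' @param x a simulated [LocTrajectorySet-class].
#' @return integer matrix, cells x frames (1 = nuclear).
#' @export
truthStates <- function(x) {
    if (!"truth" %in% SummarizedExperiment::assayNames(x))
        stop("no 'truth' assay: not a simulated set")
    SummarizedExperiment::assay(x, "truth")
}

#' Cell identifiers of a trajectory set
#' @param x a [LocTrajectorySet-class].
#' @return character vector of cell ids.
#' @export
cellIds <- function(x) rownames(x)

#' Simulated archetype labels
#' @param x a simulated [LocTrajectorySet-class].
#' @return character vector over `no_response`, `only_oscillating`,
#'   `permanent`.
#' @export
archetype <- function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"archetype" %in% colnames(rd))
        stop("no 'archetype' column: not a simulated set")
    as.character(rd$archetype)
}
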