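#' Gaussian-smooth a single frame
#'
#' Linear Gaussian blur used purely as the substrate for pixel selection
#' (nucleus and cytosol definition); medians are taken on original
#' intensities by default. Total intensity is preserved up to boundary
#' treatment (circular).
#'
#' @param frame 2-D numeric matrix of intensities.
#' @param sigma Gaussian sd in pixels (> 0).
#' @return matrix of the same dimensions.
#' @examples
#' f <- matrix(10, 9, 9); f[5, 5] <- 100
#' s <- smoothFrame(f, 1)
#' which.max(s) == which.max(f)
#' @export
smoothFrame <- function(frame, sigma = 2) {
    if (sigma <= 0) stop("sigma: must be > 0")
    as.matrix(EBImage::gblur(frame, sigma = sigma))
}

#' Define the nucleus of a cell
#'
#' In the smoothed frame, the brightest pixel within the cell region and
#' all in-region pixels within a Euclidean `radius` of it are taken as the
#' nucleus (29 pixels for radius 3 before clipping to the region). Ties for
#' the brightest pixel are broken by row-major scan order.
#'
#' @param smoothed smoothed 2-D intensity matrix.
#' @param region integer matrix of (row, col) pixel coordinates of one cell.
#' @param radius disc radius in pixels around the brightest pixel.
#' @return (row, col) matrix of nucleus pixels, row-major ordered.
#' @seealso [defineCytosol()], [extractTrajectory()]
#' @export
defineNucleus <- function(smoothed, region, radius = 3) {
    region <- as.matrix(region)
    if (nrow(region) == 0L) stop("region: must be non-empty")
    region <- orderRowMajor(region)
    vals <- smoothed[pixelIndex(region, nrow(smoothed))]
    b <- region[which.max(vals), ]   # first max in row-major order
    d2 <- (region[, 1] - b[1])^2 + (region[, 2] - b[2])^2
    region[d2 <= radius^2, , drop = FALSE]
}

#' Define the cytosol of a cell
#'
#' The `k` brightest remaining cell pixels (smoothed intensities) after
#' removing the nucleus. Using a fixed pixel count damps fluctuations from
#' vacuoles or slightly wrong cell contours. If fewer than `k` pixels
#' remain, all are returned with a warning. Ties at the k-th intensity are
#' broken by row-major scan order.
#'
#' @param smoothed smoothed 2-D intensity matrix.
#' @param region (row, col) matrix of cell pixels.
#' @param nucleus (row, col) matrix of nucleus pixels to exclude.
#' @param k number of cytosolic pixels to keep (default 90).
#' @return (row, col) matrix of cytosol pixels.
#' @export
defineCytosol <- function(smoothed, region, nucleus, k = 90) {
    region <- orderRowMajor(as.matrix(region))
    nr <- nrow(smoothed)
    idx <- pixelIndex(region, nr)
    rest <- !(idx %in% pixelIndex(as.matrix(nucleus), nr))
    region <- region[rest, , drop = FALSE]
    if (nrow(region) == 0L)
        stop("region: no pixels remain after nucleus removal")
    if (nrow(region) < k) {
        warning(sprintf("only %d cytosolic pixels available (requested %d)",
                        nrow(region), k))
        return(region)
    }
    vals <- smoothed[pixelIndex(region, nr)]
    # stable sort: descending intensity, ties in row-major order
    region[order(-vals)[seq_len(k)], , drop = FALSE]
}

#' Extract the localization trajectory of one cell
#'
#' For every frame: smooth, locate the nucleus ([defineNucleus()]) and the
#' cytosol ([defineCytosol()]) in the smoothed frame, then report the
#' median intensity of each pixel set and the localization value
#' `nuclear/cytosol - 1`. Selection always happens on the smoothed frame;
#' by default the medians are measured on the original intensities
#' (`measureOn = "original"`), which avoids biasing them toward the blur
#' scale — set `measureOn = "smoothed"` to measure on the blurred values.
#' The localization value is invariant under global rescaling of the stack.
#'
#' @param stack an [ImageStack-class].
#' @param region (row, col) matrix of the cell's pixels (constant over
#'   time; cells are assumed immobilized).
#' @param sigma smoothing sd in pixels.
#' @param radius nucleus disc radius in pixels.
#' @param k cytosolic pixel count.
#' @param measureOn `"original"` or `"smoothed"`.
#' @param cellId label for the output.
#' @return data.frame with columns `time`, `nuclear`, `cytosol`, `loc`.
#' @export
extractTrajectory <- function(stack, region, sigma = 2, radius = 3, k = 90,
                              measureOn = c("original", "smoothed"),
                              cellId = "cell_1") {
    measureOn <- match.arg(measureOn)
    stopifnot(is(stack, "ImageStack"))
    region <- as.matrix(region)
    nFrames <- length(stack)
    out <- matrix(0, nFrames, 2)
    nr <- dim(stack@data)[1]
    for (f in seq_len(nFrames)) {
        frame <- stack@data[, , f]
        sm <- smoothFrame(frame, sigma)
        nuc <- defineNucleus(sm, region, radius)
        cyt <- defineCytosol(sm, region, nuc, k)
        src <- if (measureOn == "original") frame else sm
        out[f, ] <- c(stats::median(src[pixelIndex(nuc, nr)]),
                      stats::median(src[pixelIndex(cyt, nr)]))
    }
    data.frame(cell_id = cellId, time = stack@times,
               nuclear = out[, 1], cytosol = out[, 2],
               loc = out[, 1] / out[, 2] - 1)
}

#' Extract localization trajectories for all cells of a stack
#'
#' Vectorized driver of [extractTrajectory()] over a labelled cell mask:
#' each frame is smoothed once, then nucleus/cytosol selection and medians
#' are computed per cell.
#'
#' @param stack an [ImageStack-class].
#' @param mask integer label matrix (0 = background, j = cell j) of the
#'   same dimensions as the frames.
#' @inheritParams extractTrajectory
#' @return a [LocTrajectorySet-class] with assays `loc`, `nuclear`,
#'   `cytosol`. Cells with fewer than `k` available cytosolic pixels are
#'   counted in `metadata(x)$shortCytosolCells`.
#' @examples
#' x <- simulatePopulation(SimScenario(nCells = 4, duration = 40, noiseSd = 0))
#' r <- renderFrames(x, autoLayout(4))
#' tr <- extractTrajectories(r$stack, r$mask)
#' round(range(locValues(tr)), 3)
#' @export
extractTrajectories <- function(stack, mask, sigma = 2, radius = 3, k = 90,
                                measureOn = c("original", "smoothed")) {
    measureOn <- match.arg(measureOn)
    stopifnot(is(stack, "ImageStack"))
    if (!all(dim(mask) == dim(stack@data)[1:2]))
        stop("mask: dimensions must match the frames")
    labels <- sort(setdiff(unique(as.integer(mask)), 0L))
    if (!length(labels)) stop("mask: contains no cells")
    nr <- nrow(mask)
    regions <- lapply(labels, function(l) {
        w <- which(mask == l)
        orderRowMajor(cbind(row = (w - 1L) %% nr + 1L, col = (w - 1L) %/% nr + 1L))
    })
    nFrames <- length(stack)
    nucM <- cytM <- matrix(0, length(labels), nFrames)
    short <- 0L
    for (f in seq_len(nFrames)) {
        frame <- stack@data[, , f]
        sm <- smoothFrame(frame, sigma)
        for (j in seq_along(labels)) {
            nuc <- defineNucleus(sm, regions[[j]], radius)
            cyt <- withCallingHandlers(
                defineCytosol(sm, regions[[j]], nuc, k),
                warning = function(w) {
                    short <<- short + 1L
                    invokeRestart("muffleWarning")
                })
            src <- if (measureOn == "original") frame else sm
            nucM[j, f] <- stats::median(src[pixelIndex(nuc, nr)])
            cytM[j, f] <- stats::median(src[pixelIndex(cyt, nr)])
        }
    }
    x <- LocTrajectorySet(nucM / cytM - 1, times = stack@times,
                          cellIds = sprintf("cell_%d", labels),
                          nuclear = nucM, cytosol = cytM)
    metadata(x)$extraction <- list(sigma = sigma, radius = radius, k = k,
                                   measureOn = measureOn)
    metadata(x)$shortCytosolCells <- short
    x
}

#' Background-subtracted reporter expression response
#'
#' For a slow whole-cell reporter: per frame, the mean intensity of each
#' cell minus the mean intensity of a cell-free background box; the
#' population response is the mean of this difference over cells. With
#' `mode = "relative"` the population trace is re-zeroed to its first time
#' point (the absolute difference is the default).
#'
#' @param stack an [ImageStack-class].
#' @param mask integer label matrix of cell regions.
#' @param backgroundBox integer vector `c(row1, row2, col1, col2)` of an
#'   arbitrary cell-free rectangle; must not intersect any cell region.
#' @param mode `"absolute"` or `"relative"`.
#' @return data.frame with columns `time` and `response`; the per-cell
#'   background-subtracted traces (cells x frames) are attached as
#'   attribute `"perCell"`.
#' @export
expressionResponse <- function(stack, mask, backgroundBox,
                               mode = c("absolute", "relative")) {
    mode <- match.arg(mode)
    stopifnot(is(stack, "ImageStack"), length(backgroundBox) == 4L)
    b <- as.integer(backgroundBox)
    if (b[1] > b[2] || b[3] > b[4]) stop("backgroundBox: need row1<=row2, col1<=col2")
    if (any(mask[b[1]:b[2], b[3]:b[4]] != 0L))
        stop("backgroundBox: overlaps a cell region")
    labels <- sort(setdiff(unique(as.integer(mask)), 0L))
    if (!length(labels)) stop("mask: contains no cells")
    cellIdx <- lapply(labels, function(l) which(mask == l))
    nFrames <- length(stack)
    perCell <- matrix(0, length(labels), nFrames,
                      dimnames = list(sprintf("cell_%d", labels), NULL))
    for (f in seq_len(nFrames)) {
        frame <- stack@data[, , f]
        bg <- mean(frame[b[1]:b[2], b[3]:b[4]])
        perCell[, f] <- vapply(cellIdx, function(ix) mean(frame[ix]), numeric(1)) - bg
    }
    resp <- colMeans(perCell)
    if (mode == "relative") resp <- resp - resp[1]
    out <- data.frame(time = stack@times, response = resp)
    attr(out, "perCell") <- perCell
    out
}
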