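#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

ARCHETYPES <- c("no_response", "only_oscillating", "permanent")

#' Generative scenario for synthetic localization trajectories
#'
#' A `SimScenario` bundles every parameter of the trajectory generator:
#' population size, acquisition timing, the mixture of single-cell response
#' archetypes, the lag-time distribution for permanent nuclear entry, the
#' burst statistics of the oscillatory archetype, the localization levels of
#' the two states and the measurement noise. All randomness downstream flows
#' from the `seed` slot; no global random state is consumed.
#'
#' Defaults emulate continuous blue-light stress experiments on immobilized
#' yeast cells: one frame every 4 s for 60 min, nucleus-to-cytosol intensity
#' ratios of ~1.8 when localized (localization value 0.8), oscillation
#' bursts of 2--3 min, and a log-normal lag (median 20 min) before permanent
#' nuclear entry.
#'
#' @slot nCells number of cells to simulate.
#' @slot frameInterval seconds between frames.
#' @slot duration total record length in seconds.
#' @slot archetypeWeights named non-negative proportions over
#'   `no_response`, `only_oscillating`, `permanent`; must sum to 1.
#' @slot lagMedian,lagSdlog median (seconds) and log-sd of the log-normal
#'   lag until permanent nuclear entry.
#' @slot burstRate oscillation bursts per minute (renewal process with
#'   exponential inter-burst gaps).
#' @slot burstDurationRange length-2 numeric, burst duration bounds in
#'   seconds (uniform).
#' @slot baselineLoc,nuclearLoc localization value in the cytoplasmic and
#'   nuclear state (dimensionless, ratio minus one).
#' @slot noiseSd sd of additive Gaussian noise on the localization value.
#' @slot seed integer seed.
#' @seealso [simulatePopulation()], [renderFrames()]
#' @export
setClass("SimScenario", representation(
    nCells = "integer",
    frameInterval = "numeric",
    duration = "numeric",
    archetypeWeights = "numeric",
    lagMedian = "numeric",
    lagSdlog = "numeric",
    burstRate = "numeric",
    burstDurationRange = "numeric",
    baselineLoc = "numeric",
    nuclearLoc = "numeric",
    noiseSd = "numeric",
    seed = "integer"
))

setValidity("SimScenario", function(object) {
    w <- object@archetypeWeights
    if (length(object@nCells) != 1L || is.na(object@nCells) || object@nCells < 1L)
        return("nCells: must be a single positive integer")
    if (length(w) != 3L || is.null(names(w)) || !setequal(names(w), ARCHETYPES))
        return(sprintf("archetypeWeights: must be named over {%s}",
                       paste(ARCHETYPES, collapse = ", ")))
    if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
        return("archetypeWeights: must be non-negative and sum to 1")
    if (object@frameInterval <= 0)
        return("frameInterval: must be > 0")
    if (object@duration < object@frameInterval)
        return("duration: must be >= frameInterval")
    b <- object@burstDurationRange
    if (length(b) != 2L || any(b <= 0) || b[1] > b[2])
        return("burstDurationRange: must satisfy 0 < low <= high")
    if (object@burstRate < 0)
        return("burstRate: must be >= 0")
    if (object@lagMedian <= 0 || object@lagSdlog < 0)
        return("lagMedian/lagSdlog: lagMedian > 0 and lagSdlog >= 0 required")
    if (object@noiseSd < 0)
        return("noiseSd: must be >= 0")
    TRUE
})

#' @param nCells,frameInterval,duration,archetypeWeights,lagMedian,lagSdlog,burstRate,burstDurationRange,baselineLoc,nuclearLoc,noiseSd,seed
#'   see slot documentation.
#' @return `SimScenario()` returns a validated `SimScenario` object.
#' @examples
#' sc <- SimScenario(nCells = 10, noiseSd = 0)
#' sc
#' @rdname SimScenario-class
#' @export
SimScenario <- function(nCells = 100L,
                        frameInterval = 4,
                        duration = 3600,
                        archetypeWeights = c(no_response = 0.2,
                                             only_oscillating = 0.5,
                                             permanent = 0.3),
                        lagMedian = 1200,
                        lagSdlog = 0.5,
                        burstRate = 0.2,
                        burstDurationRange = c(120, 180),
                        baselineLoc = 0,
                        nuclearLoc = 0.8,
                        noiseSd = 0.05,
                        seed = 1L) {
    new("SimScenario",
        nCells = as.integer(nCells), frameInterval = frameInterval,
        duration = duration,
        archetypeWeights = archetypeWeights[ARCHETYPES],
        lagMedian = lagMedian, lagSdlog = lagSdlog,
        burstRate = burstRate, burstDurationRange = as.numeric(burstDurationRange),
        baselineLoc = baselineLoc, nuclearLoc = nuclearLoc,
        noiseSd = noiseSd, seed = as.integer(seed))
}

setMethod("show", "SimScenario", function(object) {
    cat("SimScenario:", object@nCells, "cells,",
        object@duration / 60, "min at", object@frameInterval, "s/frame\n")
    w <- object@archetypeWeights
    cat("  archetypes:", paste(sprintf("%s=%.2f", names(w), w), collapse = ", "), "\n")
    cat(sprintf("  lag lognormal(median=%gs, sdlog=%g); bursts %g/min, %g-%gs\n",
                object@lagMedian, object@lagSdlog, object@burstRate,
                object@burstDurationRange[1], object@burstDurationRange[2]))
    cat(sprintf("  loc levels %g -> %g, noise sd %g, seed %d\n",
                object@baselineLoc, object@nuclearLoc, object@noiseSd, object@seed))
})

#' Geometry and intensities for rendering synthetic image stacks
#'
#' Cells are rendered as filled discs holding a smaller interior disc
#' nucleus. When a cell's true state is nuclear, its nucleus pixels are
#' multiplied by `nuclearGain`; all other cell pixels stay at
#' `cytosolIntensity`. Intensities are photon-like counts.
#'
#' @slot dim image dimensions, `c(rows, cols)` in pixels.
#' @slot centers n x 2 matrix of cell centre coordinates (row, col).
#' @slot cellRadius,nucleusRadius per-cell disc radii in pixels.
#' @slot nucleusOffset n x 2 matrix, nucleus centre offset from cell centre.
#' @slot background,cytosolIntensity counts outside/inside cells.
#' @slot nuclearGain multiplicative factor on nucleus pixels when localized.
#' @seealso [autoLayout()], [renderFrames()]
#' @export
setClass("RenderLayout", representation(
    dim = "integer",
    centers = "matrix",
    cellRadius = "numeric",
    nucleusRadius = "numeric",
    nucleusOffset = "matrix",
    background = "numeric",
    cytosolIntensity = "numeric",
    nuclearGain = "numeric"
))

setValidity("RenderLayout", function(object) {
    n <- nrow(object@centers)
    if (length(object@dim) != 2L || any(object@dim < 1L))
        return("dim: must be two positive pixel counts")
    if (ncol(object@centers) != 2L)
        return("centers: must be an n x 2 matrix")
    if (length(object@cellRadius) != n || length(object@nucleusRadius) != n ||
        nrow(object@nucleusOffset) != n)
        return("per-cell slots must have one entry per centre")
    # nucleus disc must sit fully inside its cell disc
    off <- sqrt(rowSums(object@nucleusOffset^2))
    if (any(off + object@nucleusRadius > object@cellRadius))
        return("nucleusOffset/nucleusRadius: nucleus region must lie inside its cell")
    if (n > 1L) {
        d <- as.matrix(dist(object@centers))
        rs <- outer(object@cellRadius, object@cellRadius, `+`)
        diag(d) <- Inf
        if (any(d <= rs))
            return("centers/cellRadius: cell regions must not overlap")
    }
    npix <- vapply(seq_len(n), function(i)
        nrow(discPixels(object@centers[i, ], object@cellRadius[i], object@dim)),
        integer(1))
    if (any(npix <= 120L))
        return("cellRadius/dim: every cell region must have > 120 pixels (clip to image?)")
    if (object@background < 0 || object@cytosolIntensity <= 0 || object@nuclearGain <= 0)
        return("background >= 0, cytosolIntensity > 0, nuclearGain > 0 required")
    TRUE
})

setMethod("show", "RenderLayout", function(object) {
    cat(sprintf("RenderLayout: %d cells on a %dx%d image\n",
                nrow(object@centers), object@dim[1], object@dim[2]))
    cat(sprintf("  background %g, cytosol %g, nuclear gain %g\n",
                object@background, object@cytosolIntensity, object@nuclearGain))
})

#' Trajectory-analysis parameters
#'
#' Parameters of the event-detection pipeline: the moving-average window,
#' the localization threshold, the minimum run length kept after cleanup,
#' the observation window over which per-cell metrics are computed, and the
#' minimum duration of a trailing nuclear run for a cell to be classified as
#' permanently localized.
#'
#' Defaults follow the standard analysis of blue-light shuttling
#' experiments: a 5-frame (~20 s) moving average, threshold 0.28 on the
#' localization value, runs shorter than 5 frames flipped, metrics over the
#' first 60 min.
#'
#' @slot window moving-average width in frames (odd, >= 1).
#' @slot threshold localization threshold (strictly-above comparison).
#' @slot minRun minimum run length in frames retained by cleanup.
#' @slot observationWindow seconds of record used for per-cell metrics.
#' @slot permanenceTail seconds the final nuclear run must last for the
#'   `permanent` classification.
#' @export
setClass("AnalysisParams", representation(
    window = "integer",
    threshold = "numeric",
    minRun = "integer",
    observationWindow = "numeric",
    permanenceTail = "numeric"
))

setValidity("AnalysisParams", function(object) {
    if (object@window < 1L || object@window %% 2L == 0L)
        return("window: must be an odd integer >= 1")
    if (object@minRun < 1L)
        return("minRun: must be >= 1")
    if (!is.finite(object@threshold))
        return("threshold: must be finite")
    if (object@observationWindow <= 0 || object@permanenceTail <= 0)
        return("observationWindow and permanenceTail must be > 0")
    TRUE
})

#' @param window,threshold,minRun,observationWindow,permanenceTail see slots.
#' @return `AnalysisParams()` returns a validated `AnalysisParams` object.
#' @examples
#' AnalysisParams()
#' @rdname AnalysisParams-class
#' @export
AnalysisParams <- function(window = 5L, threshold = 0.28, minRun = 5L,
                           observationWindow = 3600, permanenceTail = 600) {
    new("AnalysisParams", window = as.integer(window), threshold = threshold,
        minRun = as.integer(minRun), observationWindow = observationWindow,
        permanenceTail = permanenceTail)
}

setMethod("show", "AnalysisParams", function(object) {
    cat(sprintf(
        "AnalysisParams: window %d frames, threshold %g, minRun %d frames,\n",
        object@window, object@threshold, object@minRun))
    cat(sprintf("  observation window %g min, permanence tail %g min\n",
                object@observationWindow / 60, object@permanenceTail / 60))
})

#' Multi-frame fluorescence image stack
#'
#' An ordered set of single-channel intensity rasters with per-frame
#' timestamps. Pixel values are non-negative counts; coordinates are
#' (row, column), 1-based as usual in R.
#'
#' @slot data numeric array `rows x cols x frames`.
#' @slot times numeric vector of frame timestamps in seconds, strictly
#'   increasing, one per frame.
#' @seealso [renderFrames()], [extractTrajectories()], [readImageStack()]
#' @export
setClass("ImageStack", representation(data = "array", times = "numeric"))

setValidity("ImageStack", function(object) {
    d <- dim(object@data)
    if (length(d) != 3L)
        return("data: must be a rows x cols x frames array")
    if (length(object@times) != d[3])
        return("times: one timestamp per frame required")
    if (d[3] > 1L && any(diff(object@times) <= 0))
        return("times: must be strictly increasing")
    if (any(object@data < 0))
        return("data: intensities must be non-negative")
    TRUE
})

#' @param data,times see slots.
#' @return `ImageStack()` returns a validated `ImageStack`.
#' @rdname ImageStack-class
#' @export
ImageStack <- function(data, times) {
    new("ImageStack", data = data, times = as.numeric(times))
}

#' @describeIn ImageStack-class number of frames.
#' @param x,object an `ImageStack`.
#' @export
setMethod("length", "ImageStack", function(x) dim(x@data)[3])

setMethod("show", "ImageStack", function(object) {
    d <- dim(object@data)
    cat(sprintf("ImageStack: %d frames of %dx%d px, t = %g..%g s\n",
                d[3], d[1], d[2], object@times[1], object@times[d[3]]))
})

#' Set of single-cell localization trajectories
#'
#' `LocTrajectorySet` extends [SummarizedExperiment] with rows = cells and
#' columns = frames. The required `"loc"` assay holds the localization value
#' (nuclear/cytosolic median intensity ratio minus one); `colData(x)$time`
#' holds frame times in seconds. Optional assays: `"truth"` (ground-truth
#' binary state from the simulator), `"state"` (cleaned binary state from
#' [detectStates()]), `"nuclear"`/`"cytosol"` (median intensities from image
#' extraction). Simulated sets carry `archetype` and `entryTime` in
#' `rowData`; detection parameters are recorded in
#' `metadata(x)$analysisParams`.
#'
#' @seealso [simulatePopulation()], [extractTrajectories()], [detectStates()]
#' @export
setClass("LocTrajectorySet", contains = "SummarizedExperiment")

setValidity("LocTrajectorySet", function(object) {
    if (!"loc" %in% SummarizedExperiment::assayNames(object))
        return("assay 'loc' is required")
    tm <- object$time
    if (is.null(tm))
        return("colData must carry a 'time' column (seconds)")
    if (ncol(object) > 1L && any(diff(tm) <= 0))
        return("time: must be strictly increasing")
    for (nm in intersect(c("truth", "state"), SummarizedExperiment::assayNames(object))) {
        a <- SummarizedExperiment::assay(object, nm)
        if (!all(a %in% c(0, 1)))
            return(sprintf("assay '%s' must be binary", nm))
    }
    TRUE
})

#' Construct a LocTrajectorySet from a loc-value matrix
#'
#' @param loc numeric matrix, cells x frames.
#' @param times frame times in seconds (defaults to 0, dt, 2*dt, ...).
#' @param cellIds row identifiers (defaults to `cell_1 ...`).
#' @param ... further named assays of the same dimension (e.g. `truth`).
#' @return a validated [LocTrajectorySet-class] object.
#' @examples
#' x <- LocTrajectorySet(matrix(0, 2, 5), times = seq(0, 16, by = 4))
#' x
#' @export
LocTrajectorySet <- function(loc, times = (seq_len(ncol(loc)) - 1) * 4,
                             cellIds = NULL, ...) {
    loc <- as.matrix(loc)
    if (is.null(cellIds))
        cellIds <- if (!is.null(rownames(loc))) rownames(loc)
                   else sprintf("cell_%d", seq_len(nrow(loc)))
    dimnames(loc) <- list(cellIds, NULL)
    extra <- list(...)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = c(list(loc = loc), extra),
        colData = S4Vectors::DataFrame(time = as.numeric(times)))
    new("LocTrajectorySet", se)
}

setMethod("show", "LocTrajectorySet", function(object) {
    cat(sprintf("LocTrajectorySet: %d cells x %d frames (dt ~ %g s, %g min)\n",
                nrow(object), ncol(object),
                if (ncol(object) > 1) stats::median(diff(object$time)) else NA,
                diff(range(object$time)) / 60))
    cat("  assays:", paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
    if ("archetype" %in% colnames(SummarizedExperiment::rowData(object))) {
        tab <- table(SummarizedExperiment::rowData(object)$archetype)
        cat("  archetypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    }
    if (!is.null(metadata(object)$analysisParams))
        cat("  state detected with threshold",
            metadata(object)$analysisParams@threshold, "\n")
})

#' Result of a Mann-Whitney U comparison
#'
#' @slot statistic the U statistic for the first sample.
#' @slot n1,n2 sample sizes.
#' @slot pValue the p-value.
#' @slot alternative `"greater"` (first sample takes larger values) or
#'   `"two.sided"`.
#' @slot method `"exact"` (enumeration of the null) or `"normal_approx"`
#'   (tie- and continuity-corrected).
#' @seealso [mannWhitney()]
#' @export
setClass("UTestResult", representation(
    statistic = "numeric", n1 = "integer", n2 = "integer",
    pValue = "numeric", alternative = "character", method = "character"))

setValidity("UTestResult", function(object) {
    if (object@statistic < 0 || object@statistic > object@n1 * object@n2)
        return("statistic: U must lie in [0, n1*n2]")
    if (object@pValue <= 0 || object@pValue > 1)
        return("pValue: must lie in (0, 1]")
    TRUE
})

setMethod("show", "UTestResult", function(object) {
    cat(sprintf("Mann-Whitney U test (%s, %s)\n", object@method, object@alternative))
    cat(sprintf("  U = %g (n1 = %d, n2 = %d), p = %.4g\n",
                object@statistic, object@n1, object@n2, object@pValue))
})

#' Population-level summary of a condition
#'
#' @slot label condition label.
#' @slot nCells number of cells.
#' @slot fractionLocalized data.frame with columns `time` (s) and
#'   `fraction`, the instantaneous fraction of cells in the nuclear state.
#' @slot metrics per-cell metric table (see [cellMetrics()]).
#' @slot classCounts named integer counts over the three trajectory classes.
#' @slot medianTotalNuclearTime seconds, median over all cells.
#' @slot medianFirstLocalization seconds, median over responders only
#'   (`NA` when no cell responded).
#' @slot nCensored cells with no detected nuclear localization in the
#'   observation window.
#' @seealso [summarizeCondition()]
#' @export
setClass("PopulationSummary", representation(
    label = "character", nCells = "integer",
    fractionLocalized = "data.frame", metrics = "data.frame",
    classCounts = "integer", medianTotalNuclearTime = "numeric",
    medianFirstLocalization = "numeric", nCensored = "integer"))

setValidity("PopulationSummary", function(object) {
    if (nrow(object@fractionLocalized) &&
        (any(object@fractionLocalized$fraction < 0) ||
         any(object@fractionLocalized$fraction > 1)))
        return("fractionLocalized: fractions must lie in [0, 1]")
    if (sum(object@classCounts) != object@nCells)
        return("classCounts: must sum to nCells")
    TRUE
})

setMethod("show", "PopulationSummary", function(object) {
    cat(sprintf("PopulationSummary '%s': %d cells\n", object@label, object@nCells))
    cc <- object@classCounts
    cat("  classes:", paste(sprintf("%s=%d", names(cc), cc), collapse = ", "), "\n")
    cat(sprintf("  median total nuclear time: %.1f min\n",
                object@medianTotalNuclearTime / 60))
    if (is.na(object@medianFirstLocalization)) {
        cat("  median time to first localization: censored (no responders)\n")
    } else {
        cat(sprintf("  median time to first localization: %.1f min (%d of %d censored)\n",
                    object@medianFirstLocalization / 60, object@nCensored,
                    object@nCells))
    }
})
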