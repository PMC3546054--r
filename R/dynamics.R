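#' Centred moving average with truncated boundaries
#'
#' Filters a localization trajectory with a centred window of `window`
#' frames. At the record boundaries the window is truncated to the frames
#' that exist (no padding values are invented), so the output has the same
#' length as the input.
#'
#' @param x numeric series.
#' @param window odd integer window length (>= 1, <= length of `x`).
#' @return numeric series of the same length.
#' @examples
#' movingAverage(c(0, 0, 1, 0, 0), 5)
#' @export
movingAverage <- function(x, window = 5L) {
    window <- as.integer(window)
    if (window < 1L || window %% 2L == 0L) stop("window: must be odd and >= 1")
    if (window > length(x)) stop("window: longer than the series")
    if (window == 1L) return(x)
    as.numeric(zoo::rollapply(zoo::zoo(x), window, mean,
                              partial = TRUE, align = "center"))
}

#' Threshold a filtered trajectory into a binary signal
#'
#' Values strictly above the threshold are nuclear (1); a value equal to
#' the threshold is cytoplasmic. Raising the threshold never adds nuclear
#' frames.
#'
#' @param x numeric (filtered) series.
#' @param threshold localization threshold (default 0.28).
#' @return integer series of 0/1.
#' @examples
#' binarizeLoc(c(0.1, 0.5, 0.29, 0.27, 0.28))
#' @export
binarizeLoc <- function(x, threshold = 0.28) {
    as.integer(x > threshold)
}

#' Remove short runs from a binary state signal
#'
#' Nuclear (1) runs shorter than `minRun` frames are turned cytoplasmic
#' first; then, in the updated signal, cytoplasmic (0) runs shorter than
#' `minRun` are turned nuclear. Runs touching either record boundary are
#' exempt (a trajectory often starts or ends mid-event). The pass pair is
#' iterated to a fixed point, so the result is idempotent and the interior
#' of the record contains no run shorter than `minRun`.
#'
#' @param x binary (0/1) series.
#' @param minRun minimum run length in frames (default 5, ~20 s at 4 s per
#'   frame).
#' @return cleaned integer 0/1 series.
#' @examples
#' cleanRuns(c(rep(0, 6), 1, 1, 1, rep(0, 6)))          # spike removed
#' cleanRuns(c(rep(1, 10), 0, 0, 0, rep(1, 10)))        # gap filled
#' @export
cleanRuns <- function(x, minRun = 5L) {
    minRun <- as.integer(minRun)
    if (minRun < 1L) stop("minRun: must be >= 1")
    s <- as.integer(x)
    repeat {
        s2 <- flipShortRuns(flipShortRuns(s, 1L, minRun), 0L, minRun)
        if (identical(s2, s)) return(s)
        s <- s2
    }
}

# Flip maximal runs of `value` shorter than minRun; boundary runs exempt.
flipShortRuns <- function(s, value, minRun) {
    r <- rle(s)
    n <- length(r$lengths)
    if (n <= 1L) return(s)
    flip <- r$values == value & r$lengths < minRun
    flip[c(1L, n)] <- FALSE
    if (!any(flip)) return(s)
    r$values[flip] <- 1L - value
    inverse.rle(r)
}

#' Detect nuclear-localization states
#'
#' The event-detection pipeline: moving-average filter
#' ([movingAverage()]), strict thresholding ([binarizeLoc()]), then
#' run-length cleanup ([cleanRuns()]). For a [LocTrajectorySet-class] the
#' pipeline is applied to every cell's `loc` series and the result stored
#' as a `state` assay, with the parameters recorded in
#' `metadata(x)$analysisParams`.
#'
#' @param x a numeric localization series or a [LocTrajectorySet-class].
#' @param params an [AnalysisParams-class].
#' @param ... unused.
#' @return for a numeric series, an integer 0/1 state series; for a
#'   trajectory set, the set with a `state` assay added.
#' @examples
#' detectStates(c(rep(0, 10), rep(0.8, 10)), AnalysisParams())
#' @export
setGeneric("detectStates", function(x, params = AnalysisParams(), ...)
    standardGeneric("detectStates"))

#' @rdname detectStates
#' @export
setMethod("detectStates", "numeric", function(x, params = AnalysisParams(), ...) {
    validObject(params)
    if (length(x) < params@window)
        stop("trajectory shorter than the moving-average window")
    cleanRuns(binarizeLoc(movingAverage(x, params@window), params@threshold),
              params@minRun)
})

#' @rdname detectStates
#' @export
setMethod("detectStates", "LocTrajectorySet",
          function(x, params = AnalysisParams(), ...) {
    loc <- locValues(x)
    state <- t(apply(loc, 1, detectStates, params = params))
    SummarizedExperiment::assay(x, "state") <- state
    metadata(x)$analysisParams <- params
    x
})

# maximal runs of a binary series as a data.frame(start, end, value) of
# frame indices
stateRuns <- function(state) {
    r <- rle(as.integer(state))
    end <- cumsum(r$lengths)
    data.frame(start = end - r$lengths + 1L, end = end, value = r$values)
}

#' Classify a single trajectory
#'
#' `permanent` if the final maximal run is nuclear and lasts at least
#' `permanenceTail` seconds (sustained localization to the record end);
#' `only_oscillating` if the cell has nuclear events but no such trailing
#' run; `no_response` if it never localizes.
#'
#' @param state cleaned binary state series.
#' @param times frame times in seconds.
#' @param permanenceTail required duration of the trailing nuclear run
#'   (seconds, default 600).
#' @return one of `"no_response"`, `"only_oscillating"`, `"permanent"`.
#' @export
classifyTrajectory <- function(state, times, permanenceTail = 600) {
    dt <- stats::median(diff(times))
    if (length(state) * dt < permanenceTail)
        stop("record shorter than permanenceTail")
    runs <- stateRuns(state)
    if (!any(runs$value == 1L)) return("no_response")
    last <- runs[nrow(runs), ]
    if (last$value == 1L && (last$end - last$start + 1L) * dt >= permanenceTail)
        "permanent"
    else
        "only_oscillating"
}

#' Per-cell metrics from detected states
#'
#' Computes, within the observation window: whether the cell responded
#' (at least one nuclear run), the time to first nuclear localization
#' (time of the first frame of the first nuclear run; `NA` = censored),
#' the total nuclear time (nuclear frames times the frame interval), the
#' number of nuclear events (maximal runs intersecting the window; an
#' event straddling the window end counts, but only its in-window frames
#' contribute to the total time), and the trajectory classification.
#'
#' @param x a [LocTrajectorySet-class] with a `state` assay (see
#'   [detectStates()]), or a binary state series.
#' @param params an [AnalysisParams-class]; `observationWindow` and
#'   `permanenceTail` are used here.
#' @param times frame times in seconds (series method only).
#' @param cellId label (series method only).
#' @param ... unused.
#' @return data.frame with one row per cell and columns `cell_id`,
#'   `responded`, `first_localization_time`, `total_nuclear_time`,
#'   `n_events`, `classification` (times in seconds).
#' @examples
#' x <- detectStates(simulatePopulation(SimScenario(nCells = 5, seed = 2)))
#' cellMetrics(x)
#' @export
setGeneric("cellMetrics", function(x, params = AnalysisParams(), ...)
    standardGeneric("cellMetrics"))

#' @rdname cellMetrics
#' @export
setMethod("cellMetrics", "numeric",
          function(x, params = AnalysisParams(), times = NULL,
                   cellId = "cell_1", ...) {
    validObject(params)
    state <- as.integer(x)
    if (is.null(times))
        stop("times: frame times are required")
    dt <- stats::median(diff(times))
    inWin <- times < params@observationWindow
    runs <- stateRuns(state)
    ev <- runs[runs$value == 1L & times[runs$start] < params@observationWindow, ,
               drop = FALSE]
    responded <- nrow(ev) > 0L
    firstLoc <- if (responded) times[ev$start[1]] else NA_real_
    totalNuc <- sum(state == 1L & inWin) * dt
    cls <- if (!responded) "no_response"
           else classifyTrajectory(state, times, params@permanenceTail)
    data.frame(cell_id = cellId, responded = responded,
               first_localization_time = firstLoc,
               total_nuclear_time = totalNuc, n_events = nrow(ev),
               classification = cls, stringsAsFactors = FALSE)
})

#' @rdname cellMetrics
#' @export
setMethod("cellMetrics", "LocTrajectorySet",
          function(x, params = NULL, ...) {
    if (is.null(params))
        params <- metadata(x)$analysisParams
    if (is.null(params))
        params <- AnalysisParams()
    st <- stateMatrix(x)
    tm <- frameTimes(x)
    out <- do.call(rbind, lapply(seq_len(nrow(st)), function(i)
        cellMetrics(st[i, ], params = params, times = tm,
                    cellId = rownames(st)[i])))
    rownames(out) <- NULL
    out
})
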