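#' Simulate a ground-truthed population of localization trajectories
#'
#' Draws one of three single-cell response archetypes per cell and builds
#' the corresponding binary ground-truth state over the record, then emits
#' the observed localization value as `baselineLoc`/`nuclearLoc` per state
#' plus independent Gaussian noise:
#' \itemize{
#' \item `no_response`: cytoplasmic throughout;
#' \item `only_oscillating`: a renewal process of nuclear bursts —
#'   exponential inter-burst gaps with rate `burstRate` per minute, burst
#'   lengths uniform on `burstDurationRange`;
#' \item `permanent`: cytoplasmic until a log-normal lag
#'   (`lagMedian`, `lagSdlog`), nuclear from the entry frame to the end.
#' }
#' The same `(scenario, seed)` pair always yields bit-identical output.
#'
#' @param scenario a [SimScenario-class].
#' @return a [LocTrajectorySet-class] with assays `loc` (observed values)
#'   and `truth` (binary ground truth), `rowData` columns `archetype` and
#'   `entryTime` (seconds; `NA` for non-permanent cells), and the scenario
#'   in `metadata(x)$scenario`.
#' @examples
#' x <- simulatePopulation(SimScenario(nCells = 20, seed = 7))
#' table(archetype(x))
#' @export
simulatePopulation <- function(scenario) {
    stopifnot(is(scenario, "SimScenario"))
    validObject(scenario)
    nFrames <- as.integer(floor(scenario@duration / scenario@frameInterval))
    times <- (seq_len(nFrames) - 1) * scenario@frameInterval
    n <- scenario@nCells
    withr::with_seed(scenario@seed, {
        arch <- sample(ARCHETYPES, n, replace = TRUE,
                       prob = scenario@archetypeWeights)
        truth <- matrix(0L, n, nFrames)
        entry <- rep(NA_real_, n)
        for (i in seq_len(n)) {
            if (arch[i] == "permanent") {
                entry[i] <- stats::rlnorm(1, meanlog = log(scenario@lagMedian),
                                          sdlog = scenario@lagSdlog)
                truth[i, times >= entry[i]] <- 1L
            } else if (arch[i] == "only_oscillating") {
                truth[i, ] <- simulateBursts(times, scenario)
            }
        }
        loc <- scenario@baselineLoc +
            (scenario@nuclearLoc - scenario@baselineLoc) * truth
        if (scenario@noiseSd > 0)
            loc <- loc + matrix(stats::rnorm(n * nFrames, sd = scenario@noiseSd),
                                n, nFrames)
    })
    x <- LocTrajectorySet(loc, times = times, truth = truth)
    SummarizedExperiment::rowData(x)$archetype <- arch
    SummarizedExperiment::rowData(x)$entryTime <- entry
    metadata(x)$scenario <- scenario
    x
}

# Binary burst track over `times`: alternating Exp(gap)/Unif(burst) renewal.
simulateBursts <- function(times, scenario) {
    state <- integer(length(times))
    ratePerSec <- scenario@burstRate / 60
    if (ratePerSec <= 0) return(state)
    tEnd <- times[length(times)] + scenario@frameInterval
    t <- 0
    repeat {
        t <- t + stats::rexp(1, rate = ratePerSec)
        if (t >= tEnd) break
        len <- stats::runif(1, scenario@burstDurationRange[1],
                            scenario@burstDurationRange[2])
        state[times >= t & times < t + len] <- 1L
        t <- t + len
    }
    state
}

#' Lay synthetic cells out on a grid
#'
#' Convenience constructor of a non-overlapping [RenderLayout-class]: cells
#' on a square grid, identical radii, nucleus centred in the cell. With the
#' default radii each cell region has 149 pixels and each nucleus 29, so at
#' least 120 cytosolic candidate pixels always remain.
#'
#' @param nCells number of cells.
#' @param cellRadius,nucleusRadius disc radii in pixels.
#' @param spacing centre-to-centre grid spacing (default leaves a 2 px gap).
#' @param background,cytosolIntensity,nuclearGain rendering intensities.
#' @return a validated [RenderLayout-class].
#' @examples
#' autoLayout(9)
#' @export
autoLayout <- function(nCells, cellRadius = 7, nucleusRadius = 3,
                       spacing = 2 * cellRadius + 2,
                       background = 100, cytosolIntensity = 200,
                       nuclearGain = 1.8) {
    perRow <- ceiling(sqrt(nCells))
    ij <- cbind((seq_len(nCells) - 1) %/% perRow, (seq_len(nCells) - 1) %% perRow)
    centers <- cellRadius + 2 + ij * spacing
    sz <- as.integer(max(centers) + cellRadius + 2)
    new("RenderLayout",
        dim = c(sz, sz), centers = centers,
        cellRadius = rep(cellRadius, nCells),
        nucleusRadius = rep(nucleusRadius, nCells),
        nucleusOffset = matrix(0, nCells, 2),
        background = background, cytosolIntensity = cytosolIntensity,
        nuclearGain = nuclearGain)
}

#' Render a simulated population as a fluorescence image stack
#'
#' Draws each frame from the ground-truth states of a simulated population:
#' background everywhere, each cell disc at `cytosolIntensity`, and its
#' nucleus disc multiplied by `nuclearGain` on frames where the cell's true
#' state is nuclear. Optional shot noise replaces every pixel by a Poisson
#' draw with the noise-free value as mean.
#'
#' @param truth a simulated [LocTrajectorySet-class] (carries the `truth`
#'   assay and frame times).
#' @param layout a [RenderLayout-class] with one cell per trajectory.
#' @param noise `"none"` or `"poisson"`.
#' @param seed integer seed for the shot noise (defaults to the scenario's).
#' @return a list with elements `stack` ([ImageStack-class]) and `mask`
#'   (integer label matrix: 0 = background, k = cell k), the mask matching
#'   the drawn cell regions exactly.
#' @examples
#' x <- simulatePopulation(SimScenario(nCells = 4, duration = 40, seed = 1))
#' r <- renderFrames(x, autoLayout(4))
#' r$stack
#' @export
renderFrames <- function(truth, layout, noise = c("none", "poisson"),
                         seed = NULL) {
    noise <- match.arg(noise)
    stopifnot(is(layout, "RenderLayout"))
    validObject(layout)
    tr <- truthStates(truth)
    n <- nrow(tr)
    if (nrow(layout@centers) != n)
        stop("layout and truth disagree on the number of cells")
    if (is.null(seed)) {
        sc <- metadata(truth)$scenario
        seed <- if (!is.null(sc)) sc@seed else 1L
    }
    nr <- layout@dim[1]
    mask <- matrix(0L, nr, layout@dim[2])
    cellIdx <- nucIdx <- vector("list", n)
    for (i in seq_len(n)) {
        cp <- discPixels(layout@centers[i, ], layout@cellRadius[i], layout@dim)
        np <- discPixels(layout@centers[i, ] + layout@nucleusOffset[i, ],
                         layout@nucleusRadius[i], layout@dim)
        cellIdx[[i]] <- pixelIndex(cp, nr)
        nucIdx[[i]] <- pixelIndex(np, nr)
        mask[cellIdx[[i]]] <- i
    }
    base <- matrix(layout@background, nr, layout@dim[2])
    for (i in seq_len(n)) base[cellIdx[[i]]] <- layout@cytosolIntensity
    nucOn <- layout@cytosolIntensity * layout@nuclearGain
    nFrames <- ncol(tr)
    data <- array(0, dim = c(nr, layout@dim[2], nFrames))
    withr::with_seed(as.integer(seed), {
        for (f in seq_len(nFrames)) {
            fr <- base
            on <- which(tr[, f] == 1L)
            if (length(on)) fr[unlist(nucIdx[on])] <- nucOn
            if (noise == "poisson") fr[] <- stats::rpois(length(fr), fr)
            data[, , f] <- fr
        }
    })
    list(stack = ImageStack(data, frameTimes(truth)), mask = mask)
}

#' Simulate reporter-expression time courses
#'
#' Emulates tracking of a slow transcriptional reporter (e.g. Cmk2-GFP)
#' after a stress pulse: cells are illuminated, then whole-cell
#' background-subtracted fluorescence is sampled sparsely (default every
#' 10 min for 5 h). Induced cells rise monotonically in expectation after a
#' per-cell log-normal lag, saturating exponentially; uninduced cells stay
#' flat in expectation.
#'
#' @param nCells number of cells.
#' @param induced logical; `FALSE` gives flat baseline traces.
#' @param duration total tracked time in seconds.
#' @param samplingInterval seconds between samples (default 600).
#' @param baseline counts at time zero.
#' @param amplitude mean per-cell asymptotic increase (counts).
#' @param tau rise time constant in seconds.
#' @param lagMedian,lagSdlog log-normal per-cell induction lag (seconds).
#' @param noiseSd sd of additive measurement noise (counts).
#' @param seed integer seed.
#' @return numeric matrix, cells x samples, with sampling times (seconds) as
#'   an attribute `"times"` and in `colnames`.
#' @examples
#' tr <- simulateExpression(10, induced = TRUE, seed = 3)
#' round(colMeans(tr)[1:5], 1)
#' @export
simulateExpression <- function(nCells, induced = TRUE, duration = 18000,
                               samplingInterval = 600, baseline = 100,
                               amplitude = 30, tau = 3600,
                               lagMedian = 1800, lagSdlog = 0.4,
                               noiseSd = 1, seed = 1L) {
    if (duration < samplingInterval)
        stop("duration: must cover at least one sampling interval")
    if (nCells < 1) stop("nCells: must be >= 1")
    times <- seq(0, duration, by = samplingInterval)
    withr::with_seed(as.integer(seed), {
        if (induced) {
            lag <- stats::rlnorm(nCells, log(lagMedian), lagSdlog)
            amp <- amplitude * stats::rgamma(nCells, shape = 10, scale = 0.1)
            resp <- sapply(times, function(t)
                baseline + amp * pmax(0, 1 - exp(-(t - lag) / tau)) * (t > lag))
        } else {
            resp <- matrix(baseline, nCells, length(times))
        }
        if (noiseSd > 0)
            resp <- resp + matrix(stats::rnorm(nCells * length(times), sd = noiseSd),
                                  nCells, length(times))
    })
    resp <- matrix(resp, nrow = nCells)
    dimnames(resp) <- list(sprintf("cell_%d", seq_len(nCells)), times)
    attr(resp, "times") <- times
    resp
}
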