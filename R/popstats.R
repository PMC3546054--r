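#' Instantaneous fraction of localized cells
#'
#' At each time point, the fraction of cells whose cleaned state is
#' nuclear — equivalently the mean of the per-cell indicator series. The
#' fraction is instantaneous, not cumulative: transient population peaks
#' (e.g. an oscillatory factor that responds and then withdraws) are
#' preserved. `smoothWidth > 1` adds a `fraction_display` column smoothed
#' with a centred averaging filter for plotting only; it never feeds
#' downstream statistics.
#'
#' @param x a [LocTrajectorySet-class] with a `state` assay, or a binary
#'   matrix (cells x frames).
#' @param times frame times (matrix input only).
#' @param smoothWidth odd width of the display smoother (default 1 = off).
#' @return data.frame with columns `time`, `fraction` and, if requested,
#'   `fraction_display`.
#' @examples
#' x <- detectStates(simulatePopulation(SimScenario(nCells = 50, seed = 4)))
#' head(fractionLocalized(x))
#' @export
fractionLocalized <- function(x, times = NULL, smoothWidth = 1L) {
    if (is(x, "LocTrajectorySet")) {
        st <- stateMatrix(x)
        times <- frameTimes(x)
    } else {
        st <- as.matrix(x)
        if (is.null(times)) times <- seq_len(ncol(st))
    }
    if (nrow(st) == 0L) stop("empty population")
    out <- data.frame(time = times, fraction = colMeans(st))
    if (smoothWidth > 1L)
        out$fraction_display <- movingAverage(out$fraction, smoothWidth)
    out
}

#' Heatmap-ready localization matrix
#'
#' The cells x frames matrix of localization values with rows ordered by
#' time to first nuclear localization (earliest entrants first, censored
#' cells last, original order within ties). Detection is run with `params`
#' if the set has no `state` assay yet.
#'
#' @param x a [LocTrajectorySet-class].
#' @param params an [AnalysisParams-class] used if states are missing.
#' @return the reordered `loc` matrix with the ordering permutation as
#'   attribute `"ordering"` and the per-cell first-localization times
#'   (seconds, `NA` = censored) as attribute `"firstLocalization"`.
#' @export
localizationMatrix <- function(x, params = AnalysisParams()) {
    stopifnot(is(x, "LocTrajectorySet"))
    if (nrow(x) == 0L) stop("empty population")
    if (!"state" %in% SummarizedExperiment::assayNames(x))
        x <- detectStates(x, params)
    m <- cellMetrics(x)
    ord <- order(m$first_localization_time, na.last = TRUE)
    out <- locValues(x)[ord, , drop = FALSE]
    attr(out, "ordering") <- ord
    attr(out, "firstLocalization") <- m$first_localization_time[ord]
    out
}

# cache of exact null U distributions, keyed by "n1,n2"
.uNullCache <- new.env(parent = emptyenv())

exactUNull <- function(n1, n2) {
    key <- paste(n1, n2)
    if (!is.null(.uNullCache[[key]])) return(.uNullCache[[key]])
    # U for every equally likely assignment of ranks 1..n1+n2 to sample 1
    u <- utils::combn(n1 + n2, n1, FUN = sum) - n1 * (n1 + 1) / 2
    .uNullCache[[key]] <- u
    u
}

#' Mann-Whitney U test
#'
#' Rank-based nonparametric comparison of two samples, used to assess
#' whether the first sample takes larger values than the second
#' (`alternative = "greater"`, the default). With both groups of size at
#' most 8 and no ties, the null distribution of U is obtained exactly by
#' enumerating all assignments of ranks to the first sample; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"greater"` (x larger than y) or `"two.sided"`.
#' @param exactMax largest per-group size for exact enumeration (default 8,
#'   keeping at most `choose(16, 8) = 12870` arrangements).
#' @return a [UTestResult-class].
#' @examples
#' mannWhitney(c(3, 4), c(1, 2))           # p = 1/6 by enumeration
#' @export
mannWhitney <- function(x, y, alternative = c("greater", "two.sided"),
                        exactMax = 8L) {
    alternative <- match.arg(alternative)
    if (!length(x) || !length(y)) stop("samples must be non-empty")
    n1 <- length(x); n2 <- length(y)
    rk <- rank(c(x, y))
    U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- anyDuplicated(c(x, y)) > 0L
    if (n1 <= exactMax && n2 <= exactMax && !ties) {
        null <- exactUNull(n1, n2)
        pG <- mean(null >= U)
        pL <- mean(null <= U)
        p <- if (alternative == "greater") pG else min(1, 2 * min(pG, pL))
        method <- "exact"
    } else {
        p <- uNormalApprox(U, rk, n1, n2, alternative)
        method <- "normal_approx"
    }
    new("UTestResult", statistic = U, n1 = as.integer(n1), n2 = as.integer(n2),
        pValue = max(p, .Machine$double.xmin), alternative = alternative,
        method = method)
}

# normal approximation with tie and continuity corrections
uNormalApprox <- function(U, rk, n1, n2, alternative) {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie <- table(rk)
    sigma2 <- n1 * n2 / 12 * (N + 1 - sum(tie^3 - tie) / (N * (N - 1)))
    if (sigma2 <= 0) return(1)
    sigma <- sqrt(sigma2)
    if (alternative == "greater") {
        stats::pnorm((U - mu - 0.5) / sigma, lower.tail = FALSE)
    } else {
        z <- (abs(U - mu) - 0.5) / sigma
        min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
}

#' Summarize a condition at the population level
#'
#' Aggregates per-cell metrics into the population outputs: the
#' instantaneous fraction-localized curve (if tracks are supplied), the
#' median total nuclear time over all cells, the median time to first
#' nuclear localization over responders only (censored cells are counted
#' and reported, never imputed — at weak stimuli few cells respond and a
#' responders-only median can look deceptively fast), and the tally of
#' trajectory classes.
#'
#' @param metrics per-cell metric table from [cellMetrics()].
#' @param tracks optional [LocTrajectorySet-class] with a `state` assay,
#'   used for the fraction-localized curve.
#' @param label condition label.
#' @return a [PopulationSummary-class].
#' @examples
#' x <- detectStates(simulatePopulation(SimScenario(nCells = 40, seed = 5)))
#' summarizeCondition(cellMetrics(x), x, label = "demo")
#' @export
summarizeCondition <- function(metrics, tracks = NULL, label = "") {
    if (!nrow(metrics)) stop("empty metrics table")
    frac <- if (!is.null(tracks)) fractionLocalized(tracks)
            else data.frame(time = numeric(0), fraction = numeric(0))
    cls <- table(factor(metrics$classification, levels = ARCHETYPES))
    responders <- metrics$first_localization_time[metrics$responded]
    new("PopulationSummary",
        label = label, nCells = nrow(metrics),
        fractionLocalized = frac, metrics = metrics,
        classCounts = stats::setNames(as.integer(cls), names(cls)),
        medianTotalNuclearTime = stats::median(metrics$total_nuclear_time),
        medianFirstLocalization =
            if (length(responders)) stats::median(responders) else NA_real_,
        nCensored = sum(!metrics$responded))
}
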