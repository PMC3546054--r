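# Shared fixture builders and independent oracles.

# A single-archetype scenario with noise off unless asked for.
pureScenario <- function(arch, nCells = 20, noiseSd = 0, seed = 1L, ...) {
    w <- c(no_response = 0, only_oscillating = 0, permanent = 0)
    w[arch] <- 1
    SimScenario(nCells = nCells, archetypeWeights = w, noiseSd = noiseSd,
                seed = seed, ...)
}

# Brute-force oracle: all pixels of `region` within Euclidean `radius` of
# the brightest (row-major first) pixel, by direct enumeration.
bruteNucleus <- function(smoothed, region, radius = 3) {
    region <- region[order(region[, 1], region[, 2]), , drop = FALSE]
    vals <- apply(region, 1, function(p) smoothed[p[1], p[2]])
    b <- region[which.max(vals), ]
    keep <- apply(region, 1, function(p)
        (p[1] - b[1])^2 + (p[2] - b[2])^2 <= radius^2)
    region[keep, , drop = FALSE]
}

# Brute-force oracle: top-k remaining pixels by a full sort with
# row-major tie-break.
bruteCytosol <- function(smoothed, region, nucleus, k = 90) {
    region <- region[order(region[, 1], region[, 2]), , drop = FALSE]
    key <- region[, 1] * 1e6 + region[, 2]
    nkey <- nucleus[, 1] * 1e6 + nucleus[, 2]
    region <- region[!(key %in% nkey), , drop = FALSE]
    vals <- apply(region, 1, function(p) smoothed[p[1], p[2]])
    region[order(-vals)[seq_len(min(k, nrow(region)))], , drop = FALSE]
}

# Random connected-ish blob region: disc plus jitter, clipped to bounds.
randomRegion <- function(dim, minPixels = 100) {
    repeat {
        ctr <- c(runif(1, 8, dim[1] - 8), runif(1, 8, dim[2] - 8))
        rad <- runif(1, 5.8, 8)
        px <- shuttleQuant:::discPixels(ctr, rad, dim)
        if (nrow(px) >= minPixels) return(px)
    }
}

# Row-major canonical form: pixel selections are sets, so comparisons
# against the oracles are order-insensitive.
sortPx <- function(px) unname(px[order(px[, 1], px[, 2]), , drop = FALSE])

# All binary vectors of length n as rows.
allBinaryStrings <- function(n) {
    m <- as.matrix(expand.grid(rep(list(0:1), n)))
    dimnames(m) <- NULL
    m
}

# Reference cleanup semantics stated directly: interior runs shorter than
# minRun must not survive, and re-application must not change the result.
hasShortInteriorRun <- function(s, minRun) {
    r <- rle(as.integer(s))
    n <- length(r$lengths)
    if (n <= 2L) return(FALSE)
    any(r$lengths[-c(1L, n)] < minRun)
}
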