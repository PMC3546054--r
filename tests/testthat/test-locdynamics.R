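test_that("moving average: centred, truncated boundaries, identity cases", {
    expect_equal(movingAverage(rep(0.3, 10), 5), rep(0.3, 10))
    x <- c(0.4, 0.1, 0.9, 0.2, 0.5)
    expect_equal(movingAverage(x, 1), x)
    out <- movingAverage(c(0, 0, 1, 0, 0), 5)
    expect_equal(out[3], 0.2)
    expect_equal(out, c(1/3, 1/4, 1/5, 1/4, 1/3))   # truncated windows
    expect_error(movingAverage(x, 4), "odd")
    expect_error(movingAverage(x, 7), "longer")
})

test_that("binarization is strictly above the threshold and monotone", {
    expect_equal(binarizeLoc(rep(0, 5)), rep(0L, 5))
    expect_equal(binarizeLoc(0.28), 0L)               # boundary rule
    expect_equal(binarizeLoc(c(0.1, 0.5, 0.29, 0.27)), c(0L, 1L, 1L, 0L))
    set.seed(3)
    x <- runif(200, 0, 0.6)
    lo <- binarizeLoc(x, 0.2)
    hi <- binarizeLoc(x, 0.4)
    expect_true(all(hi <= lo))    # raising the threshold never adds frames
})

test_that("run cleanup removes spikes, fills gaps, exempts boundaries", {
    expect_equal(cleanRuns(rep(0L, 20), 5), rep(0L, 20))
    # 3-frame spike inside long zeros: removed
    spike <- c(rep(0L, 10), 1L, 1L, 1L, rep(0L, 10))
    expect_equal(cleanRuns(spike, 5), rep(0L, 23))
    # two 10-frame events separated by a 3-frame gap: merged to one 23-run
    runs <- c(rep(1L, 10), rep(0L, 3), rep(1L, 10))
    expect_equal(cleanRuns(runs, 5), rep(1L, 23))
    # boundary runs are exempt even when short
    tail2 <- c(rep(0L, 10), 1L, 1L)
    expect_equal(cleanRuns(tail2, 5), tail2)
    head3 <- c(1L, 1L, 1L, rep(0L, 10))
    expect_equal(cleanRuns(head3, 5), head3)
    # removal precedes gap filling: a short event between long zeros
    # disappears instead of seeding a filled gap
    mix <- c(rep(0L, 6), 1L, 1L, rep(0L, 6), rep(1L, 8))
    expect_equal(cleanRuns(mix, 5), c(rep(0L, 14), rep(1L, 8)))
})

test_that("cleanup is idempotent and leaves no short interior runs", {
    set.seed(41)
    for (rep in 1:300) {
        n <- sample(5:60, 1)
        s <- as.integer(runif(n) < runif(1))
        for (minRun in c(2L, 5L)) {
            cl <- cleanRuns(s, minRun)
            expect_identical(cleanRuns(cl, minRun), cl)
            expect_false(hasShortInteriorRun(cl, minRun))
        }
    }
})

test_that("state detection finds a clean step with small onset delay", {
    params <- AnalysisParams()
    # noise-free step 0 -> 0.8 at frame 40, held to the end
    x <- c(rep(0, 39), rep(0.8, 41))
    st <- detectStates(x, params)
    runs <- rle(st)
    expect_equal(sum(runs$values == 1), 1)            # exactly one event
    onset <- which(st == 1)[1]
    expect_lte(abs(onset - 40), 2)
    # constant sub-threshold trace: no events
    expect_equal(detectStates(rep(0.1, 50), params), rep(0L, 50))
    expect_error(detectStates(c(0.1, 0.2), params), "shorter")
})

test_that("detection recovers ground truth on noisy synthetic populations", {
    x <- simulatePopulation(SimScenario(nCells = 60, noiseSd = 0.05, seed = 21L))
    xs <- detectStates(x)
    acc <- mean(stateMatrix(xs) == truthStates(x))
    expect_gte(acc, 0.95)
    prov <- S4Vectors::metadata(xs)$analysisParams
    expect_s4_class(prov, "AnalysisParams")
    expect_equal(prov@threshold, 0.28)
})

test_that("per-cell metrics: censoring, times and event counts", {
    params <- AnalysisParams()
    times <- (0:899) * 4
    # never nuclear: censored, zero total time, class no_response
    m0 <- cellMetrics(rep(0L, 900), params, times = times)
    expect_false(m0$responded)
    expect_true(is.na(m0$first_localization_time))
    expect_equal(m0$total_nuclear_time, 0)
    expect_equal(m0$n_events, 0L)
    expect_equal(m0$classification, "no_response")
    # first nuclear frame at the 150-frame mark (4 s frames): 600 s
    s <- rep(0L, 900); s[151:300] <- 1L
    m1 <- cellMetrics(s, params, times = times)
    expect_equal(m1$first_localization_time, 600)
    expect_equal(m1$total_nuclear_time, 150 * 4)
    expect_equal(m1$n_events, 1L)
    # nuclear for 300 frames at 4 s: total 1200 s
    s2 <- rep(0L, 900); s2[101:400] <- 1L
    expect_equal(cellMetrics(s2, params, times = times)$total_nuclear_time, 1200)
    # an event straddling the observation window end counts once, but only
    # its in-window frames contribute to the total time
    long <- rep(0L, 1000); long[801:1000] <- 1L
    times2 <- (0:999) * 4
    m2 <- cellMetrics(long, params, times = times2)
    expect_equal(m2$n_events, 1L)
    expect_equal(m2$total_nuclear_time, (900 - 800) * 4)
})

test_that("trajectory classification follows the trailing-run rule", {
    times <- (0:899) * 4
    expect_equal(classifyTrajectory(rep(0L, 900), times), "no_response")
    # events but the final 10 min cytoplasmic: only oscillating
    osc <- rep(0L, 900); osc[101:200] <- 1L
    expect_equal(classifyTrajectory(osc, times), "only_oscillating")
    # nuclear from minute 30 to the record end: permanent
    perm <- rep(0L, 900); perm[451:900] <- 1L
    expect_equal(classifyTrajectory(perm, times), "permanent")
    # trailing nuclear run shorter than the tail: still oscillating
    short <- rep(0L, 900); short[851:900] <- 1L
    expect_equal(classifyTrajectory(short, times), "only_oscillating")
    expect_error(classifyTrajectory(rep(0L, 10), (0:9) * 4), "shorter")
})
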