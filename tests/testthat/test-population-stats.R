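test_that("fraction localized is the instantaneous mean of cell indicators", {
    st <- rbind(c(1L, 1L, 0L), c(1L, 0L, 0L))
    f <- fractionLocalized(st, times = c(0, 4, 8))
    expect_equal(f$fraction, c(1, 0.5, 0))
    # 2 of 8 nuclear at a time point
    st8 <- matrix(0L, 8, 1); st8[1:2, 1] <- 1L
    expect_equal(fractionLocalized(st8, times = 0)$fraction, 0.25)
    # linearity: population fraction equals the mean of per-cell series
    x <- detectStates(simulatePopulation(SimScenario(nCells = 40, seed = 14L)))
    f2 <- fractionLocalized(x)
    expect_equal(f2$fraction, colMeans(stateMatrix(x)))
    # display smoothing is an extra column, never replacing the fraction
    f3 <- fractionLocalized(x, smoothWidth = 5)
    expect_equal(f3$fraction, f2$fraction)
    expect_equal(f3$fraction_display, movingAverage(f2$fraction, 5))
    expect_error(fractionLocalized(matrix(0L, 0, 3), times = c(0, 4, 8)),
                 "empty")
})

test_that("a permanent-only noise-free population has a non-decreasing curve", {
    x <- detectStates(simulatePopulation(
        pureScenario("permanent", nCells = 50, seed = 8L)))
    f <- fractionLocalized(x)
    expect_true(all(diff(f$fraction) >= 0))
})

test_that("localization matrix orders cells by entry time, censored last", {
    loc <- rbind(c(rep(0, 300), rep(0.8, 600)),   # enters at 20 min
                 c(rep(0, 150), rep(0.8, 750)),   # enters at 10 min
                 rep(0, 900))                     # never
    x <- LocTrajectorySet(loc, times = (0:899) * 4,
                          cellIds = c("late", "early", "none"))
    m <- localizationMatrix(x)
    expect_equal(rownames(m), c("early", "late", "none"))
    expect_equal(attr(m, "ordering"), c(2L, 1L, 3L))
    expect_true(is.na(attr(m, "firstLocalization")[3]))
    # single flat trajectory: one constant row
    x1 <- LocTrajectorySet(matrix(0.1, 1, 20))
    expect_equal(unname(localizationMatrix(x1)[1, ]), rep(0.1, 20))
})

test_that("Mann-Whitney exact p-values match direct enumeration", {
    r <- mannWhitney(c(3, 4), c(1, 2))           # all 6 orderings, extreme one
    expect_equal(r@pValue, 1/6)
    expect_equal(r@method, "exact")
    expect_equal(r@statistic, 4)
    r2 <- mannWhitney(2, 1)                      # 2 equally likely orderings
    expect_equal(r2@pValue, 0.5)
    # identical samples, large n, two-sided: no shift detectable
    set.seed(5)
    z <- rnorm(40)
    r3 <- mannWhitney(z, z + rnorm(40, sd = 1e-8), alternative = "two.sided")
    expect_gte(r3@pValue, 0.9)
    expect_equal(r3@method, "normal_approx")
    expect_error(mannWhitney(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney agrees with the reference implementation", {
    set.seed(99)
    for (rep in 1:20) {
        x <- sample(1000, sample(3:8, 1))        # distinct -> tie-free
        y <- sample(2000:3000, sample(3:8, 1))
        mine <- mannWhitney(x, y)
        ref <- wilcox.test(x, y, alternative = "greater", exact = TRUE)
        expect_equal(mine@pValue, unname(ref$p.value), tolerance = 1e-12)
        expect_equal(mine@statistic, unname(ref$statistic))
    }
    # approximation branch (ties force it) against the corrected reference
    for (rep in 1:20) {
        x <- sample(1:10, 15, replace = TRUE)
        y <- sample(3:12, 18, replace = TRUE)
        mine <- mannWhitney(x, y, alternative = "two.sided")
        ref <- suppressWarnings(
            wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                        correct = TRUE))
        expect_equal(mine@method, "normal_approx")
        expect_equal(mine@pValue, unname(ref$p.value), tolerance = 1e-12)
    }
})

test_that("condition summary reports responder medians and class tallies", {
    mk <- function(first, total, cls)
        data.frame(cell_id = sprintf("c%d", seq_along(first)),
                   responded = !is.na(first),
                   first_localization_time = first,
                   total_nuclear_time = total,
                   n_events = as.integer(!is.na(first)),
                   classification = cls)
    m <- mk(c(5, 7, 9, NA) * 60, c(10, 20, 30, 0) * 60,
            c("only_oscillating", "only_oscillating", "permanent",
              "no_response"))
    s <- summarizeCondition(m, label = "demo")
    expect_equal(s@medianFirstLocalization, 7 * 60)   # responders only
    expect_equal(s@nCensored, 1L)
    expect_equal(sum(s@classCounts), 4L)
    expect_equal(s@classCounts[["permanent"]], 1L)
    # no responders at all: median censored, reported as NA
    s0 <- summarizeCondition(mk(c(NA, NA), c(0, 0),
                                c("no_response", "no_response")))
    expect_true(is.na(s0@medianFirstLocalization))
    expect_equal(s0@nCensored, 2L)
    # permutation invariance in cell order
    perm <- m[c(3, 1, 4, 2), ]
    sp <- summarizeCondition(perm, label = "demo")
    expect_equal(sp@medianFirstLocalization, s@medianFirstLocalization)
    expect_equal(sp@medianTotalNuclearTime, s@medianTotalNuclearTime)
    expect_equal(sp@classCounts, s@classCounts)
})
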