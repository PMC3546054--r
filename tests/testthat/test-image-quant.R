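test_that("Gaussian smoothing preserves constants and mass, peaks at an impulse", {
    const <- matrix(7, 15, 15)
    expect_equal(smoothFrame(const, 2), const, tolerance = 1e-12)
    imp <- matrix(0, 21, 21)
    imp[11, 11] <- 50
    s <- smoothFrame(imp, 1)
    expect_equal(which.max(s), which.max(imp))
    expect_lt(abs(sum(s) - sum(imp)) / sum(imp), 0.005)
    expect_error(smoothFrame(const, 0), "sigma")
})

test_that("nucleus is the 29-pixel disc around the brightest smoothed pixel", {
    # 11x11 all-interior cell, one hot pixel: enumeration gives 29 pixels
    img <- matrix(10, 15, 15)
    img[8, 8] <- 100
    region <- as.matrix(expand.grid(row = 3:13, col = 3:13))[, c("row", "col")]
    nuc <- defineNucleus(img, region, radius = 3)
    expect_identical(nrow(nuc), 29L)
    off <- sweep(nuc, 2, c(8, 8))
    expect_true(all(rowSums(off^2) <= 9))
    # brute-force enumeration agrees
    expect_equal(unname(nuc), unname(bruteNucleus(img, region, 3)))

    # bright pixel at the region edge: disc clipped to the region
    img2 <- matrix(10, 15, 15)
    img2[3, 3] <- 100
    nuc2 <- defineNucleus(img2, region, radius = 3)
    expect_lt(nrow(nuc2), 29L)
    expect_true(all(nuc2[, 1] >= 3 & nuc2[, 2] >= 3))

    # uniform region: tie broken to the first pixel in row-major order
    img3 <- matrix(10, 15, 15)
    nuc3 <- defineNucleus(img3, region, radius = 3)
    expect_equal(unname(nuc3[1, ]), c(3, 3))
    expect_true(all((nuc3[, 1] - 3)^2 + (nuc3[, 2] - 3)^2 <= 9))

    expect_error(defineNucleus(img, region[0, , drop = FALSE]), "non-empty")
})

test_that("cytosol is the top-k of the remaining pixels, with fallback", {
    set.seed(71)
    img <- matrix(runif(900, 10, 20), 30, 30)
    img[8, 8] <- 100   # nucleus lands interior, full 29-pixel disc
    # region of exactly 119 pixels: 29-px nucleus leaves exactly 90
    region <- as.matrix(expand.grid(row = 3:13, col = 3:13))[, c("row", "col")]
    region <- region[-c(1, 121), ]
    nuc <- defineNucleus(img, region, 3)
    expect_identical(nrow(nuc), 29L)
    cyt <- defineCytosol(img, region, nuc, k = 90)
    expect_identical(nrow(cyt), 90L)
    # fewer than k remaining: all returned, with a warning
    small <- region[1:60, ]
    nucS <- defineNucleus(img, small, 3)
    expect_warning(cytS <- defineCytosol(img, small, nucS, k = 90),
                   "cytosolic pixels")
    expect_identical(nrow(cytS), 60L - nrow(nucS))
    expect_error(defineCytosol(img, nucS, nucS, k = 90), "no pixels remain")

    # synthetic gradient: selection equals a brute-force sort
    grad <- outer(1:30, 1:30, function(r, c) r + 0.01 * c)
    cytG <- defineCytosol(grad, region, nuc, k = 90)
    expect_equal(sortPx(cytG), sortPx(bruteCytosol(grad, region, nuc, 90)))
})

test_that("nucleus and cytosol are disjoint subsets of the cell region", {
    set.seed(12)
    for (rep in 1:10) {
        img <- matrix(runif(1600, 5, 50), 40, 40)
        region <- randomRegion(c(40, 40))
        nuc <- defineNucleus(img, region, 3)
        cyt <- suppressWarnings(defineCytosol(img, region, nuc, 90))
        keyR <- region[, 1] * 1000 + region[, 2]
        keyN <- nuc[, 1] * 1000 + nuc[, 2]
        keyC <- cyt[, 1] * 1000 + cyt[, 2]
        expect_true(all(keyN %in% keyR))
        expect_true(all(keyC %in% keyR))
        expect_length(intersect(keyN, keyC), 0)
    }
})

test_that("extracted localization value is the median ratio minus one", {
    # uniform cell: loc is exactly 0 in every frame
    x <- simulatePopulation(pureScenario("no_response", nCells = 1,
                                         duration = 20))
    r <- renderFrames(x, autoLayout(1))
    tr <- extractTrajectory(r$stack, which(r$mask == 1, arr.ind = TRUE))
    expect_equal(tr$loc, rep(0, 5), tolerance = 1e-12)

    # nucleus drawn at 1.5x cytosol: loc = 0.5 exactly (noise-free)
    x2 <- simulatePopulation(pureScenario("permanent", nCells = 1,
                                          duration = 20, lagMedian = 1e-6,
                                          lagSdlog = 0))
    expect_true(all(truthStates(x2)[, -1] == 1L))
    lay <- autoLayout(1, nuclearGain = 1.5)
    r2 <- renderFrames(x2, lay)
    tr2 <- extractTrajectory(r2$stack, which(r2$mask == 1, arr.ind = TRUE))
    expect_equal(tr2$loc, 0.5 * as.numeric(truthStates(x2)[1, ]),
                 tolerance = 1e-9)

    # global rescaling leaves the trajectory unchanged
    scaled <- ImageStack(r2$stack@data * 10, r2$stack@times)
    tr3 <- extractTrajectory(scaled, which(r2$mask == 1, arr.ind = TRUE))
    expect_equal(tr3$loc, tr2$loc, tolerance = 1e-12)
})

test_that("noise-free extraction equals the analytic ratio of drawn intensities", {
    sc <- pureScenario("permanent", nCells = 9, duration = 60,
                       lagMedian = 20, lagSdlog = 0.4, seed = 9L)
    x <- simulatePopulation(sc)
    lay <- autoLayout(9, nuclearGain = 1.8)
    r <- renderFrames(x, lay)
    tr <- extractTrajectories(r$stack, r$mask)
    analytic <- 0.8 * truthStates(x)      # gain 1.8 -> ratio - 1 = 0.8
    expect_lt(max(abs(locValues(tr) - analytic)), 1e-9)
    # and within 0.05 of the nominal nuclear level when localized
    expect_true(all(abs(locValues(tr)[truthStates(x) == 1] - 0.8) < 0.05))
})

test_that("renderer rejects inconsistent layouts", {
    x <- simulatePopulation(pureScenario("no_response", nCells = 2,
                                         duration = 20))
    lay <- autoLayout(2)
    lay@centers[2, ] <- lay@centers[1, ] + c(0, 3)   # overlap
    expect_error(renderFrames(x, lay), "overlap")
    lay2 <- autoLayout(2)
    lay2@nucleusOffset[1, ] <- c(6, 0)               # nucleus pokes out
    expect_error(renderFrames(x, lay2), "inside its cell")
    expect_error(renderFrames(x, autoLayout(3)), "number of cells")
})

test_that("expression response is the background-subtracted mean over cells", {
    # constructed frame: two cells with means 110 and 120 over background 100
    mask <- matrix(0L, 30, 30)
    mask[5:10, 5:10] <- 1L
    mask[20:25, 20:25] <- 2L
    fr <- matrix(100, 30, 30)
    fr[mask == 1L] <- 110
    fr[mask == 2L] <- 120
    stack <- ImageStack(array(rep(fr, 3), dim = c(30, 30, 3)), times = c(0, 1, 2))
    out <- expressionResponse(stack, mask, backgroundBox = c(1, 4, 1, 4))
    expect_equal(out$response, rep(15, 3))
    # all cells equal to background: response 0
    stack0 <- ImageStack(array(100, dim = c(30, 30, 3)), times = c(0, 1, 2))
    out0 <- expressionResponse(stack0, mask, c(1, 4, 1, 4))
    expect_equal(out0$response, rep(0, 3))
    # moving the box within the uniform background changes nothing
    out2 <- expressionResponse(stack, mask, c(26, 29, 1, 6))
    expect_equal(out2$response, out$response)
    # overlapping box rejected
    expect_error(expressionResponse(stack, mask, c(5, 10, 5, 10)), "overlaps")
})
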