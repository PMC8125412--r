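test_that("normalization divides by frame size and keeps off-screen samples", {
    gd <- GazeDataset(matrix(c(960, 0, -10), 1, 3),
                      matrix(c(540, 0, 540), 1, 3),
                      width = 1920, height = 1080)
    nd <- suppressMessages(normalizeGaze(gd))
    expect_equal(as.vector(nd@x), c(0.5, 0, -10 / 1920))
    expect_equal(as.vector(nd@y), c(0.5, 0, 0.5))
    expect_true(isNormalized(nd))
    expect_identical(offScreenCount(nd), 1L)
    filtered <- filterOffScreen(nd)
    expect_true(is.na(filtered@x[1, 3]))
    expect_error(normalizeGaze(nd), "already normalized")
    bad <- GazeDataset(matrix(1), matrix(1), width = 1, height = 1)
    bad@W <- -1
    expect_error(normalizeGaze(bad), "dimensions")
})

test_that("frame aggregation averages samples within half-open intervals", {
    raw <- data.frame(observer = 1, time = c(0.00, 0.02),
                      x = c(0.1, 0.3), y = c(0.1, 0.3))
    gd <- aggregateToFrames(raw, frameRate = 25, width = 1, height = 1)
    expect_equal(as.vector(gd@x), 0.2)
    expect_equal(as.vector(gd@y), 0.2)

    # 500 Hz tracker, 25 fps: 20 samples land in each frame
    tm <- seq(0, by = 1 / 500, length.out = 40)
    raw <- data.frame(observer = 1, time = tm, x = tm, y = 0.5)
    gd <- aggregateToFrames(raw, frameRate = 25, width = 1, height = 1,
                            samplingRate = 500)
    expect_identical(nFrames(gd), 2L)
    expect_equal(gd@x[1, 1], mean(tm[1:20]))
    expect_equal(gd@x[1, 2], mean(tm[21:40]))

    # a blink frame stays missing and is excluded from point bags
    raw <- data.frame(observer = c(1, 1), time = c(0.00, 0.08),
                      x = c(0.1, NA), y = c(0.1, NA))
    gd <- aggregateToFrames(raw, frameRate = 25, width = 1, height = 1)
    expect_true(is.na(gd@x[1, 3]))
    nd <- GazeDataset(gd@x, gd@y, 1, 1, normalized = TRUE)
    expect_identical(nPoints(collectWindowPoints(nd, 3, 0L)), 0L)

    expect_warning(
        aggregateToFrames(raw[0, ], frameRate = 25, width = 1, height = 1),
        "empty")
    expect_error(aggregateToFrames(raw, frameRate = 25, width = 1,
                                   height = 1, samplingRate = 10),
                 "samplingRate")
})

test_that("window pooling clips at video boundaries", {
    set.seed(1)
    gd <- randomGazeDataset(58, 30, missingFrac = 0)
    expect_identical(nPoints(collectWindowPoints(gd, 15, 5L)), 58L * 11L)
    expect_identical(nPoints(collectWindowPoints(gd, 1, 5L)), 58L * 6L)
    expect_identical(nPoints(collectWindowPoints(gd, 10, 0L)), 58L)
    expect_error(collectWindowPoints(gd, 0, 5L), "outside")
    expect_error(collectWindowPoints(gd, 31, 5L), "outside")
})

test_that("pair consistency counts close pairs among unordered pairs", {
    expect_equal(pairConsistency(rbind(c(0, 0), c(0.05, 0), c(0.3, 0)), 0.1),
                 1 / 3)
    expect_equal(pairConsistency(matrix(0.42, 5, 2), 0.1), 1)
    expect_equal(pairConsistency(matrix(0.5, 1, 2), 0.1), 0)
    expect_equal(pairConsistency(matrix(numeric(0), 0, 2), 0.1), 0)
    # the inequality is strict: coincident-distance pairs at exactly thetaS
    expect_equal(pairConsistency(rbind(c(0, 0), c(0.1, 0)), 0.1), 0)
})

test_that("perfectly consistent gaze scores 1 everywhere", {
    sc <- Scenario(N = 10, T = 30, attractor = c(0.4, 0.6), alpha = 1,
                   clusterSd = 0, seed = 2)
    expect_true(all(scores(temporalSalience(generateGaze(sc))) == 1))
})

test_that("scores stay in [0,1] and ignore observer identity", {
    set.seed(7)
    for (rep in 1:5) {
        gd <- randomGazeDataset(sample(2:6, 1), sample(5:15, 1))
        p <- GlimpseParams(thetaS = runif(1, 0.05, 0.3),
                           thetaT = sample(0:3, 1))
        s <- scores(suppressWarnings(temporalSalience(gd, p)))
        expect_true(all(s >= 0 & s <= 1))
        perm <- sample(nObservers(gd))
        expect_equal(scores(suppressWarnings(temporalSalience(gd[perm, ], p))),
                     s)
    }
})

test_that("scores are pointwise non-decreasing in the spatial scale", {
    set.seed(8)
    gd <- randomGazeDataset(5, 20)
    s1 <- scores(temporalSalience(gd, GlimpseParams(0.05, 3L)))
    s2 <- scores(temporalSalience(gd, GlimpseParams(0.15, 3L)))
    expect_true(all(s2 >= s1))
})

test_that("wider temporal windows smooth the score profile", {
    gd <- generateGaze(Scenario(N = 12, T = 80, seed = 13))
    tv <- vapply(c(0L, 2L, 5L), function(tt)
        sum(abs(diff(scores(temporalSalience(gd, GlimpseParams(0.1, tt)))))),
        numeric(1))
    expect_true(all(diff(tv) <= 0))
})

test_that("optimized scoring equals the literal double-loop oracle", {
    set.seed(99)
    for (rep in 1:10) {
        gd <- randomGazeDataset(sample(2:5, 1), sample(5:20, 1))
        thetaS <- runif(1, 0.05, 0.3)
        thetaT <- sample(0:3, 1)
        expect_equal(
            scores(suppressWarnings(
                temporalSalience(gd, GlimpseParams(thetaS, thetaT)))),
            oracleSalience(gd, thetaS, thetaT))
    }
})

test_that("frames without pair evidence score zero with a warning", {
    x <- matrix(NA_real_, 2, 5)
    x[1, 3] <- 0.5
    gd <- GazeDataset(x, x, width = 1, height = 1, normalized = TRUE)
    expect_warning(s <- temporalSalience(gd, GlimpseParams(0.1, 0L)),
                   "fewer than 2")
    expect_equal(scores(s), rep(0, 5))
})

test_that("constant baseline repeats lambda and validates its range", {
    expect_equal(scores(constantBaseline(5, 0.25)), rep(0.25, 5))
    expect_equal(scores(constantBaseline(3, 0)), rep(0, 3))
    expect_equal(scores(constantBaseline(3, 1)), rep(1, 3))
    expect_error(constantBaseline(3, 1.2), "lambda")
    expect_error(constantBaseline(0, 0.5), "T")
})
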