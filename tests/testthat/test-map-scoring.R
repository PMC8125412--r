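test_that("mutual information scoring matches hand-computed cases", {
    # constant maps: zero-entropy marginals give zero MI
    seq <- SalienceMapSequence(rep(list(matrix(0.3, 6, 6)), 4))
    expect_equal(scores(scoreMutualInfo(seq, thetaT = 1, nBins = 8)),
                 rep(0, 4))

    # identical balanced binary maps: I(S, S) = H(S) = 1 bit
    m <- matrix(rep(c(0, 1), each = 32), 8, 8)
    seq <- SalienceMapSequence(list(m, m, m))
    s <- scores(scoreMutualInfo(seq, thetaT = 1, nBins = 2))
    expect_equal(s[2], 1)
    expect_equal(scoreRange(scoreMutualInfo(seq, thetaT = 1, nBins = 2)),
                 c(0, 1))

    # independently shuffled pixels: MI near zero (histogram bias only)
    set.seed(4)
    base <- matrix(runif(64 * 64), 64, 64)
    maps <- lapply(1:6, function(i) matrix(sample(base), 64, 64))
    s <- scores(scoreMutualInfo(SalienceMapSequence(maps), thetaT = 2,
                                nBins = 8))
    expect_true(all(s < 0.05))

    expect_error(scoreMutualInfo(SalienceMapSequence(list(m))), "2 frames")
})

test_that("mutual information is symmetric under time reversal", {
    set.seed(5)
    maps <- lapply(1:7, function(i) matrix(runif(100), 10, 10))
    s <- scores(scoreMutualInfo(SalienceMapSequence(maps), thetaT = 2,
                                nBins = 4))
    srev <- scores(scoreMutualInfo(SalienceMapSequence(rev(maps)),
                                   thetaT = 2, nBins = 4))
    expect_equal(srev, rev(s))
})

test_that("max-value scoring rescales by the declared value scale", {
    zero <- matrix(0, 4, 4)
    mid <- matrix(0.7, 4, 4)
    expect_equal(scores(scoreMaxValue(SalienceMapSequence(list(zero, mid)))),
                 c(0, 0.7))
    m255 <- matrix(c(rep(0, 15), 255), 4, 4)
    expect_equal(scores(scoreMaxValue(SalienceMapSequence(list(m255),
                                                          valueScale = 255))),
                 1)
})

test_that("salience centroid is the intensity-weighted pixel mean", {
    m <- matrix(0, 10, 10)
    m[8, 4] <- 2          # row 8 = y 7, col 4 = x 3
    expect_equal(salienceCentroid(m), c(x = 3, y = 7))
    expect_equal(salienceCentroid(matrix(1, 5, 9)), c(x = 4, y = 2))
    expect_equal(salienceCentroid(matrix(c(1, 0, 0, 3), 2, 2, byrow = TRUE)),
                 c(x = 0.75, y = 0.75))
    expect_error(salienceCentroid(matrix(0, 3, 3)), "zero-mass")
})

test_that("spread kernel bandwidth follows the map width", {
    k <- makeSpreadKernel(100, 0.1)
    expect_equal(k@sigma, 5)
    expect_identical(k@side, 21L)
    expect_equal(spreadKernelValue(k, 0, 0), 1)
    k <- makeSpreadKernel(1920, 0.1)
    expect_equal(k@sigma, 96)
    expect_identical(k@side, 385L)
})

test_that("spread scoring matches closed forms on point masses", {
    one <- matrix(0, 16, 16); one[5, 9] <- 3
    expect_equal(scores(scoreSpread(SalienceMapSequence(list(one)), 0.1)), 1)

    # two equal masses D apart: both terms exp(-(D/2)^2 / (2 sigma^2))
    two <- matrix(0, 20, 40); two[10, 11] <- 1; two[10, 21] <- 1
    sigma <- 40 * 0.1 / 2
    expect_equal(scores(scoreSpread(SalienceMapSequence(list(two)), 0.1)),
                 exp(-25 / (2 * sigma^2)))

    expect_warning(
        s <- scoreSpread(SalienceMapSequence(list(matrix(0, 4, 4))), 0.1),
        "zero-mass")
    expect_equal(scores(s), 0)
})

test_that("spread scoring is invariant to positive rescaling", {
    set.seed(6)
    m <- matrix(runif(30 * 20), 20, 30)
    s1 <- scores(scoreSpread(SalienceMapSequence(list(m)), 0.1))
    s2 <- scores(scoreSpread(SalienceMapSequence(list(m * 37.5)), 0.1))
    expect_equal(s1, s2)
})

test_that("binarization thresholds by fixed fraction or Otsu", {
    m <- matrix(c(0, 10, 10, 10), 2, 2)
    B <- binarizeMap(m, method = "fixed:0.5")
    expect_equal(B + 0, matrix(c(0, 1, 1, 1), 2, 2), ignore_attr = TRUE)
    expect_equal(attr(B, "threshold"), 5)
    expect_false(any(binarizeMap(matrix(0, 3, 3), method = "fixed:0.5")))
    expect_warning(B <- binarizeMap(matrix(2, 3, 3)), "constant")
    expect_false(any(B))

    # Otsu lands between the clusters of a bimodal map and agrees with
    # an exhaustive within-class-variance search
    set.seed(12)
    m <- matrix(c(runif(60, 0, 0.2), runif(40, 0.7, 1)), 10, 10)
    B <- binarizeMap(m, method = "otsu")
    thr <- attr(B, "threshold")
    expect_gt(thr, 0.2)
    expect_lt(thr, 0.7)
    expect_equal(m > thr, m > bruteForceOtsu(m))
})

test_that("component centroids are 8-connected and normalized", {
    B <- matrix(FALSE, 10, 12)
    B[2:3, 2:3] <- TRUE
    B[8:9, 10:11] <- TRUE
    cs <- componentCentroids(B)
    cen <- centroids(cs)[order(centroids(cs)[, "x"]), ]
    expect_equal(nrow(cen), 2)
    expect_equal(unname(cen[1, ]), c(1.5 / 12, 1.5 / 10))
    expect_equal(unname(cen[2, ]), c(9.5 / 12, 7.5 / 10))

    expect_identical(nrow(centroids(componentCentroids(
        matrix(FALSE, 4, 4)))), 0L)

    # L-shaped component: pixels (x,y) = (0,0), (1,0), (1,1)
    B <- matrix(FALSE, 3, 3)
    B[1, 1] <- B[1, 2] <- B[2, 2] <- TRUE
    cen <- centroids(componentCentroids(B))
    expect_equal(unname(cen[1, ]), c((2 / 3) / 3, (1 / 3) / 3))

    # a diagonal touch joins components only under 8-connectivity
    B <- matrix(FALSE, 4, 4); B[1, 1] <- B[2, 2] <- TRUE
    expect_equal(nrow(centroids(componentCentroids(B))), 1)
})

test_that("point-hypotheses scoring follows the gaze scoring contract", {
    # one stationary blob: all window centroids coincide
    m <- matrix(0, 16, 16); m[8, 8] <- 1
    seq <- SalienceMapSequence(rep(list(m), 5))
    expect_equal(scores(scorePoints(seq, GlimpseParams(0.1, 2L),
                                    method = "fixed:0.5")),
                 rep(1, 5))

    # no suprathreshold pixels anywhere: no centroids, score 0
    seq <- SalienceMapSequence(rep(list(matrix(0, 8, 8)), 3))
    expect_warning(s <- scorePoints(seq, GlimpseParams(0.1, 1L),
                                    method = "fixed:0.5"),
                   "fewer than 2 centroids")
    expect_equal(scores(s), rep(0, 3))

    # two stationary blobs 0.5 apart: 6 window centroids, 6 of 15 pairs close
    s <- scores(scorePoints(twoBlobMaps(3), GlimpseParams(0.1, 1L),
                            method = "fixed:0.5"))
    expect_equal(s[2], 0.4)
})

test_that("all scorers return one value per frame", {
    set.seed(3)
    maps <- lapply(1:6, function(i) matrix(runif(64), 8, 8))
    seq <- SalienceMapSequence(maps)
    expect_length(scores(scoreMutualInfo(seq, thetaT = 2, nBins = 4)), 6)
    expect_length(scores(scoreMaxValue(seq)), 6)
    expect_length(scores(scoreSpread(seq, 0.1)), 6)
    expect_length(scores(suppressWarnings(scorePoints(seq))), 6)
})
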