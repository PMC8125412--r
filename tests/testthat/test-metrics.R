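test_that("length-normalized distance matches hand computations", {
    expect_equal(signalDistance(c(0.3, 0.7), c(0.3, 0.7)), 0)
    expect_equal(signalDistance(rep(1, 6), rep(0, 6)), 1)
    expect_equal(signalDistance(c(1, 0, 1, 0), c(0, 0, 0, 0)), sqrt(0.5))
    expect_error(signalDistance(1:3, 1:4), "lengths differ")
})

test_that("signal distance behaves as a metric on random triples", {
    set.seed(21)
    for (rep in 1:20) {
        a <- runif(10); b <- runif(10); c <- runif(10)
        expect_equal(signalDistance(a, b), signalDistance(b, a))
        expect_equal(signalDistance(a, a), 0)
        expect_lte(signalDistance(a, c),
                   signalDistance(a, b) + signalDistance(b, c) + 1e-12)
    }
})

test_that("mean Jaccard index matches hand computations", {
    expect_equal(signalIoU(c(0.4, 0.2), c(0.4, 0.2)), 1)
    expect_equal(signalIoU(c(0.5, 0.1), c(0, 0)), 0)
    expect_equal(signalIoU(c(0.2, 0.8), c(0.4, 0.4)), 0.5)
    expect_equal(signalIoU(c(0, 0.5), c(0, 0.5)), 1)  # 0/0 counts as 1
    expect_error(signalIoU(c(-0.1, 0), c(0, 0)), "nonnegative")
})

test_that("Jaccard index is symmetric and scales linearly", {
    set.seed(22)
    s <- runif(15, min = 0.01)
    expect_equal(signalIoU(s, 0.3 * s), 0.3)
    a <- runif(15); b <- runif(15)
    expect_equal(signalIoU(a, b), signalIoU(b, a))
})

test_that("soft precision/recall follow the min-sum definitions", {
    r <- c(1, 0, 0, 1)
    expect_equal(softPrecisionRecall(r, r),
                 c(precision = 1, recall = 1))
    expect_equal(softPrecisionRecall(c(0.5, 0.5, 0), c(1, 0, 0)),
                 c(precision = 0.5, recall = 0.5))
    pr <- softPrecisionRecall(c(0.5, 0.5), c(0, 0))
    expect_true(is.na(pr["recall"]))
    pr <- softPrecisionRecall(c(0, 0), c(1, 0))
    expect_true(is.na(pr["precision"]))
    # precision and recall coincide whenever the signal masses agree
    set.seed(23)
    r <- rbinom(20, 1, 0.4)
    s <- runif(20); s <- s * sum(r) / sum(s)
    pr <- softPrecisionRecall(s, r)
    expect_equal(unname(pr["precision"]), unname(pr["recall"]))
})

test_that("rank correlations handle monotone transforms and ties", {
    s <- c(0.1, 0.4, 0.2, 0.9, 0.5)
    expect_equal(rankCorrelations(s, s^2 + 1),
                 c(rho = 1, tau = 1))
    expect_equal(rankCorrelations(s, -s), c(rho = -1, tau = -1))
    expect_equal(unname(rankCorrelations(c(1, 2, 3), c(1, 3, 2))["tau"]),
                 1 / 3)
    expect_true(all(is.na(rankCorrelations(rep(0.5, 5), s))))
    expect_equal(rankCorrelations(s, c(0.2, 0.6, 0.3, 0.8, 0.4)),
                 rankCorrelations(c(0.2, 0.6, 0.3, 0.8, 0.4), s))
})

test_that("change points expand into clipped binary windows", {
    r <- binaryReferenceFromChangepoints(100, T = 200, tolerance = 5)
    expect_equal(sum(scores(r)), 11)
    expect_equal(which(scores(r) == 1), 95:105)
    expect_equal(scores(binaryReferenceFromChangepoints(integer(0), 50, 5)),
                 rep(0, 50))
    r <- binaryReferenceFromChangepoints(1, T = 50, tolerance = 5)
    expect_equal(which(scores(r) == 1), 1:6)
    expect_error(binaryReferenceFromChangepoints(300, T = 200, tolerance = 5),
                 "must lie in")
})

test_that("compareSignals bundles every applicable measure", {
    s <- c(0.2, 0.8, 0.4, 0.6)
    ref <- binaryReferenceFromChangepoints(2, T = 4, tolerance = 0)
    rep1 <- compareSignals(s, ref)
    expect_equal(rep1@d, signalDistance(s, scores(ref)))
    expect_equal(rep1@precision, sum(pmin(s, scores(ref))) / sum(s))
    expect_equal(rep1@recall, sum(pmin(s, scores(ref))))
    df <- as.data.frame(rep1)
    expect_identical(df$T, 4L)
    # min-max normalization maps both signals onto [0, 1]
    rep2 <- compareSignals(c(2, 6, 4), c(1, 3, 2), normalize = TRUE)
    expect_equal(rep2@d, 0)
    expect_equal(rep2@iou, 1)
})

test_that("constant-baseline comparison reports IoU but no correlation", {
    s <- SalienceSeries(c(0.2, 0.3, 0.25, 0.5))
    base <- constantBaseline(4, 0.25)
    rep <- compareSignals(s, base)
    expect_true(is.na(rep@rho) && is.na(rep@tau))
    expect_equal(rep@iou, mean(pmin(scores(s), 0.25) / pmax(scores(s), 0.25)))
})
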