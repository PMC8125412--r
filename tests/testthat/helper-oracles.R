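# Independent oracles and small fixture builders used across test files.

# Literal double-loop implementation of the windowed pair-consistency
# score: enumerate every unordered pair of pooled points explicitly.
oracleSalience <- function(gd, thetaS, thetaT) {
    Tn <- nFrames(gd)
    N <- nObservers(gd)
    s <- numeric(Tn)
    for (t in seq_len(Tn)) {
        pts <- NULL
        for (tt in max(1, t - thetaT):min(Tn, t + thetaT))
            for (o in seq_len(N))
                if (!is.na(gd@x[o, tt]))
                    pts <- rbind(pts, c(gd@x[o, tt], gd@y[o, tt]))
        n <- if (is.null(pts)) 0L else nrow(pts)
        if (n < 2L) next
        cnt <- 0L
        for (i in seq_len(n - 1L))
            for (j in (i + 1L):n)
                if (sqrt(sum((pts[i, ] - pts[j, ])^2)) < thetaS)
                    cnt <- cnt + 1L
        s[t] <- 2 * cnt / (n * (n - 1))
    }
    s
}

# Random small dataset with optional missing samples, in [0,1] units.
randomGazeDataset <- function(N, T, missingFrac = 0.1) {
    x <- matrix(runif(N * T), N, T)
    y <- matrix(runif(N * T), N, T)
    drop <- matrix(runif(N * T) < missingFrac, N, T)
    x[drop] <- NA_real_
    y[drop] <- NA_real_
    GazeDataset(x, y, width = 100, height = 100, normalized = TRUE)
}

# Exhaustive Otsu: the cut (on the same 256-level grid the implementation
# quantizes to) minimizing within-class variance.
bruteForceOtsu <- function(map) {
    v <- as.vector(map) / max(map)
    cuts <- (0:255) / 256
    wcv <- vapply(cuts, function(thr) {
        lo <- v[v <= thr]; hi <- v[v > thr]
        vlo <- if (length(lo) > 1) var(lo) else 0
        vhi <- if (length(hi) > 1) var(hi) else 0
        (length(lo) * vlo + length(hi) * vhi) / length(v)
    }, numeric(1))
    cuts[which.min(wcv)] * max(map)
}

# Maps holding two stationary unit point masses 0.5 apart (normalized),
# repeated over nFrames frames.
twoBlobMaps <- function(nFrames = 3L, side = 32L) {
    m <- matrix(0, side, side)
    m[side / 2, side / 4] <- 1
    m[side / 2, side / 4 + side / 2] <- 1
    SalienceMapSequence(rep(list(m), nFrames))
}
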