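#' Normalize gaze positions to frame-relative units
#'
#' Divides every x by the frame width W and every y by the frame height H,
#' so on-screen gaze lies in the unit square. Off-screen samples (outside
#' [0,1] after division) are retained — they can legitimately indicate
#' inconsistency — but counted and reported via a message; use
#' \code{\link{filterOffScreen}} to drop them.
#'
#' @param dataset a pixel-unit \linkS4class{GazeDataset}.
#' @return The dataset with normalized positions.
#' @examples
#' gd <- GazeDataset(matrix(960, 1, 1), matrix(540, 1, 1),
#'                   width = 1920, height = 1080)
#' normalizeGaze(gd)@x  # 0.5
#' @export
normalizeGaze <- function(dataset) {
    stopifnot(is(dataset, "GazeDataset"))
    if (dataset@normalized)
        stop("dataset is already normalized")
    if (dataset@W <= 0 || dataset@H <= 0)
        stop("invalid frame dimensions: W and H must be positive")
    out <- GazeDataset(dataset@x / dataset@W, dataset@y / dataset@H,
                       width = dataset@W, height = dataset@H,
                       frameRate = dataset@frameRate, normalized = TRUE)
    off <- offScreenCount(out)
    if (off > 0)
        message(sprintf("normalizeGaze: %d off-screen sample(s) retained", off))
    out
}

#' Count gaze samples outside the unit square
#'
#' @param dataset a normalized \linkS4class{GazeDataset}.
#' @return Integer count of non-missing samples with x or y outside [0, 1].
#' @export
offScreenCount <- function(dataset) {
    stopifnot(is(dataset, "GazeDataset"), dataset@normalized)
    ok <- !is.na(dataset@x)
    sum(ok & (dataset@x < 0 | dataset@x > 1 |
              dataset@y < 0 | dataset@y > 1))
}

#' Drop off-screen gaze samples
#'
#' Marks samples outside the unit square as missing.
#'
#' @param dataset a normalized \linkS4class{GazeDataset}.
#' @return The dataset with off-screen samples set to missing.
#' @export
filterOffScreen <- function(dataset) {
    stopifnot(is(dataset, "GazeDataset"), dataset@normalized)
    bad <- !is.na(dataset@x) &
        (dataset@x < 0 | dataset@x > 1 | dataset@y < 0 | dataset@y > 1)
    x <- dataset@x; y <- dataset@y
    x[bad] <- NA_real_; y[bad] <- NA_real_
    GazeDataset(x, y, width = dataset@W, height = dataset@H,
                frameRate = dataset@frameRate, normalized = TRUE)
}

#' Average raw timestamped gaze samples into per-frame positions
#'
#' Eye trackers usually sample much faster than the video frame rate (e.g.
#' a 500 Hz tracker against 25 fps video gives 20 samples per frame), so
#' each observer's valid samples within a frame's half-open time interval
#' [(t-1)/frameRate, t/frameRate) are averaged into a single position.
#' Frames in which an observer has no valid sample (e.g. blinks) are
#' marked missing and excluded from all later point pooling.
#'
#' @param samples data.frame with columns \code{observer}, \code{time}
#'   (seconds, nonnegative), \code{x}, \code{y}; NA in x or y marks an
#'   invalid sample.
#' @param frameRate video frames per second.
#' @param width,height source frame size in pixels.
#' @param samplingRate optional tracker sampling rate (samples/s); if
#'   given it must be at least \code{frameRate}.
#' @param T optional total frame count (defaults to the last frame with
#'   data).
#' @return A pixel-unit \linkS4class{GazeDataset} (frames are 1-based).
#' @examples
#' raw <- data.frame(observer = 1, time = c(0.00, 0.02),
#'                   x = c(0.1, 0.3), y = c(0.1, 0.3))
#' aggregateToFrames(raw, frameRate = 25, width = 1, height = 1)@x  # 0.2
#' @export
aggregateToFrames <- function(samples, frameRate, width, height,
                              samplingRate = NULL, T = NULL) {
    stopifnot(is.data.frame(samples), frameRate > 0)
    need <- c("observer", "time", "x", "y")
    if (!all(need %in% names(samples)))
        stop("samples must have columns observer, time, x, y")
    if (!is.null(samplingRate) && samplingRate < frameRate)
        stop("samplingRate must be at least frameRate")
    if (nrow(samples) == 0) {
        warning("empty gaze stream: returning empty dataset")
        return(GazeDataset(matrix(numeric(0), 0, 0),
                           matrix(numeric(0), 0, 0),
                           width = width, height = height,
                           frameRate = frameRate))
    }
    if (any(samples$time < 0)) stop("timestamps must be nonnegative")
    frame <- floor(samples$time * frameRate) + 1L
    obs <- sort(unique(samples$observer))
    Tmax <- if (is.null(T)) max(frame) else as.integer(T)
    valid <- !is.na(samples$x) & !is.na(samples$y) & frame <= Tmax
    x <- matrix(NA_real_, length(obs), Tmax)
    y <- matrix(NA_real_, length(obs), Tmax)
    if (any(valid)) {
        oi <- match(samples$observer, obs)[valid]
        fi <- frame[valid]
        key <- (oi - 1L) * Tmax + fi
        mx <- vapply(split(samples$x[valid], key), mean, numeric(1))
        my <- vapply(split(samples$y[valid], key), mean, numeric(1))
        at <- as.integer(names(mx))
        x[cbind((at - 1L) %/% Tmax + 1L, (at - 1L) %% Tmax + 1L)] <- mx
        y[cbind((at - 1L) %/% Tmax + 1L, (at - 1L) %% Tmax + 1L)] <- my
    }
    GazeDataset(x, y, width = width, height = height, frameRate = frameRate)
}

#' Pool gaze points over a temporal window
#'
#' Collects all non-missing positions from all observers over the window
#' [t - thetaT, t + thetaT], clipped to [1, T] at the video boundaries, as
#' an anonymous bag of points.
#'
#' @param dataset a normalized \linkS4class{GazeDataset}.
#' @param t center frame, 1-based.
#' @param thetaT temporal half-window in frames.
#' @return A \linkS4class{PointBag}.
#' @export
collectWindowPoints <- function(dataset, t, thetaT) {
    stopifnot(is(dataset, "GazeDataset"))
    if (!dataset@normalized)
        stop("dataset must be normalized first (see normalizeGaze)")
    Tn <- nFrames(dataset)
    if (length(t) != 1L || is.na(t) || t < 1 || t > Tn)
        stop(sprintf("frame t = %s outside [1, %d]", as.character(t), Tn))
    cols <- max(1L, as.integer(t) - as.integer(thetaT)):
            min(Tn, as.integer(t) + as.integer(thetaT))
    px <- as.vector(dataset@x[, cols, drop = FALSE])
    py <- as.vector(dataset@y[, cols, drop = FALSE])
    keep <- !is.na(px) & !is.na(py)
    new("PointBag",
        points = cbind(x = px[keep], y = py[keep]),
        sourceFrame = as.integer(t))
}

#' Fraction of point pairs closer than the spatial scale
#'
#' The core consistency statistic: the fraction of unordered pairs of
#' points in the bag whose Euclidean distance is strictly below
#' \code{thetaS}; equivalently a windowed, threshold-normalized form of
#' Ripley's K statistic. Bags with fewer than two points carry no pair
#' evidence and score 0.
#'
#' @param bag a \linkS4class{PointBag} or an n x 2 numeric matrix.
#' @param thetaS positive distance threshold (normalized units).
#' @return A score in [0, 1].
#' @examples
#' pts <- rbind(c(0, 0), c(0.05, 0), c(0.3, 0))
#' pairConsistency(pts, 0.1)  # 1/3: only the first pair is close
#' @export
pairConsistency <- function(bag, thetaS) {
    stopifnot(thetaS > 0)
    pts <- if (is(bag, "PointBag")) bag@points else as.matrix(bag)
    n <- nrow(pts)
    if (n < 2L) return(0)
    mean(stats::dist(pts) < thetaS)
}

#' Temporal salience from multi-observer gaze consistency
#'
#' For every frame t, pools all observers' gaze points over the temporal
#' window [t - thetaT, t + thetaT] (clipped at the video boundaries) and
#' scores the fraction of point pairs closer than thetaS. High values mean
#' that observers look at the same place at the same time — the signature
#' of an attention-grabbing moment. The score needs no training and never
#' inspects the video content.
#'
#' Frames whose window holds fewer than two points (all observers missing)
#' score 0; a single warning reports how many such frames occurred.
#'
#' @param dataset a normalized \linkS4class{GazeDataset}.
#' @param params a \linkS4class{GlimpseParams} (defaults thetaS = 0.1,
#'   thetaT = 5).
#' @return A \linkS4class{SalienceSeries} of length T with values in [0,1].
#' @examples
#' sc <- Scenario(N = 10, T = 40, alpha = 1, clusterSd = 0, seed = 7)
#' s <- temporalSalience(generateGaze(sc))
#' all(scores(s) == 1)  # perfectly consistent gaze
#' @export
temporalSalience <- function(dataset, params = GlimpseParams()) {
    stopifnot(is(dataset, "GazeDataset"), is(params, "GlimpseParams"))
    validObject(params)
    if (!dataset@normalized)
        stop("dataset must be normalized first (see normalizeGaze)")
    Tn <- nFrames(dataset)
    if (Tn == 0L || nObservers(dataset) == 0L)
        stop("empty dataset: no observers or frames")
    vals <- numeric(Tn)
    degenerate <- 0L
    for (t in seq_len(Tn)) {
        bag <- collectWindowPoints(dataset, t, params@thetaT)
        if (nPoints(bag) < 2L) degenerate <- degenerate + 1L
        vals[t] <- pairConsistency(bag, params@thetaS)
    }
    if (degenerate > 0L)
        warning(sprintf(
            "%d frame(s) had fewer than 2 gaze points in the window; scored 0",
            degenerate))
    SalienceSeries(vals, range = c(0, 1),
                   label = sprintf("glimpse thetaS=%g thetaT=%d",
                                   params@thetaS, params@thetaT))
}

#' Constant salience baseline
#'
#' The trivial signal s(t) = lambda, a useful floor when judging
#' map-derived scores.
#'
#' @param T number of frames.
#' @param lambda constant score in [0, 1].
#' @return A \linkS4class{SalienceSeries}.
#' @examples
#' scores(constantBaseline(5, 0.25))
#' @export
constantBaseline <- function(T, lambda) {
    if (length(lambda) != 1L || is.na(lambda) || lambda < 0 || lambda > 1)
        stop("lambda must be a single value in [0, 1]")
    if (T < 1) stop("T must be at least 1")
    SalienceSeries(rep(as.numeric(lambda), T), range = c(0, 1),
                   label = sprintf("baseline lambda=%g", lambda))
}
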