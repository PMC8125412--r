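#' @import methods
NULL

#' Multi-observer gaze recordings for one video
#'
#' Holds at most one gaze position per (observer, frame), stored as two
#' parallel N x T matrices (observers in rows, frames in columns) with
#' \code{NA} marking missing samples (blinks, tracking loss). Positions are
#' either in source pixels or, after \code{\link{normalizeGaze}}, divided by
#' the frame width \code{W} and height \code{H} so that on-screen gaze lies
#' in the unit square. Note that this per-axis division makes Euclidean
#' distances anisotropic for non-square frames; the spatial scale parameter
#' is defined in these normalized units.
#'
#' @slot x numeric N x T matrix of horizontal positions.
#' @slot y numeric N x T matrix of vertical positions (origin top-left).
#' @slot W,H source frame width and height in pixels.
#' @slot frameRate frames per second (may be \code{NA} if unknown).
#' @slot normalized logical; \code{TRUE} once positions are divided by W, H.
#'
#' @seealso \code{\link{normalizeGaze}}, \code{\link{temporalSalience}},
#'   \code{\link{readGazeCSV}}
#' @exportClass GazeDataset
setClass("GazeDataset",
    representation(x = "matrix", y = "matrix", W = "numeric", H = "numeric",
                   frameRate = "numeric", normalized = "logical"),
    prototype(frameRate = NA_real_, normalized = FALSE))

setValidity("GazeDataset", function(object) {
    msg <- NULL
    if (!all(dim(object@x) == dim(object@y)))
        msg <- c(msg, "x and y matrices must have identical dimensions")
    if (length(object@W) != 1L || length(object@H) != 1L ||
        !is.finite(object@W) || !is.finite(object@H) ||
        object@W <= 0 || object@H <= 0)
        msg <- c(msg, "W and H must be single positive numbers")
    if (length(object@normalized) != 1L || is.na(object@normalized))
        msg <- c(msg, "normalized must be TRUE or FALSE")
    if (object@normalized && any(is.infinite(object@x), is.infinite(object@y)))
        msg <- c(msg, "normalized positions must be finite or NA")
    if (is.null(msg)) TRUE else msg
})

#' Construct a GazeDataset
#'
#' @param x,y numeric N x T matrices of gaze positions (NA = missing).
#' @param width,height source frame size in pixels.
#' @param frameRate frames per second, or NA.
#' @param normalized whether positions are already in [0,1] units.
#' @return A \linkS4class{GazeDataset}.
#' @examples
#' gd <- GazeDataset(matrix(0.5, 3, 10), matrix(0.5, 3, 10),
#'                   width = 1920, height = 1080, normalized = TRUE)
#' nObservers(gd)
#' @export
GazeDataset <- function(x, y, width, height, frameRate = NA_real_,
                        normalized = FALSE) {
    x <- as.matrix(x); y <- as.matrix(y)
    storage.mode(x) <- "double"; storage.mode(y) <- "double"
    new("GazeDataset", x = x, y = y, W = as.numeric(width),
        H = as.numeric(height), frameRate = as.numeric(frameRate),
        normalized = isTRUE(normalized))
}

#' Spatial and temporal scales of the gaze-consistency score
#'
#' \code{thetaS} is the distance below which two gaze points count as
#' consistent, in normalized (frame-relative) units; \code{thetaT} is the
#' half-width of the temporal pooling window in frames, so each score pools
#' gaze over \code{2 * thetaT + 1} frames. The defaults (0.1 and 5) are the
#' reference operating point used throughout the package.
#'
#' @slot thetaS positive spatial scale (normalized units).
#' @slot thetaT nonnegative integer temporal half-window (frames).
#' @exportClass GlimpseParams
setClass("GlimpseParams",
    representation(thetaS = "numeric", thetaT = "integer"),
    prototype(thetaS = 0.1, thetaT = 5L))

setValidity("GlimpseParams", function(object) {
    msg <- NULL
    if (length(object@thetaS) != 1L || !is.finite(object@thetaS) ||
        object@thetaS <= 0)
        msg <- c(msg, "thetaS must be a single positive number")
    if (length(object@thetaT) != 1L || is.na(object@thetaT) ||
        object@thetaT < 0L)
        msg <- c(msg, "thetaT must be a single nonnegative integer")
    if (is.null(msg)) TRUE else msg
})

#' @param thetaS spatial scale (normalized units); default 0.1.
#' @param thetaT temporal half-window in frames; default 5.
#' @return A \linkS4class{GlimpseParams}.
#' @rdname GlimpseParams-class
#' @examples
#' GlimpseParams()
#' GlimpseParams(thetaS = 0.05, thetaT = 0)
#' @export
GlimpseParams <- function(thetaS = 0.1, thetaT = 5L) {
    if (length(thetaT) != 1L || is.na(thetaT) || thetaT != round(thetaT))
        stop("thetaT must be an integer number of frames")
    new("GlimpseParams", thetaS = as.numeric(thetaS),
        thetaT = as.integer(thetaT))
}

#' Bag of gaze points pooled over a temporal window
#'
#' The unordered multiset of gaze positions from all observers within a
#' window centered on \code{sourceFrame}; observer identity is deliberately
#' discarded, so the consistency score depends only on the point pattern.
#'
#' @slot points numeric n x 2 matrix (columns x, y).
#' @slot sourceFrame the center frame index of the window.
#' @exportClass PointBag
setClass("PointBag",
    representation(points = "matrix", sourceFrame = "integer"))

setValidity("PointBag", function(object) {
    if (ncol(object@points) != 2L)
        return("points must be an n x 2 matrix")
    if (anyNA(object@points))
        return("points must not contain NA (drop missing samples first)")
    TRUE
})

#' A per-frame scalar salience signal
#'
#' A numeric sequence s(t), t = 1..T, with a documented closed range:
#' [0, 1] for gaze-consistency and map-based scores, [0, log2(nBins)] bits
#' for the windowed mutual-information scorer.
#'
#' @slot values numeric vector of length T.
#' @slot range numeric length-2 closed interval containing all values.
#' @slot label free-text description of the signal's origin.
#' @exportClass SalienceSeries
setClass("SalienceSeries",
    representation(values = "numeric", range = "numeric", label = "character"),
    prototype(range = c(0, 1), label = ""))

setValidity("SalienceSeries", function(object) {
    msg <- NULL
    if (length(object@range) != 2L || object@range[1] > object@range[2])
        msg <- c(msg, "range must be a nondecreasing length-2 interval")
    v <- object@values
    if (anyNA(v) || any(!is.finite(v)))
        msg <- c(msg, "values must be finite and non-missing")
    else if (length(v) &&
             (min(v) < object@range[1] - 1e-9 ||
              max(v) > object@range[2] + 1e-9))
        msg <- c(msg, "values must lie inside the declared range")
    if (is.null(msg)) TRUE else msg
})

#' @param values numeric scores, one per frame.
#' @param range declared closed range of the signal.
#' @param label free-text label.
#' @return A \linkS4class{SalienceSeries}.
#' @rdname SalienceSeries-class
#' @export
SalienceSeries <- function(values, range = c(0, 1), label = "") {
    new("SalienceSeries", values = as.numeric(values),
        range = as.numeric(range), label = as.character(label))
}

#' A sequence of per-frame spatial salience maps
#'
#' Nonnegative 2D maps S(x, y; t), one per frame, all of identical size.
#' Maps are stored as standard R matrices with rows indexing y (top to
#' bottom) and columns indexing x, matching image-file conventions.
#' \code{valueScale} documents the maximum of the encoding (1 for float
#' maps, 255 for 8-bit).
#'
#' @slot maps list of T numeric H x W matrices.
#' @slot valueScale declared maximum of the value encoding.
#' @exportClass SalienceMapSequence
setClass("SalienceMapSequence",
    representation(maps = "list", valueScale = "numeric"),
    prototype(valueScale = 1))

setValidity("SalienceMapSequence", function(object) {
    if (!length(object@maps)) return("at least one map is required")
    dims <- vapply(object@maps, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
        return("all maps must have identical dimensions")
    for (m in object@maps) {
        if (!is.matrix(m) || !is.numeric(m))
            return("each map must be a numeric matrix")
        if (anyNA(m) || any(!is.finite(m)) || any(m < 0))
            return("map values must be finite and nonnegative")
    }
    if (length(object@valueScale) != 1L || object@valueScale <= 0)
        return("valueScale must be a single positive number")
    TRUE
})

#' @param maps list of numeric H x W matrices (rows = y, columns = x).
#' @param valueScale declared maximum of the value encoding (default 1).
#' @return A \linkS4class{SalienceMapSequence}.
#' @rdname SalienceMapSequence-class
#' @examples
#' seq <- SalienceMapSequence(replicate(3, matrix(runif(12), 3, 4),
#'                                      simplify = FALSE))
#' length(seq)
#' @export
SalienceMapSequence <- function(maps, valueScale = 1) {
    new("SalienceMapSequence", maps = maps,
        valueScale = as.numeric(valueScale))
}

#' Gaussian kernel describing tolerated spatial spread
#'
#' The bandwidth is tied to the map width through the spatial scale:
#' sigma = W * thetaS / 2, and the nominal (odd) window side is
#' l = 2 * ceiling(2 * sigma) + 1. The kernel peaks at 1 at its center so a
#' perfectly concentrated map scores exactly 1 under the spread scorer.
#'
#' @slot sigma Gaussian bandwidth in pixels.
#' @slot side odd nominal window side length in pixels (metadata; the
#'   spread scorer evaluates the kernel over the whole map).
#' @slot peak kernel value at the center (always 1).
#' @seealso \code{\link{makeSpreadKernel}}, \code{\link{scoreSpread}}
#' @exportClass SpreadKernel
setClass("SpreadKernel",
    representation(sigma = "numeric", side = "integer", peak = "numeric"),
    prototype(peak = 1))

setValidity("SpreadKernel", function(object) {
    msg <- NULL
    if (object@sigma <= 0) msg <- c(msg, "sigma must be positive")
    if (object@side %% 2L != 1L) msg <- c(msg, "side must be odd")
    if (object@peak != 1) msg <- c(msg, "peak must be 1")
    if (is.null(msg)) TRUE else msg
})

#' Thresholded map and its component centroids
#'
#' @slot binaryMap logical H x W matrix B.
#' @slot centroids numeric k x 2 matrix of component centroids (columns
#'   x, y) in normalized [0,1] units, one per 8-connected component of B.
#' @slot threshold the applied cut value (NA if unknown).
#' @seealso \code{\link{binarizeMap}}, \code{\link{componentCentroids}}
#' @exportClass ComponentSet
setClass("ComponentSet",
    representation(binaryMap = "matrix", centroids = "matrix",
                   threshold = "numeric"),
    prototype(threshold = NA_real_))

setValidity("ComponentSet", function(object) {
    if (ncol(object@centroids) != 2L)
        return("centroids must be a k x 2 matrix")
    if (nrow(object@centroids) &&
        (min(object@centroids) < 0 || max(object@centroids) > 1))
        return("centroids must lie inside the unit square")
    TRUE
})

#' Binary reference signal built from change points
#'
#' r(t) = 1 for frames within \code{tolerance} frames of a change point,
#' 0 otherwise; used for soft precision/recall against a salience signal.
#'
#' @slot values integer 0/1 vector of length T.
#' @slot changepoints source frame indices.
#' @slot tolerance frames counted as "temporally close" to a change point.
#' @seealso \code{\link{binaryReferenceFromChangepoints}},
#'   \code{\link{softPrecisionRecall}}
#' @exportClass BinaryReference
setClass("BinaryReference",
    representation(values = "integer", changepoints = "integer",
                   tolerance = "integer"))

setValidity("BinaryReference", function(object) {
    if (!all(object@values %in% c(0L, 1L)))
        return("values must be 0 or 1")
    TRUE
})

#' Pairwise comparison of two temporal salience signals
#'
#' Bundles the signal-comparison measures: length-normalized Euclidean
#' distance d, mean Jaccard index (IoU), soft precision and recall against
#' a binary reference, and Spearman / Kendall rank correlations. Measures
#' that are undefined for the given pair (e.g. correlations of a constant
#' signal, recall against an all-zero reference) are NA.
#'
#' @slot d length-normalized Euclidean distance, >= 0.
#' @slot iou mean Jaccard index in [0, 1] (NA if a signal has negatives).
#' @slot precision,recall soft precision/recall in [0, 1] (NA when not
#'   compared against a binary reference or undefined).
#' @slot rho Spearman rank correlation in [-1, 1].
#' @slot tau Kendall tau-b rank correlation in [-1, 1].
#' @slot T compared signal length.
#' @seealso \code{\link{compareSignals}}
#' @exportClass ComparisonReport
setClass("ComparisonReport",
    representation(d = "numeric", iou = "numeric", precision = "numeric",
                   recall = "numeric", rho = "numeric", tau = "numeric",
                   T = "integer"))

#' Observer-subset convergence analysis result
#'
#' For each observer count k, the mean (and standard error) over sampled
#' k-subsets of the distance between the subset score and the all-observer
#' score.
#'
#' @slot ks observer counts 1..N.
#' @slot pOfK number of subsets evaluated per k: min(pmax, choose(N, k)).
#' @slot meanD mean distance d(s_k, s_N) per k.
#' @slot stderrD standard error of the mean per k (NA when pOfK = 1).
#' @slot pmax sampling cap.
#' @slot seed RNG seed used.
#' @seealso \code{\link{convergenceCurve}}
#' @exportClass ConvergenceResult
setClass("ConvergenceResult",
    representation(ks = "integer", pOfK = "integer", meanD = "numeric",
                   stderrD = "numeric", pmax = "integer", seed = "integer"))

setValidity("ConvergenceResult", function(object) {
    n <- length(object@ks)
    if (length(object@pOfK) != n || length(object@meanD) != n ||
        length(object@stderrD) != n)
        return("ks, pOfK, meanD, stderrD must have equal length")
    if (any(object@meanD < 0)) return("meanD must be nonnegative")
    TRUE
})

#' Synthetic viewing scenario
#'
#' Describes a ground-truth attention structure from which matching gaze
#' data and salience maps can be generated: a scripted attractor trajectory
#' that attending observers follow (with isotropic Gaussian jitter), an
#' attended fraction alpha(t) giving the probability of attending at each
#' frame, and parameters of the rendered map blobs. Observers switch
#' between attending and background (uniform) gaze with a persistence
#' parameter, which yields the temporal autocorrelation characteristic of
#' real scan paths.
#'
#' @slot N number of observers.
#' @slot T number of frames.
#' @slot attractor T x 2 matrix of attended locations in the unit square.
#' @slot alpha per-frame attended fraction in [0, 1].
#' @slot clusterSd isotropic spread of attended gaze (normalized units).
#' @slot mapSize map width and height (W, H) in pixels.
#' @slot blobSd spatial spread of rendered map blobs in pixels.
#' @slot noiseSd additive map noise level (clipped at zero).
#' @slot switchProb per-frame probability that an observer re-draws its
#'   attending state (lower = more persistent).
#' @slot clip logical; clip gaze to the unit square (on-screen viewing).
#' @slot seed RNG seed.
#' @seealso \code{\link{generateGaze}}, \code{\link{generateSalienceMaps}}
#' @exportClass Scenario
setClass("Scenario",
    representation(N = "integer", T = "integer", attractor = "matrix",
                   alpha = "numeric", clusterSd = "numeric",
                   mapSize = "integer", blobSd = "numeric",
                   noiseSd = "numeric", switchProb = "numeric",
                   clip = "logical", seed = "integer"))

setValidity("Scenario", function(object) {
    msg <- NULL
    if (object@N < 1L) msg <- c(msg, "N must be >= 1")
    if (object@T < 1L) msg <- c(msg, "T must be >= 1")
    if (nrow(object@attractor) != object@T || ncol(object@attractor) != 2L)
        msg <- c(msg, "attractor must be a T x 2 matrix")
    else if (min(object@attractor) < 0 || max(object@attractor) > 1)
        msg <- c(msg, "attractor must lie inside the unit square")
    if (length(object@alpha) != object@T ||
        any(object@alpha < 0 | object@alpha > 1))
        msg <- c(msg, "alpha must be a length-T vector in [0, 1]")
    if (any(c(object@clusterSd, object@blobSd, object@noiseSd) < 0))
        msg <- c(msg, "clusterSd, blobSd, noiseSd must be >= 0")
    if (object@switchProb < 0 || object@switchProb > 1)
        msg <- c(msg, "switchProb must be in [0, 1]")
    if (length(object@mapSize) != 2L || any(object@mapSize < 1L))
        msg <- c(msg, "mapSize must be two positive integers (W, H)")
    if (is.null(msg)) TRUE else msg
})
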