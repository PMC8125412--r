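#' @rdname GazeDataset-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("nObservers", function(object) standardGeneric("nObservers"))

#' @rdname GazeDataset-class
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname GazeDataset-class
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))

#' @rdname GazeDataset-class
#' @export
setGeneric("frameSize", function(object) standardGeneric("frameSize"))

#' @rdname SalienceSeries-class
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))

#' @rdname SalienceSeries-class
#' @export
setGeneric("scoreRange", function(object) standardGeneric("scoreRange"))

#' @rdname PointBag-class
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))

#' @rdname ComponentSet-class
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

setMethod("nObservers", "GazeDataset", function(object) nrow(object@x))
setMethod("nFrames", "GazeDataset", function(object) ncol(object@x))
setMethod("isNormalized", "GazeDataset", function(object) object@normalized)
setMethod("frameSize", "GazeDataset",
    function(object) c(W = object@W, H = object@H))
setMethod("nFrames", "SalienceSeries", function(object) length(object@values))
setMethod("nFrames", "SalienceMapSequence",
    function(object) length(object@maps))

setMethod("scores", "SalienceSeries", function(object) object@values)
setMethod("scores", "BinaryReference",
    function(object) as.numeric(object@values))
setMethod("scoreRange", "SalienceSeries", function(object) object@range)
setMethod("nPoints", "PointBag", function(object) nrow(object@points))
setMethod("centroids", "ComponentSet", function(object) object@centroids)

#' @rdname SalienceSeries-class
#' @export
setMethod("length", "SalienceSeries", function(x) length(x@values))

#' @rdname SalienceMapSequence-class
#' @export
setMethod("length", "SalienceMapSequence", function(x) length(x@maps))

#' @rdname SalienceMapSequence-class
#' @param i frame index.
#' @export
setMethod("[[", "SalienceMapSequence", function(x, i) x@maps[[i]])

#' Subset a gaze dataset by observers and/or frames
#'
#' @param x a \linkS4class{GazeDataset}.
#' @param i observer indices.
#' @param j frame indices.
#' @param ... ignored.
#' @param drop ignored (never drops).
#' @return A \linkS4class{GazeDataset} with the selected observers/frames.
#' @export
setMethod("[", "GazeDataset", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@x))
    if (missing(j)) j <- seq_len(ncol(x@x))
    GazeDataset(x@x[i, j, drop = FALSE], x@y[i, j, drop = FALSE],
                width = x@W, height = x@H, frameRate = x@frameRate,
                normalized = x@normalized)
})

setMethod("show", "GazeDataset", function(object) {
    n <- length(object@x)
    miss <- sum(is.na(object@x))
    cat(sprintf("GazeDataset: %d observer(s) x %d frame(s), %s\n",
                nObservers(object), nFrames(object),
                if (object@normalized) "normalized [0,1]" else "pixel units"))
    cat(sprintf("  frame %g x %g px, %s fps; missing samples: %d/%d (%.1f%%)\n",
                object@W, object@H,
                ifelse(is.na(object@frameRate), "?", object@frameRate),
                miss, n, if (n) 100 * miss / n else 0))
    if (object@normalized) {
        off <- offScreenCount(object)
        if (off > 0) cat(sprintf("  off-screen samples: %d\n", off))
    }
})

setMethod("show", "SalienceSeries", function(object) {
    cat(sprintf("SalienceSeries '%s': T = %d, range [%g, %g]\n",
                object@label, length(object@values),
                object@range[1], object@range[2]))
    if (length(object@values))
        cat(sprintf("  mean %.4f, min %.4f, max %.4f\n",
                    mean(object@values), min(object@values),
                    max(object@values)))
})

setMethod("show", "SalienceMapSequence", function(object) {
    d <- dim(object@maps[[1]])
    cat(sprintf("SalienceMapSequence: T = %d maps of %d x %d (W x H), value scale %g\n",
                length(object@maps), d[2], d[1], object@valueScale))
})

setMethod("show", "GlimpseParams", function(object) {
    cat(sprintf("GlimpseParams: thetaS = %g (normalized units), thetaT = %d frame(s)\n",
                object@thetaS, object@thetaT))
})

setMethod("show", "PointBag", function(object) {
    cat(sprintf("PointBag: %d point(s) pooled around frame %d\n",
                nrow(object@points), object@sourceFrame))
})

setMethod("show", "ComparisonReport", function(object) {
    fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.4f", v))
    cat(sprintf("ComparisonReport over T = %d frames\n", object@T))
    cat(sprintf("  d = %s, IoU = %s\n", fmt(object@d), fmt(object@iou)))
    cat(sprintf("  precision = %s, recall = %s\n",
                fmt(object@precision), fmt(object@recall)))
    cat(sprintf("  Spearman rho = %s, Kendall tau = %s\n",
                fmt(object@rho), fmt(object@tau)))
})

setMethod("show", "ConvergenceResult", function(object) {
    cat(sprintf("ConvergenceResult: N = %d, pmax = %d, seed = %d\n",
                max(object@ks), object@pmax, object@seed))
    print(utils::head(as.data.frame(object), 10))
    if (length(object@ks) > 10) cat("  ...\n")
})

setMethod("show", "Scenario", function(object) {
    cat(sprintf("Scenario: N = %d observers, T = %d frames, seed = %d\n",
                object@N, object@T, object@seed))
    cat(sprintf("  attended fraction alpha in [%g, %g], cluster sd %g\n",
                min(object@alpha), max(object@alpha), object@clusterSd))
    cat(sprintf("  maps %d x %d px, blob sd %g px, noise sd %g\n",
                object@mapSize[1], object@mapSize[2], object@blobSd,
                object@noiseSd))
})

#' @rdname ConvergenceResult-class
#' @param x a \linkS4class{ConvergenceResult}.
#' @param row.names,optional,... passed on conventions (ignored).
#' @export
as.data.frame.ConvergenceResult <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
    data.frame(k = x@ks, p_of_k = x@pOfK, mean_d = x@meanD,
               stderr_d = x@stderrD)
}

#' @rdname ComparisonReport-class
#' @param x a \linkS4class{ComparisonReport}.
#' @param row.names,optional,... passed on conventions (ignored).
#' @export
as.data.frame.ComparisonReport <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
    data.frame(T = x@T, d = x@d, iou = x@iou, precision = x@precision,
               recall = x@recall, rho = x@rho, tau = x@tau)
}
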