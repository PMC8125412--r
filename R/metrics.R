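# Extract a numeric signal from SalienceSeries, BinaryReference or numeric.
.signalValues <- function(s) {
    if (is(s, "SalienceSeries")) s@values
    else if (is(s, "BinaryReference")) as.numeric(s@values)
    else if (is.numeric(s)) as.numeric(s)
    else stop("expected a SalienceSeries, BinaryReference or numeric vector")
}

.checkSameLength <- function(v1, v2) {
    if (length(v1) != length(v2))
        stop(sprintf("signal lengths differ: %d vs %d",
                     length(v1), length(v2)))
    if (length(v1) < 1L) stop("signals must have length >= 1")
}

#' Length-normalized Euclidean distance between two signals
#'
#' d(s1, s2) = sqrt(mean((s1(t) - s2(t))^2)); the root-mean-square
#' difference, so signals of different video lengths are comparable.
#'
#' @param s1,s2 \linkS4class{SalienceSeries} or numeric vectors of equal
#'   length.
#' @return Nonnegative distance.
#' @examples
#' signalDistance(c(1, 0, 1, 0), c(0, 0, 0, 0))  # sqrt(0.5)
#' @export
signalDistance <- function(s1, s2) {
    v1 <- .signalValues(s1); v2 <- .signalValues(s2)
    .checkSameLength(v1, v2)
    sqrt(mean((v1 - v2)^2))
}

#' Mean Jaccard index (intersection over union) of two signals
#'
#' The mean over frames of min(s1, s2) / max(s1, s2) for nonnegative
#' signals. Frames where both signals are exactly 0 agree completely and
#' count as 1.
#'
#' @param s1,s2 nonnegative signals of equal length.
#' @return IoU in [0, 1].
#' @examples
#' signalIoU(c(0.2, 0.8), c(0.4, 0.4))  # 0.5
#' @export
signalIoU <- function(s1, s2) {
    v1 <- .signalValues(s1); v2 <- .signalValues(s2)
    .checkSameLength(v1, v2)
    if (any(v1 < 0) || any(v2 < 0))
        stop("IoU requires nonnegative signals")
    hi <- pmax(v1, v2)
    lo <- pmin(v1, v2)
    ratio <- ifelse(hi == 0, 1, lo / hi)
    mean(ratio)
}

#' Soft precision and recall of a signal against a binary reference
#'
#' Generalizes precision/recall to nonnegative real-valued signals through
#' sums of pointwise minima: with I = sum(min(s, r)), S = sum(s) and
#' R = sum(r), precision = I/S and recall = I/R. When S or R is zero the
#' corresponding measure is undefined and reported as NA.
#'
#' @param s a nonnegative signal.
#' @param r a \linkS4class{BinaryReference} or binary numeric vector of
#'   the same length.
#' @return Named numeric \code{c(precision, recall)} (NA when undefined).
#' @examples
#' softPrecisionRecall(c(0.5, 0.5, 0), c(1, 0, 0))  # 0.5, 0.5
#' @export
softPrecisionRecall <- function(s, r) {
    v <- .signalValues(s); rv <- .signalValues(r)
    .checkSameLength(v, rv)
    if (any(v < 0)) stop("signal must be nonnegative")
    if (!all(rv %in% c(0, 1))) stop("reference must be binary")
    I <- sum(pmin(v, rv)); S <- sum(v); R <- sum(rv)
    c(precision = if (S > 0) I / S else NA_real_,
      recall = if (R > 0) I / R else NA_real_)
}

#' Spearman and Kendall rank correlations of two signals
#'
#' Spearman's rho uses average ranks for ties; Kendall's tau is the
#' tie-corrected tau-b. A constant signal has no rank ordering, so both
#' are undefined (NA) in that case.
#'
#' @param s1,s2 signals of equal length >= 2.
#' @return Named numeric \code{c(rho, tau)}.
#' @examples
#' rankCorrelations(c(1, 2, 3), c(1, 3, 2))  # tau = 1/3
#' @export
rankCorrelations <- function(s1, s2) {
    v1 <- .signalValues(s1); v2 <- .signalValues(s2)
    .checkSameLength(v1, v2)
    if (length(v1) < 2L) stop("rank correlations need length >= 2")
    if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
        return(c(rho = NA_real_, tau = NA_real_))
    c(rho = stats::cor(v1, v2, method = "spearman"),
      tau = stats::cor(v1, v2, method = "kendall"))
}

#' Binary reference signal from change-point frames
#'
#' r(t) = 1 for frames within \code{tolerance} frames of any change point
#' (window clipped to [1, T]), else 0. Used to compare a salience signal
#' against e.g. detected scene changes.
#'
#' @param changepoints frame indices in [1, T] (may be empty).
#' @param T total frame count.
#' @param tolerance nonnegative number of frames counted as "close".
#' @return A \linkS4class{BinaryReference}.
#' @examples
#' sum(scores(binaryReferenceFromChangepoints(100, 200, 5)))  # 11 ones
#' @export
binaryReferenceFromChangepoints <- function(changepoints, T, tolerance = 5L) {
    T <- as.integer(T); tolerance <- as.integer(tolerance)
    stopifnot(T >= 1L, tolerance >= 0L)
    changepoints <- as.integer(changepoints)
    if (length(changepoints) &&
        (min(changepoints) < 1L || max(changepoints) > T))
        stop(sprintf("changepoints must lie in [1, %d]", T))
    r <- integer(T)
    for (cp in changepoints) {
        w <- max(1L, cp - tolerance):min(T, cp + tolerance)
        r[w] <- 1L
    }
    new("BinaryReference", values = r, changepoints = changepoints,
        tolerance = tolerance)
}

#' Min-max normalize a signal to [0, 1]
#'
#' Applied before comparing against external signals on other scales
#' (e.g. interestingness scores). A constant signal maps to all zeros.
#'
#' @param s a signal.
#' @return A numeric vector in [0, 1].
#' @export
minMaxNormalize <- function(s) {
    v <- .signalValues(s)
    span <- max(v) - min(v)
    if (span == 0) rep(0, length(v)) else (v - min(v)) / span
}

#' Compare two temporal salience signals with all applicable measures
#'
#' Computes the length-normalized distance, the mean Jaccard index (for
#' nonnegative signals), rank correlations, and — when \code{s2} is a
#' \linkS4class{BinaryReference} or \code{reference} is supplied — soft
#' precision and recall.
#'
#' @param s1 a signal (\linkS4class{SalienceSeries} or numeric).
#' @param s2 a second signal, possibly a \linkS4class{BinaryReference}.
#' @param reference optional \linkS4class{BinaryReference} scored against
#'   \code{s1} for precision/recall.
#' @param normalize min-max normalize both signals to [0, 1] first.
#' @return A \linkS4class{ComparisonReport}.
#' @examples
#' compareSignals(c(0.2, 0.8, 0.4), c(0.1, 0.9, 0.2))
#' @export
compareSignals <- function(s1, s2, reference = NULL, normalize = FALSE) {
    v1 <- .signalValues(s1); v2 <- .signalValues(s2)
    .checkSameLength(v1, v2)
    if (is.null(reference) && is(s2, "BinaryReference"))
        reference <- s2
    if (normalize) {
        v1 <- minMaxNormalize(v1)
        v2 <- minMaxNormalize(v2)
    }
    iou <- if (all(v1 >= 0) && all(v2 >= 0)) signalIoU(v1, v2) else NA_real_
    rc <- if (length(v1) >= 2L) rankCorrelations(v1, v2)
          else c(rho = NA_real_, tau = NA_real_)
    pr <- c(precision = NA_real_, recall = NA_real_)
    if (!is.null(reference))
        pr <- softPrecisionRecall(v1, reference)
    new("ComparisonReport", d = signalDistance(v1, v2), iou = iou,
        precision = unname(pr["precision"]), recall = unname(pr["recall"]),
        rho = unname(rc["rho"]), tau = unname(rc["tau"]),
        T = length(v1))
}
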