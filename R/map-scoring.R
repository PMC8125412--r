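#' Windowed mutual information between neighboring salience maps
#'
#' Scores frame t by the average mutual information between its map and
#' each other map in the window [t - thetaT, t + thetaT] (the k = 0
#' self-term is excluded: self-information equals the map's entropy and is
#' independent of temporal consistency). Out-of-range neighbors at the
#' sequence boundaries are skipped and the divisor reduced accordingly.
#'
#' MI is estimated from a joint histogram after linear quantization of the
#' whole sequence into \code{nBins} levels over its global value range.
#' Units are bits; the score range is [0, log2(nBins)].
#'
#' @param seq a \linkS4class{SalienceMapSequence} of length >= 2.
#' @param thetaT temporal half-window in frames (>= 1).
#' @param nBins histogram bins per variable (>= 2; default 64).
#' @return A \linkS4class{SalienceSeries} in bits.
#' @examples
#' m <- matrix(rep(c(0, 1), each = 32), 8, 8)  # half dark, half bright
#' seq <- SalienceMapSequence(list(m, m, m))
#' scores(scoreMutualInfo(seq, thetaT = 1, nBins = 2))[2]  # 1 bit
#' @export
scoreMutualInfo <- function(seq, thetaT = 5L, nBins = 64L) {
    stopifnot(is(seq, "SalienceMapSequence"))
    Tn <- length(seq@maps)
    if (Tn < 2L) stop("mutual information needs at least 2 frames")
    if (thetaT < 1L) stop("thetaT must be >= 1")
    if (nBins < 2L) stop("nBins must be >= 2")
    thetaT <- as.integer(thetaT); nBins <- as.integer(nBins)
    rng <- range(vapply(seq@maps, range, numeric(2)))
    span <- rng[2] - rng[1]
    quant <- lapply(seq@maps, function(m) {
        if (span == 0) rep(1L, length(m))
        else pmin(nBins, floor((as.vector(m) - rng[1]) / span * nBins) + 1L)
    })
    vals <- numeric(Tn)
    for (t in seq_len(Tn)) {
        ks <- (t - thetaT):(t + thetaT)
        ks <- ks[ks >= 1L & ks <= Tn & ks != t]
        vals[t] <- mean(vapply(ks, function(k)
            .mutualInformation(quant[[t]], quant[[k]], nBins), numeric(1)))
    }
    SalienceSeries(vals, range = c(0, log2(nBins)),
                   label = sprintf("mutualinfo thetaT=%d nBins=%d",
                                   thetaT, nBins))
}

# MI in bits from two equal-length integer vectors with levels 1..nBins.
.mutualInformation <- function(a, b, nBins) {
    joint <- tabulate((a - 1L) * nBins + b, nbins = nBins * nBins)
    P <- matrix(joint / length(a), nBins, nBins)  # P[i,j] = Pr(b=i, a=j)
    pa <- colSums(P); pb <- rowSums(P)
    nz <- which(P > 0, arr.ind = TRUE)
    p <- P[nz]
    sum(p * log2(p / (pb[nz[, 1]] * pa[nz[, 2]])))
}

#' Global-maximum map score
#'
#' s(t) is the largest value of the map at frame t after rescaling by the
#' declared value scale, a rough indication of how salient the frame is
#' when maps are clean and concentrated.
#'
#' @param seq a \linkS4class{SalienceMapSequence}.
#' @return A \linkS4class{SalienceSeries} in [0, 1].
#' @export
scoreMaxValue <- function(seq) {
    stopifnot(is(seq, "SalienceMapSequence"))
    vals <- vapply(seq@maps, max, numeric(1)) / seq@valueScale
    SalienceSeries(vals, range = c(0, 1), label = "maxvalue")
}

#' Intensity-weighted centroid of a salience map
#'
#' @param map a nonnegative numeric matrix (rows = y, columns = x).
#' @return Named vector \code{c(x, y)} in pixels, 0-based pixel centers.
#' @examples
#' salienceCentroid(matrix(c(1, 0, 0, 3), 2, 2, byrow = TRUE))  # (0.75, 0.75)
#' @export
salienceCentroid <- function(map) {
    map <- as.matrix(map)
    mass <- sum(map)
    if (mass <= 0) stop("zero-mass map: centroid undefined")
    xc <- sum((seq_len(ncol(map)) - 1) * colSums(map)) / mass
    yc <- sum((seq_len(nrow(map)) - 1) * rowSums(map)) / mass
    c(x = xc, y = yc)
}

#' Gaussian spread kernel tied to the spatial scale
#'
#' The bandwidth follows the map width: sigma = W * thetaS / 2, so the
#' kernel tolerates the same relative spread that the gaze-based score
#' tolerates through thetaS. The nominal window side l = 2 ceiling(2
#' sigma) + 1 is kept as metadata; evaluation is over the whole map.
#'
#' @param W map width in pixels.
#' @param thetaS spatial scale in normalized units.
#' @return A \linkS4class{SpreadKernel}.
#' @examples
#' makeSpreadKernel(100, 0.1)  # sigma 5, side 21
#' @export
makeSpreadKernel <- function(W, thetaS) {
    stopifnot(W > 0, thetaS > 0)
    sigma <- W * thetaS / 2
    new("SpreadKernel", sigma = sigma,
        side = as.integer(2 * ceiling(2 * sigma) + 1), peak = 1)
}

#' Evaluate a spread kernel at pixel offsets
#'
#' @param kernel a \linkS4class{SpreadKernel}.
#' @param dx,dy offsets from the kernel center in pixels.
#' @return Kernel values exp(-(dx^2 + dy^2) / (2 sigma^2)), peak 1 at 0.
#' @export
spreadKernelValue <- function(kernel, dx, dy) {
    stopifnot(is(kernel, "SpreadKernel"))
    exp(-(dx^2 + dy^2) / (2 * kernel@sigma^2))
}

#' Centroid-spread map score
#'
#' Scores a frame by how concentrated its salience mass is around its own
#' centroid: the map is weighted by a Gaussian kernel centered at the
#' salience centroid and the weighted mass is divided by the total mass.
#' A single concentrated peak scores 1; widely spread mass scores near 0.
#' The ratio form makes the score invariant to rescaling the map by any
#' positive constant. Zero-mass frames score 0 (reported via one warning).
#'
#' @param seq a \linkS4class{SalienceMapSequence}.
#' @param thetaS spatial scale (normalized units) setting the kernel
#'   bandwidth through \code{\link{makeSpreadKernel}}.
#' @return A \linkS4class{SalienceSeries} in [0, 1].
#' @export
scoreSpread <- function(seq, thetaS = 0.1) {
    stopifnot(is(seq, "SalienceMapSequence"), thetaS > 0)
    d <- dim(seq@maps[[1]])
    H <- d[1]; W <- d[2]
    kernel <- makeSpreadKernel(W, thetaS)
    X <- matrix(rep(0:(W - 1), each = H), H, W)
    Y <- matrix(rep(0:(H - 1), W), H, W)
    zero <- 0L
    vals <- vapply(seq@maps, function(m) {
        mass <- sum(m)
        if (mass == 0) { zero <<- zero + 1L; return(0) }
        ctr <- salienceCentroid(m)
        G <- spreadKernelValue(kernel, X - ctr[["x"]], Y - ctr[["y"]])
        sum(m * G) / mass
    }, numeric(1))
    if (zero > 0L)
        warning(sprintf("%d zero-mass map(s) scored 0", zero))
    SalienceSeries(vals, range = c(0, 1),
                   label = sprintf("spread thetaS=%g", thetaS))
}

#' Threshold a salience map to a binary map
#'
#' Default thresholding is Otsu's criterion (maximizing between-class
#' variance on a 256-level quantization); alternatively a fixed fraction
#' of the map maximum. Pixels strictly above the threshold are set.
#' A constant map gives Otsu nothing to separate: the result is an empty
#' binary map, with a warning.
#'
#' @param map a nonnegative numeric matrix.
#' @param method \code{"otsu"} (default), \code{"fixed"}, or the string
#'   form \code{"fixed:<f>"} giving the fraction inline.
#' @param fraction fraction of the map maximum used when
#'   \code{method = "fixed"} (default 0.5).
#' @return A logical matrix with attribute \code{"threshold"}.
#' @examples
#' binarizeMap(matrix(c(0, 10, 10, 10), 2, 2), method = "fixed:0.5")
#' @export
binarizeMap <- function(map, method = "otsu", fraction = 0.5) {
    map <- as.matrix(map)
    if (any(map < 0)) stop("map must be nonnegative")
    if (grepl("^fixed:", method)) {
        fraction <- as.numeric(sub("^fixed:", "", method))
        method <- "fixed"
    }
    method <- match.arg(method, c("otsu", "fixed"))
    mx <- max(map)
    if (method == "fixed") {
        if (is.na(fraction) || fraction < 0 || fraction > 1)
            stop("fixed-threshold fraction must be in [0, 1]")
        thr <- fraction * mx
    } else {
        if (mx == min(map)) {
            warning("constant map: Otsu undefined, returning empty binary map")
            B <- matrix(FALSE, nrow(map), ncol(map))
            attr(B, "threshold") <- mx
            return(B)
        }
        thr <- EBImage::otsu(map / mx, range = c(0, 1), levels = 256) * mx
    }
    B <- map > thr
    attr(B, "threshold") <- thr
    B
}

# Label 8-connected components of a logical matrix by iterative frontier
# expansion; returns an integer matrix (0 = background).
.labelComponents8 <- function(B) {
    nr <- nrow(B); nc <- ncol(B)
    lab <- matrix(0L, nr, nc)
    cur <- 0L
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    for (i in which(B)) {
        if (lab[i]) next
        cur <- cur + 1L
        lab[i] <- cur
        frontier <- i
        while (length(frontier)) {
            r <- (frontier - 1L) %% nr + 1L
            cc <- (frontier - 1L) %/% nr + 1L
            nbr <- rep(r, each = 8L) + dr
            nbc <- rep(cc, each = 8L) + dc
            keep <- nbr >= 1L & nbr <= nr & nbc >= 1L & nbc <= nc
            ni <- unique((nbc[keep] - 1L) * nr + nbr[keep])
            ni <- ni[B[ni] & lab[ni] == 0L]
            lab[ni] <- cur
            frontier <- ni
        }
    }
    lab
}

#' Centroids of the connected components of a binary map
#'
#' Components are 8-connected. Each component's centroid is the mean of
#' its 0-based pixel coordinates, then normalized to the unit square by
#' dividing x by W and y by H — so the centroids are directly usable as
#' surrogate gaze points under the normalized spatial scale.
#'
#' @param B a logical matrix (as from \code{\link{binarizeMap}}).
#' @return A \linkS4class{ComponentSet}; empty maps give zero centroids.
#' @export
componentCentroids <- function(B) {
    B <- as.matrix(B)
    thr <- attr(B, "threshold")
    if (is.null(thr)) thr <- NA_real_
    mode(B) <- "logical"
    nr <- nrow(B); nc <- ncol(B)
    lab <- .labelComponents8(B)
    k <- max(lab)
    if (k == 0L) {
        cen <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
    } else {
        idx <- which(lab > 0L)
        px <- (idx - 1L) %/% nr      # 0-based column = x
        py <- (idx - 1L) %% nr       # 0-based row = y
        g <- lab[idx]
        cen <- cbind(
            x = as.vector(tapply(px, g, mean)) / nc,
            y = as.vector(tapply(py, g, mean)) / nr)
    }
    new("ComponentSet", binaryMap = B, centroids = cen,
        threshold = as.numeric(thr))
}

#' Point-hypotheses map score
#'
#' Turns each map into surrogate "gaze" points — the centroids of the
#' connected components of the thresholded map — and scores them exactly
#' like multi-observer gaze: centroids are pooled over the temporal window
#' [t - thetaT, t + thetaT] (clipped at the boundaries) and scored by the
#' fraction of pairs closer than thetaS. Noisy, multi-modal maps thereby
#' provide the data variability that a single clean map lacks.
#'
#' Frames whose window yields fewer than two centroids score 0 (one
#' aggregate warning).
#'
#' @param seq a \linkS4class{SalienceMapSequence}.
#' @param params a \linkS4class{GlimpseParams}.
#' @param method,fraction thresholding, as in \code{\link{binarizeMap}}.
#' @return A \linkS4class{SalienceSeries} in [0, 1].
#' @export
scorePoints <- function(seq, params = GlimpseParams(), method = "otsu",
                        fraction = 0.5) {
    stopifnot(is(seq, "SalienceMapSequence"), is(params, "GlimpseParams"))
    Tn <- length(seq@maps)
    perFrame <- lapply(seq@maps, function(m)
        centroids(componentCentroids(binarizeMap(m, method, fraction))))
    vals <- numeric(Tn)
    degenerate <- 0L
    for (t in seq_len(Tn)) {
        w <- max(1L, t - params@thetaT):min(Tn, t + params@thetaT)
        bag <- do.call(rbind, perFrame[w])
        if (is.null(bag) || nrow(bag) < 2L) {
            degenerate <- degenerate + 1L
            vals[t] <- 0
        } else {
            vals[t] <- pairConsistency(bag, params@thetaS)
        }
    }
    if (degenerate > 0L)
        warning(sprintf(
            "%d frame(s) had fewer than 2 centroids in the window; scored 0",
            degenerate))
    SalienceSeries(vals, range = c(0, 1),
                   label = sprintf("points thetaS=%g thetaT=%d %s",
                                   params@thetaS, params@thetaT, method))
}
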