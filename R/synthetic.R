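#' Construct a synthetic viewing scenario
#'
#' Defines the ground truth from which \code{\link{generateGaze}} and
#' \code{\link{generateSalienceMaps}} draw: at each frame, an attending
#' observer looks at the scripted attractor location plus isotropic
#' Gaussian jitter, while a non-attending observer looks uniformly at
#' random; attending states persist over frames (two-state Markov chain
#' per observer), giving the temporal autocorrelation characteristic of
#' real gaze. The defaults emulate a typical eye-tracking panel watching
#' a moderately engaging clip: 20 observers, 200 frames (8 s at 25 fps),
#' a slowly circling attractor, and an event-structured attended
#' fraction — background attention 0.15 with a high-attention segment
#' (0.85) over the middle third of the clip — so the generated data
#' carry a salient temporal event by default. Gaze cluster spread is
#' 0.03 (a third of the default spatial scale 0.1).
#'
#' @param N observers (default 20).
#' @param T frames (default 200).
#' @param attractor T x 2 matrix of attended locations in the unit
#'   square, a single \code{c(x, y)} point recycled to all frames, or
#'   NULL for the default circular path (center (0.5, 0.5), radius 0.25,
#'   one revolution over the clip).
#' @param alpha attended fraction per frame in [0, 1]; a scalar is
#'   recycled to all frames; NULL (default) gives the event profile
#'   0.15 / 0.85 / 0.15 over thirds of the clip.
#' @param clusterSd spread of attended gaze, normalized units (0.03).
#' @param mapSize map width and height in pixels (default 64 x 64).
#' @param blobSd map blob spread in pixels (default 4).
#' @param noiseSd additive map noise sd, clipped at zero (default 0.02).
#' @param switchProb per-frame probability of re-drawing the attending
#'   state (default 0.05; lower = more persistent observers).
#' @param clip clip gaze to the unit square, emulating on-screen viewing
#'   (default TRUE).
#' @param seed RNG seed (default 1).
#' @return A \linkS4class{Scenario}.
#' @examples
#' Scenario(N = 10, T = 50, alpha = 0.5, seed = 42)
#' @export
Scenario <- function(N = 20L, T = 200L, attractor = NULL, alpha = NULL,
                     clusterSd = 0.03, mapSize = c(64L, 64L), blobSd = 4,
                     noiseSd = 0.02, switchProb = 0.05, clip = TRUE,
                     seed = 1L) {
    N <- as.integer(N); T <- as.integer(T)
    if (is.null(attractor)) {
        ang <- 2 * pi * (seq_len(T) - 1) / max(T, 1L)
        attractor <- cbind(0.5 + 0.25 * cos(ang), 0.5 + 0.25 * sin(ang))
    } else if (is.numeric(attractor) && length(attractor) == 2L) {
        attractor <- matrix(attractor, T, 2, byrow = TRUE)
    } else {
        attractor <- as.matrix(attractor)
    }
    if (is.null(alpha)) {
        alpha <- rep(0.15, T)
        alpha[seq_len(T) > T / 3 & seq_len(T) <= 2 * T / 3] <- 0.85
    } else if (length(alpha) == 1L) {
        alpha <- rep(alpha, T)
    }
    new("Scenario", N = N, T = T, attractor = attractor,
        alpha = as.numeric(alpha), clusterSd = as.numeric(clusterSd),
        mapSize = as.integer(mapSize), blobSd = as.numeric(blobSd),
        noiseSd = as.numeric(noiseSd), switchProb = as.numeric(switchProb),
        clip = isTRUE(clip), seed = as.integer(seed))
}

#' Generate multi-observer gaze from a scenario
#'
#' Per observer and frame: with the observer currently attending, gaze is
#' the attractor location plus isotropic Gaussian jitter of sd
#' \code{clusterSd} (clipped to the unit square when \code{clip});
#' otherwise gaze is uniform on the unit square. The attending state is
#' initialized Bernoulli(alpha(1)) and at each later frame is re-drawn
#' Bernoulli(alpha(t)) with probability \code{switchProb}, else carried
#' over — so the marginal attending fraction tracks alpha(t) while
#' consecutive frames stay correlated. Identical scenarios (including
#' seed) give identical datasets.
#'
#' @param sc a \linkS4class{Scenario}.
#' @return A normalized \linkS4class{GazeDataset} (W, H from
#'   \code{mapSize}).
#' @examples
#' gd <- generateGaze(Scenario(N = 5, T = 20, seed = 9))
#' nObservers(gd); nFrames(gd)
#' @export
generateGaze <- function(sc) {
    stopifnot(is(sc, "Scenario"))
    validObject(sc)
    .withSeed(sc@seed, {
        N <- sc@N; Tn <- sc@T
        x <- matrix(NA_real_, N, Tn)
        y <- matrix(NA_real_, N, Tn)
        state <- stats::runif(N) < sc@alpha[1]
        for (t in seq_len(Tn)) {
            if (t > 1L) {
                redraw <- stats::runif(N) < sc@switchProb
                state[redraw] <- stats::runif(sum(redraw)) < sc@alpha[t]
            }
            na <- sum(state)
            if (na > 0L) {
                x[state, t] <- sc@attractor[t, 1] +
                    stats::rnorm(na, 0, sc@clusterSd)
                y[state, t] <- sc@attractor[t, 2] +
                    stats::rnorm(na, 0, sc@clusterSd)
            }
            if (na < N) {
                x[!state, t] <- stats::runif(N - na)
                y[!state, t] <- stats::runif(N - na)
            }
        }
        if (sc@clip) {
            x <- pmin(pmax(x, 0), 1)
            y <- pmin(pmax(y, 0), 1)
        }
        GazeDataset(x, y, width = sc@mapSize[1], height = sc@mapSize[2],
                    normalized = TRUE)
    })
}

#' Generate matching salience maps from a scenario
#'
#' Each frame is a W x H map with an isotropic Gaussian blob (sd
#' \code{blobSd} pixels, peak alpha(t)) at the attractor location, plus
#' nonnegative (zero-clipped) Gaussian noise of sd \code{noiseSd}. The
#' map stream is seeded independently of the gaze stream so the two can
#' be generated in either order.
#'
#' @param sc a \linkS4class{Scenario}.
#' @return A \linkS4class{SalienceMapSequence} with value scale 1.
#' @examples
#' seq <- generateSalienceMaps(Scenario(N = 5, T = 10, noiseSd = 0))
#' length(seq)
#' @export
generateSalienceMaps <- function(sc) {
    stopifnot(is(sc, "Scenario"))
    validObject(sc)
    W <- sc@mapSize[1]; H <- sc@mapSize[2]
    X <- matrix(rep(0:(W - 1), each = H), H, W)
    Y <- matrix(rep(0:(H - 1), W), H, W)
    .withSeed(sc@seed + 10007L, {
        maps <- lapply(seq_len(sc@T), function(t) {
            cx <- sc@attractor[t, 1] * W
            cy <- sc@attractor[t, 2] * H
            blob <- if (sc@blobSd > 0)
                sc@alpha[t] *
                    exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sc@blobSd^2))
            else matrix(0, H, W)
            if (sc@noiseSd > 0)
                blob <- blob + pmax(matrix(stats::rnorm(H * W, 0,
                                                        sc@noiseSd), H, W), 0)
            blob
        })
        SalienceMapSequence(maps, valueScale = 1)
    })
}

#' Probability that two uniform points in the unit square are close
#'
#' The closed-form probability that two independent uniform points in the
#' unit square lie at Euclidean distance below thetaS, valid for
#' 0 <= thetaS <= 1:
#' pi thetaS^2 - (8/3) thetaS^3 + thetaS^4 / 2.
#' This is the expected consistency score of completely inconsistent
#' (uniform) gaze — the analytic floor against which structured gaze is
#' judged. The regime thetaS in (1, sqrt(2)] has a different closed form
#' and is not implemented.
#'
#' @param thetaS distance threshold in [0, 1].
#' @return The pair probability.
#' @examples
#' uniformPairProbability(0.1)  # about 0.0288
#' @export
uniformPairProbability <- function(thetaS) {
    if (any(thetaS < 0) || any(thetaS > sqrt(2)))
        stop("thetaS must lie in [0, sqrt(2)]")
    if (any(thetaS > 1))
        stop("thetaS in (1, sqrt(2)] is outside the implemented regime")
    pi * thetaS^2 - (8 / 3) * thetaS^3 + thetaS^4 / 2
}
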