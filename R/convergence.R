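# Run expr with a temporarily seeded RNG, restoring the caller's state.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit({
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Number of distinct observer subsets
#'
#' The binomial coefficient choose(N, k), computed by the multiplicative
#' formula; exact for results below 2^53 (far beyond any realistic
#' observer panel).
#'
#' @param N total observers.
#' @param k subset size, 0 <= k <= N.
#' @return The exact count.
#' @examples
#' countObserverCombinations(58, 3)  # 30856
#' @export
countObserverCombinations <- function(N, k) {
    if (length(N) != 1L || length(k) != 1L || is.na(N) || is.na(k) ||
        N != round(N) || k != round(k))
        stop("N and k must be single integers")
    if (N < 0 || k < 0 || k > N)
        stop("need 0 <= k <= N")
    k <- min(k, N - k)
    res <- 1
    for (i in seq_len(k)) res <- res * (N - k + i) / i
    round(res)
}

# TRUE if choose(N, k) <= cap, without computing huge coefficients.
.combinationsAtMost <- function(N, k, cap) {
    k <- min(k, N - k)
    res <- 1
    for (i in seq_len(k)) {
        res <- res * (N - k + i) / i
        if (res > cap) return(FALSE)
    }
    TRUE
}

#' Sample distinct observer subsets of size k
#'
#' If there are at most \code{pmax} distinct k-subsets they are all
#' enumerated (no sampling noise); otherwise \code{pmax} distinct subsets
#' are drawn uniformly, reproducibly under \code{seed}.
#'
#' @param N total observers.
#' @param k subset size, 1 <= k <= N.
#' @param pmax cap on the number of subsets (default 400).
#' @param seed RNG seed (NULL = use current RNG state).
#' @return A list of sorted integer vectors, each of length k.
#' @examples
#' length(sampleObserverSubsets(5, 2, pmax = 400))  # all 10 pairs
#' @export
sampleObserverSubsets <- function(N, k, pmax = 400L, seed = NULL) {
    stopifnot(N >= 1L, k >= 1L, k <= N, pmax >= 1L)
    N <- as.integer(N); k <- as.integer(k); pmax <- as.integer(pmax)
    if (.combinationsAtMost(N, k, pmax)) {
        cmb <- utils::combn(N, k)
        return(lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
    }
    .withSeed(seed, {
        seen <- new.env(hash = TRUE)
        out <- vector("list", pmax)
        got <- 0L
        while (got < pmax) {
            s <- sort(sample.int(N, k))
            key <- paste(s, collapse = ",")
            if (is.null(seen[[key]])) {
                seen[[key]] <- TRUE
                got <- got + 1L
                out[[got]] <- s
            }
        }
        out
    })
}

#' Observer-count convergence of the salience score
#'
#' How many observers are enough? For each k = 1..N, draws up to
#' \code{pmax} distinct k-subsets of observers, recomputes the salience
#' series from each subset's gaze alone, and measures its
#' length-normalized distance to the all-observer series. The mean
#' distance per k (with its standard error) quantifies how quickly the
#' score stabilizes as observers are added; it is exactly 0 at k = N.
#'
#' @param dataset a normalized \linkS4class{GazeDataset} with N >= 2.
#' @param params a \linkS4class{GlimpseParams}.
#' @param pmax cap on subsets per k (default 400).
#' @param seed RNG seed for subset sampling.
#' @return A \linkS4class{ConvergenceResult}.
#' @examples
#' sc <- Scenario(N = 6, T = 30, seed = 3)
#' convergenceCurve(generateGaze(sc), pmax = 20, seed = 1)
#' @export
convergenceCurve <- function(dataset, params = GlimpseParams(),
                             pmax = 400L, seed = 1L) {
    stopifnot(is(dataset, "GazeDataset"))
    N <- nObservers(dataset)
    if (N < 2L) stop("convergence analysis needs at least 2 observers")
    sN <- scores(suppressWarnings(temporalSalience(dataset, params)))
    ks <- seq_len(N)
    meanD <- stderrD <- numeric(N)
    pOfK <- integer(N)
    for (k in ks) {
        subsets <- sampleObserverSubsets(N, k, pmax = pmax,
                                         seed = seed + k)
        ds <- vapply(subsets, function(obs) {
            sk <- scores(suppressWarnings(
                temporalSalience(dataset[obs, ], params)))
            signalDistance(sk, sN)
        }, numeric(1))
        pOfK[k] <- length(subsets)
        meanD[k] <- mean(ds)
        stderrD[k] <- if (length(ds) > 1L)
            stats::sd(ds) / sqrt(length(ds)) else NA_real_
    }
    new("ConvergenceResult", ks = ks, pOfK = pOfK, meanD = meanD,
        stderrD = stderrD, pmax = as.integer(pmax), seed = as.integer(seed))
}
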