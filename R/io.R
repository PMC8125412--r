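#' Read a gaze CSV into a GazeDataset
#'
#' Two layouts are accepted, distinguished by the header: aggregated
#' (\code{observer,frame,x,y}, 1-based integer frames, at most one row per
#' observer and frame) or raw (\code{observer,time,x,y}, timestamps in
#' seconds, averaged into frames via \code{\link{aggregateToFrames}},
#' which requires \code{frameRate}). Empty x or y cells mark missing
#' samples. Malformed rows are rejected with line-numbered messages.
#'
#' @param path CSV file path.
#' @param width,height source frame size in pixels.
#' @param frameRate frames per second (required for raw timestamped
#'   input).
#' @return A pixel-unit \linkS4class{GazeDataset}; a summary (observers,
#'   frames, missing count) is reported via \code{message}.
#' @export
readGazeCSV <- function(path, width, height, frameRate = NA_real_) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    df <- utils::read.csv(path, colClasses = "character",
                          strip.white = TRUE)
    hdr <- names(df)
    raw <- all(c("observer", "time", "x", "y") %in% hdr)
    agg <- all(c("observer", "frame", "x", "y") %in% hdr)
    if (!raw && !agg)
        stop("header must be observer,frame,x,y or observer,time,x,y")
    tcol <- if (raw) "time" else "frame"
    lineOf <- function(i) i + 1L  # header is line 1
    num <- function(col, allowBlank = FALSE) {
        v <- df[[col]]
        blank <- !nzchar(v)
        out <- suppressWarnings(as.numeric(v))
        bad <- which(is.na(out) & !blank)
        if (length(bad))
            stop(sprintf("non-numeric '%s' value at line %d: '%s'",
                         col, lineOf(bad[1]), v[bad[1]]))
        if (!allowBlank && any(blank))
            stop(sprintf("blank '%s' value at line %d", col,
                         lineOf(which(blank)[1])))
        out
    }
    obs <- num("observer")
    tv <- num(tcol)
    x <- num("x", allowBlank = TRUE)
    y <- num("y", allowBlank = TRUE)
    if (agg) {
        if (any(tv != round(tv) | tv < 1))
            stop(sprintf("frame must be a positive integer at line %d",
                         lineOf(which(tv != round(tv) | tv < 1)[1])))
        dup <- which(duplicated(cbind(obs, tv)))
        if (length(dup))
            stop(sprintf("duplicate (observer, frame) row at line %d",
                         lineOf(dup[1])))
        ids <- sort(unique(obs))
        Tn <- as.integer(max(tv))
        X <- matrix(NA_real_, length(ids), Tn)
        Y <- matrix(NA_real_, length(ids), Tn)
        pos <- cbind(match(obs, ids), as.integer(tv))
        X[pos] <- x
        Y[pos] <- y
        out <- GazeDataset(X, Y, width = width, height = height,
                           frameRate = frameRate)
    } else {
        if (is.na(frameRate))
            stop("frameRate is required for timestamped gaze input")
        out <- aggregateToFrames(
            data.frame(observer = obs, time = tv, x = x, y = y),
            frameRate = frameRate, width = width, height = height)
    }
    message(sprintf(
        "readGazeCSV: %d observer(s), %d frame(s), %d missing sample(s)",
        nObservers(out), nFrames(out), sum(is.na(out@x))))
    out
}

#' Write a salience series as a scores CSV
#'
#' Writes \code{frame,score} with 1-based frames and 6-decimal scores;
#' \code{\link{readScores}} reproduces the series to 1e-6.
#'
#' @param series a \linkS4class{SalienceSeries}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeScores <- function(series, path) {
    v <- .signalValues(series)
    lines <- c("frame,score",
               if (length(v)) sprintf("%d,%.6f", seq_along(v), v))
    writeLines(lines, path)
    invisible(path)
}

#' Read a scores CSV as a salience series
#'
#' @param path a \code{frame,score} CSV as written by
#'   \code{\link{writeScores}}.
#' @return A \linkS4class{SalienceSeries}; the declared range is [0, 1]
#'   when all scores fit it, otherwise the observed range.
#' @export
readScores <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    df <- utils::read.csv(path)
    if (!all(c("frame", "score") %in% names(df)))
        stop("scores CSV must have header frame,score")
    v <- as.numeric(df$score[order(df$frame)])
    rng <- if (!length(v) || (min(v) >= 0 && max(v) <= 1)) c(0, 1)
           else range(v)
    SalienceSeries(v, range = rng, label = basename(path))
}

#' Read a list of change-point frames
#'
#' One frame index per line (blank lines and \code{#} comments ignored).
#'
#' @param path text file path.
#' @return Integer vector of frame indices.
#' @export
readChangepoints <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    v <- suppressWarnings(as.integer(lines))
    if (anyNA(v)) stop("changepoint file must hold one integer per line")
    v
}

#' Read a salience-map sequence
#'
#' Accepts either a directory of grayscale PNG files named
#' \code{frame_\%06d.png} (consecutive indices; a gap is an error; RGB
#' input is converted to grayscale by luminance with a warning) or an
#' \code{.rds} file holding a numeric array of shape (T, H, W).
#'
#' @param path directory or .rds file path.
#' @param valueScale declared maximum of the value encoding; PNG values
#'   (read in [0, 1]) are multiplied by it so stored magnitudes are
#'   recovered.
#' @return A \linkS4class{SalienceMapSequence}.
#' @export
readMapSequence <- function(path, valueScale = 1) {
    if (dir.exists(path)) {
        files <- list.files(path, pattern = "^frame_[0-9]{6}\\.png$")
        if (!length(files))
            stop(sprintf("no frame_%%06d.png files in %s", path))
        idx <- as.integer(sub("^frame_([0-9]{6})\\.png$", "\\1", files))
        files <- files[order(idx)]
        idx <- sort(idx)
        if (any(diff(idx) != 1L))
            stop(sprintf("gap in frame numbering: missing frame %06d",
                         idx[which(diff(idx) != 1L)[1]] + 1L))
        rgbSeen <- FALSE
        maps <- lapply(file.path(path, files), function(f) {
            img <- png::readPNG(f)
            if (length(dim(img)) == 3L) {
                rgbSeen <<- TRUE
                img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] +
                    0.0722 * img[, , 3]
            }
            img * valueScale
        })
        if (rgbSeen)
            warning("RGB map(s) converted to grayscale by luminance")
    } else if (file.exists(path)) {
        arr <- readRDS(path)
        if (!is.array(arr) || length(dim(arr)) != 3L)
            stop("array container must hold a (T, H, W) numeric array")
        maps <- lapply(seq_len(dim(arr)[1]), function(t) arr[t, , ])
    } else {
        stop(sprintf("path not found: %s", path))
    }
    SalienceMapSequence(maps, valueScale = valueScale)
}

#' Write a salience-map sequence as grayscale PNGs
#'
#' Writes \code{frame_\%06d.png} (1-based) into \code{dir}, rescaling by
#' the sequence's value scale into [0, 1].
#'
#' @param seq a \linkS4class{SalienceMapSequence}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeMapSequence <- function(seq, dir) {
    stopifnot(is(seq, "SalienceMapSequence"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (t in seq_along(seq@maps)) {
        m <- pmin(pmax(seq@maps[[t]] / seq@valueScale, 0), 1)
        png::writePNG(m, file.path(dir, sprintf("frame_%06d.png", t)))
    }
    invisible(dir)
}
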