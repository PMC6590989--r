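## TIRF spot detection, tracking, and the co-movement colocalization score.
##
## Coordinates: x = row index, y = column index of the frame matrix, in
## pixels, sub-pixel resolution after centroid refinement.

.asMatrix <- function(img) {
  if (is(img, "Image")) EBImage::imageData(img) else img
}

## band-pass centred on the spot scale; the narrow kernel pair (sigma/sqrt2,
## sigma*sqrt2) keeps neighbouring spots >~ 2.5 px apart resolvable
.dog <- function(frame, sigma) {
  im <- EBImage::Image(frame)
  g1 <- .asMatrix(EBImage::gblur(im, sigma = sigma / sqrt(2)))
  g2 <- .asMatrix(EBImage::gblur(im, sigma = sigma * sqrt(2)))
  g1 - g2
}

#' Detect diffraction-limited spots in an image stack
#'
#' Band-pass filters each frame with a difference of Gaussians (kernels
#' sigma/sqrt(2) and sigma*sqrt(2), a constant-bandwidth pair centred on
#' the spot scale), finds local maxima exceeding the frame's background median
#' plus \code{k} robust standard deviations (MAD-based) of the band-pass
#' response, and refines each maximum to sub-pixel precision by intensity
#' centroid over a local window.
#'
#' @param frames an H x W x T numeric array, a single H x W matrix, or a
#'   \linkS4class{FrameStack} channel.
#' @param sigma spot scale in pixels (approximately the PSF sigma;
#'   default 1.5).
#' @param k detection threshold in robust SDs above the band-pass median
#'   (default 5).
#' @param minSeparation minimum distance between detections in pixels;
#'   within it only the strongest peak survives (default 2, about the
#'   diffraction-limited resolution at the default sigma).
#' @return data.frame with columns frame, x, y, intensity.
#' @export
detectSpots <- function(frames, sigma = 1.5, k = 5, minSeparation = 2) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1))
  nT <- dim(frames)[3]
  out <- vector("list", nT)
  for (t in seq_len(nT)) {
    fr <- frames[, , t]
    if (max(fr) == min(fr)) next              # constant frame: no spots
    d <- .dog(fr, sigma)
    thr <- stats::median(d) + k * stats::mad(d)
    if (stats::mad(d) == 0) thr <- stats::median(d) + k * stats::sd(d)
    mx <- .asMatrix(EBImage::dilate(EBImage::Image(d),
                                    EBImage::makeBrush(3, "box")))
    peaks <- which(d >= mx & d > thr, arr.ind = TRUE)
    if (nrow(peaks) == 0) next
    # non-maximum suppression: one detection per resolvable spot
    if (nrow(peaks) > 1) {
      ord <- order(d[peaks], decreasing = TRUE)
      peaks <- peaks[ord, , drop = FALSE]
      keep <- rep(TRUE, nrow(peaks))
      for (p in 2:nrow(peaks)) {
        dd <- sqrt((peaks[seq_len(p - 1), 1] - peaks[p, 1])^2 +
                   (peaks[seq_len(p - 1), 2] - peaks[p, 2])^2)
        if (any(dd[keep[seq_len(p - 1)]] < minSeparation)) keep[p] <- FALSE
      }
      peaks <- peaks[keep, , drop = FALSE]
    }
    r <- max(2L, ceiling(sigma))
    H <- nrow(fr); W <- ncol(fr)
    res <- matrix(NA_real_, nrow(peaks), 3)
    for (p in seq_len(nrow(peaks))) {
      i <- peaks[p, 1]; j <- peaks[p, 2]
      ii <- max(1, i - r):min(H, i + r)
      jj <- max(1, j - r):min(W, j + r)
      w <- pmax(d[ii, jj, drop = FALSE], 0)
      if (sum(w) == 0) { res[p, ] <- c(i, j, fr[i, j]); next }
      res[p, 1] <- sum(outer(ii, rep(1, length(jj))) * w) / sum(w)
      res[p, 2] <- sum(outer(rep(1, length(ii)), jj) * w) / sum(w)
      res[p, 3] <- fr[i, j]
    }
    out[[t]] <- data.frame(frame = t, x = res[, 1], y = res[, 2],
                           intensity = res[, 3])
  }
  found <- do.call(rbind, out)
  if (is.null(found))
    data.frame(frame = integer(), x = numeric(), y = numeric(),
               intensity = numeric())
  else found
}

#' Link per-frame detections into tracks
#'
#' Frame-to-frame nearest-neighbour assignment, greedy by ascending pair
#' distance; a link is made only when the distance is at most \code{rLink}.
#' Unmatched detections open new tracks.  No gap closing: track frames are
#' strictly consecutive.
#'
#' @param spots data.frame from [detectSpots()] (frame, x, y, intensity).
#' @param rLink maximum linking distance in pixels.
#' @return data.frame with columns track_id, frame, x, y, intensity.
#' @export
linkTracks <- function(spots, rLink = 4) {
  if (rLink <= 0) stop("rLink must be > 0")
  if (nrow(spots) == 0)
    return(cbind(data.frame(track_id = integer()), spots))
  spots <- spots[order(spots$frame), ]
  spots$track_id <- NA_integer_
  frames <- sort(unique(spots$frame))
  nextId <- 1L
  idx <- which(spots$frame == frames[1])
  spots$track_id[idx] <- seq(nextId, length.out = length(idx))
  nextId <- nextId + length(idx)
  for (f in frames[-1]) {
    cur <- which(spots$frame == f)
    prev <- which(spots$frame == f - 1)          # consecutive frames only
    if (length(prev) && length(cur)) {
      dmat <- sqrt(outer(spots$x[prev], spots$x[cur], "-")^2 +
                   outer(spots$y[prev], spots$y[cur], "-")^2)
      ord <- order(dmat)
      usedP <- logical(length(prev)); usedC <- logical(length(cur))
      for (o in ord) {
        if (dmat[o] > rLink) break
        pi <- (o - 1) %% length(prev) + 1
        ci <- (o - 1) %/% length(prev) + 1
        if (usedP[pi] || usedC[ci]) next
        usedP[pi] <- TRUE; usedC[ci] <- TRUE
        spots$track_id[cur[ci]] <- spots$track_id[prev[pi]]
      }
    }
    new <- cur[is.na(spots$track_id[cur])]
    if (length(new)) {
      spots$track_id[new] <- seq(nextId, length.out = length(new))
      nextId <- nextId + length(new)
    }
  }
  rownames(spots) <- NULL
  spots[, c("track_id", "frame", "x", "y", "intensity")]
}

.trackList <- function(tracks) {
  split(tracks[, c("frame", "x", "y")], tracks$track_id)
}

## longest run of TRUE in a logical vector, plus the run table
.runs <- function(flag) {
  if (length(flag) == 0) return(data.frame(start = integer(), length = integer()))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], length = r$lengths[r$values])
}

#' Score dynamic colocalization by the co-movement rule
#'
#' A red track counts as colocalized when some green track stays within
#' \code{rPair} pixels of it on at least \code{minConsecutive} consecutive
#' shared frames; shorter coincidences are rejected as chance encounters.
#' The percentage is taken over red tracks at least \code{minConsecutive}
#' frames long (configurable to the green or union denominator).
#'
#' @param redTracks,greenTracks track data.frames from [linkTracks()].
#' @param rPair pairing radius in pixels (default 3).
#' @param minConsecutive minimum consecutive paired frames (default 3).
#' @param denominator which channel's tracks define the percentage:
#'   "red" (default), "green" or "union".
#' @param greenFrameOffset frames added to green timestamps to correct for
#'   sequential excitation (default 0).
#' @return a \linkS4class{ColocResult}.
#' @export
scoreComovement <- function(redTracks, greenTracks, rPair = 3,
                            minConsecutive = 3L,
                            denominator = c("red", "green", "union"),
                            greenFrameOffset = 0L) {
  if (minConsecutive < 1) stop("minConsecutive must be >= 1")
  denominator <- match.arg(denominator)
  if (nrow(greenTracks)) greenTracks$frame <- greenTracks$frame + greenFrameOffset

  score <- function(aTracks, bTracks) {
    aL <- .trackList(aTracks); bL <- .trackList(bTracks)
    aL <- aL[vapply(aL, nrow, 1L) >= minConsecutive]
    coloc <- logical(length(aL))
    episodes <- list()
    for (i in seq_along(aL)) {
      ta <- aL[[i]]
      for (j in seq_along(bL)) {
        tb <- bL[[j]]
        shared <- intersect(ta$frame, tb$frame)
        if (length(shared) < minConsecutive) next
        shared <- sort(shared)
        da <- ta[match(shared, ta$frame), ]
        db <- tb[match(shared, tb$frame), ]
        near <- sqrt((da$x - db$x)^2 + (da$y - db$y)^2) <= rPair
        # runs must be consecutive in frame number, not just in shared order
        breaks <- c(TRUE, diff(shared) != 1)
        grp <- cumsum(breaks)
        for (g in unique(grp)) {
          sel <- grp == g
          rn <- .runs(near[sel])
          rn <- rn[rn$length >= minConsecutive, , drop = FALSE]
          if (nrow(rn)) {
            coloc[i] <- TRUE
            episodes[[length(episodes) + 1]] <- data.frame(
              red_id = names(aL)[i], green_id = names(bL)[j],
              start_frame = shared[sel][rn$start], length = rn$length)
          }
        }
      }
    }
    list(n = length(aL), nColoc = sum(coloc),
         episodes = if (length(episodes)) do.call(rbind, episodes)
                    else data.frame(red_id = character(), green_id = character(),
                                    start_frame = integer(), length = integer()))
  }

  r <- score(redTracks, greenTracks)
  if (denominator == "red") {
    n <- r$n; nc <- r$nColoc
  } else {
    g <- score(greenTracks, redTracks)
    if (denominator == "green") { n <- g$n; nc <- g$nColoc }
    else { n <- r$n + g$n; nc <- r$nColoc + g$nColoc }
  }
  new("ColocResult",
      nRedTracks = as.integer(n), nColocRedTracks = as.integer(nc),
      percentage = if (n > 0) 100 * nc / n else NA_real_,
      episodes = DataFrame(r$episodes),
      parameters = list(rPair = rPair, minConsecutive = minConsecutive,
                        denominator = denominator,
                        greenFrameOffset = greenFrameOffset))
}

#' Run the full co-movement pipeline on a two-channel stack
#'
#' Convenience wrapper: detect spots in both channels, link tracks, score
#' co-movement.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @inheritParams detectSpots
#' @inheritParams linkTracks
#' @inheritParams scoreComovement
#' @return list with \code{result} (\linkS4class{ColocResult}),
#'   \code{redTracks}, \code{greenTracks}.
#' @export
tirfColoc <- function(stack, sigma = 1.5, k = 5, rLink = 4, rPair = 3,
                      minConsecutive = 3L) {
  red <- linkTracks(detectSpots(stack@red, sigma, k), rLink)
  green <- linkTracks(detectSpots(stack@green, sigma, k), rLink)
  list(result = scoreComovement(red, green, rPair, minConsecutive),
       redTracks = red, greenTracks = green)
}

#' Write / read a two-channel stack as multi-page TIFF
#'
#' 16-bit storage; intensities are divided by 65535 on write and rescaled
#' on read, so integer intensities up to 65535 round-trip exactly.
#' Negative values (read-noise excursions) clamp to 0, as on a real camera.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param file TIFF path.
#' @param dialect page order: "stacked" (all red pages then all green) or
#'   "interleaved" (red1, green1, red2, ...).
#' @export
writeFrameStack <- function(stack, file, dialect = c("stacked", "interleaved")) {
  dialect <- match.arg(dialect)
  nT <- dim(stack@red)[3]
  pages <- vector("list", 2 * nT)
  clamp <- function(m) pmin(pmax(m, 0), 65535) / 65535
  if (dialect == "stacked") {
    for (t in seq_len(nT)) pages[[t]] <- clamp(stack@red[, , t])
    for (t in seq_len(nT)) pages[[nT + t]] <- clamp(stack@green[, , t])
  } else {
    for (t in seq_len(nT)) {
      pages[[2 * t - 1]] <- clamp(stack@red[, , t])
      pages[[2 * t]] <- clamp(stack@green[, , t])
    }
  }
  tiff::writeTIFF(pages, file, bits.per.sample = 16)
  invisible(file)
}

#' @rdname writeFrameStack
#' @param frameInterval,pixelSize metadata to attach on read.
#' @export
readFrameStack <- function(file, dialect = c("stacked", "interleaved"),
                           frameInterval = 0.5, pixelSize = NA_real_) {
  dialect <- match.arg(dialect)
  pages <- tiff::readTIFF(file, all = TRUE)
  nT <- length(pages) / 2
  if (nT != round(nT)) stop("odd number of TIFF pages for a two-channel stack")
  d <- dim(pages[[1]])
  red <- array(0, c(d, nT)); green <- array(0, c(d, nT))
  for (t in seq_len(nT)) {
    if (dialect == "stacked") {
      red[, , t] <- pages[[t]] * 65535
      green[, , t] <- pages[[nT + t]] * 65535
    } else {
      red[, , t] <- pages[[2 * t - 1]] * 65535
      green[, , t] <- pages[[2 * t]] * 65535
    }
  }
  FrameStack(red, green, frameInterval, pixelSize)
}
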