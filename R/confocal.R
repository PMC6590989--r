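## Membrane-versus-whole-cell reporter quantification from confocal images.
##
## The membrane ROI comes from the membrane-dye channel (Otsu threshold,
## morphological closing, largest connected component); the whole-cell ROI
## is the filled ring.  Reporter pixels at or below the background level
## (median outside the cell) are excluded from all sums.

#' Segment the membrane ring from the membrane-dye channel
#'
#' Global Otsu threshold on the normalized channel, morphological closing
#' with a disc, then retention of the largest connected component (the
#' stained ring).
#'
#' @param membraneChannel numeric matrix.
#' @param brushSize diameter of the closing disc in pixels (odd; default 5).
#' @return logical matrix mask.
#' @export
segmentMembrane <- function(membraneChannel, brushSize = 5) {
  rng <- range(membraneChannel)
  if (rng[1] == rng[2]) stop("membrane channel is constant; cannot segment")
  norm <- (membraneChannel - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm))
  mask <- norm > thr
  if (!any(mask)) stop("no foreground after thresholding")
  closed <- EBImage::closing(EBImage::Image(mask * 1),
                             EBImage::makeBrush(brushSize, "disc"))
  lab <- EBImage::bwlabel(closed)
  labm <- .asMatrix(lab)
  if (max(labm) < 1) stop("no connected component found")
  sizes <- tabulate(labm[labm > 0])
  labm == which.max(sizes)
}

#' Background-excluded reporter intensity within a mask
#'
#' Sums reporter pixels inside the mask that are strictly above the
#' background level; pixels at or below background are excluded.
#'
#' @param reporterChannel numeric matrix.
#' @param mask logical matrix (non-empty).
#' @param backgroundLevel intensity threshold.
#' @return the intensity sum.
#' @export
reporterInROI <- function(reporterChannel, mask, backgroundLevel) {
  if (!any(mask)) stop("empty mask")
  v <- reporterChannel[mask]
  sum(v[v > backgroundLevel])
}

#' Membrane fraction of the reporter signal in a confocal image
#'
#' Segments the membrane ring from the dye channel, fills it to obtain the
#' whole-cell mask, estimates background as the median reporter intensity
#' outside the cell, and reports the ratio of background-excluded reporter
#' intensity in the ring to that in the whole cell.  Also reports the
#' coefficient of variation of reporter intensity along the ring perimeter
#' (binned by angle around the cell centroid) as a clustering index.
#'
#' @param image a \linkS4class{ConfocalImage}.
#' @param backgroundLevel optional fixed background; default median of
#'   reporter pixels outside the cell mask.
#' @param nAngleBins perimeter bins for the clustering index (default 36).
#' @return a \linkS4class{CellQuant}.
#' @export
membraneFraction <- function(image, backgroundLevel = NULL, nAngleBins = 36) {
  ring <- segmentMembrane(image@membrane)
  cell <- .asMatrix(EBImage::fillHull(EBImage::Image(ring * 1))) > 0
  rep_ <- image@reporter
  if (is.null(backgroundLevel))
    backgroundLevel <- stats::median(rep_[!cell])
  total <- reporterInROI(rep_, cell, backgroundLevel)
  if (total <= 0) stop("zero total reporter intensity after background exclusion")
  memb <- reporterInROI(rep_, ring & cell, backgroundLevel)

  # clustering index: per-angle mean ring intensity around the centroid
  idx <- which(ring, arr.ind = TRUE)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  ang <- atan2(idx[, 2] - cy, idx[, 1] - cx)
  bin <- cut(ang, breaks = seq(-pi, pi, length.out = nAngleBins + 1),
             include.lowest = TRUE)
  vals <- pmax(rep_[ring] - backgroundLevel, 0)
  perBin <- tapply(vals, bin, mean)
  perBin <- perBin[!is.na(perBin)]
  cv <- if (mean(perBin) > 0) stats::sd(perBin) / mean(perBin) else 0

  new("CellQuant",
      totalReporter = total, membraneReporter = memb,
      membraneFraction = memb / total, membraneCv = cv,
      backgroundLevel = as.numeric(backgroundLevel),
      ringMask = ring, cellMask = cell)
}

#' Write / read a multi-channel confocal image as multi-page TIFF
#'
#' Pages: membrane, reporter, nuclear.  16-bit storage as in
#' [writeFrameStack()].
#'
#' @param image a \linkS4class{ConfocalImage}.
#' @param file TIFF path.
#' @export
writeConfocalImage <- function(image, file) {
  clamp <- function(m) pmin(pmax(m, 0), 65535) / 65535
  tiff::writeTIFF(list(clamp(image@membrane), clamp(image@reporter),
                       clamp(image@nuclear)), file, bits.per.sample = 16)
  invisible(file)
}

#' @rdname writeConfocalImage
#' @export
readConfocalImage <- function(file) {
  pages <- tiff::readTIFF(file, all = TRUE)
  if (length(pages) < 2) stop("expected at least membrane and reporter pages")
  ConfocalImage(pages[[1]] * 65535, pages[[2]] * 65535,
                if (length(pages) >= 3) pages[[3]] * 65535 else NULL)
}
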