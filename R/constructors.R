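#' CRAC motif pattern presets and constructor
#'
#' The canonical CRAC motif is (L/V)-X1-5-(Y)-X1-5-(K/R); the extended form
#' admits F and W at the aromatic anchor: (L/V)-X1-5-(Y/F/W)-X1-5-(K/R).
#' Gaps count residues strictly between anchors.
#'
#' @param preset \code{"crac-extended"} (default) or \code{"crac-canonical"}
#'   (short forms \code{"extended"} / \code{"canonical"} accepted).
#' @return a \linkS4class{MotifPattern}.
#' @examples
#' cracPattern("canonical")
#' @export
cracPattern <- function(preset = c("crac-extended", "crac-canonical",
                                   "extended", "canonical")) {
  preset <- match.arg(preset)
  if (preset %in% c("crac-extended", "extended"))
    motifPattern("crac-extended", aromatic = c("Y", "F", "W"))
  else
    motifPattern("crac-canonical", aromatic = "Y")
}

#' @param name pattern name.
#' @param apolar,aromatic,basic anchor residue sets.
#' @param gapMin,gapMax inclusive gap bounds (residues strictly between
#'   anchors).
#' @rdname cracPattern
#' @export
motifPattern <- function(name, apolar = c("L", "V"), aromatic = c("Y", "F", "W"),
                         basic = c("K", "R"), gapMin = 1L, gapMax = 5L) {
  new("MotifPattern", name = name, apolar = toupper(apolar),
      aromatic = toupper(aromatic), basic = toupper(basic),
      gapMin = as.integer(gapMin), gapMax = as.integer(gapMax))
}

#' Transmembrane topology constructor
#'
#' @param segmentId character vector of segment ids.
#' @param start,end 1-based inclusive residue numbers.
#' @return a \linkS4class{TMTopology}.
#' @examples
#' TMTopology(c("TM2", "TM4"), c(766, 828), c(793, 858))
#' @export
TMTopology <- function(segmentId, start, end) {
  seg <- IRanges::IRanges(start = as.integer(start), end = as.integer(end),
                          names = as.character(segmentId))
  new("TMTopology", segments = seg)
}

#' Mouse TRPA1 TM2/TM4 topology presets
#'
#' Two published boundary conventions exist for TM2: 766-793 (the alignment
#' figure convention) and 765-793 (the structural-modeling convention).  Both
#' are kept as selectable presets; TM4 is 828-858 under the first convention
#' and 830-857 under the second.
#'
#' @param convention \code{"alignment"} (default) or \code{"modeling"}.
#' @return a \linkS4class{TMTopology} with segments TM2 and TM4.
#' @export
trpa1Topology <- function(convention = c("alignment", "modeling")) {
  convention <- match.arg(convention)
  if (convention == "alignment")
    TMTopology(c("TM2", "TM4"), c(766L, 828L), c(793L, 858L))
  else
    TMTopology(c("TM2", "TM4"), c(765L, 830L), c(793L, 857L))
}

#' @rdname FractionProfile-class
#' @param label marker name.
#' @param condition condition string.
#' @param intensities non-negative intensities, fraction 1 first.
#' @param source replicate / blot identifier.
#' @export
FractionProfile <- function(label, condition, intensities, source = "blot1") {
  new("FractionProfile", label = as.character(label),
      condition = as.character(condition),
      intensities = as.numeric(intensities), source = as.character(source))
}

#' @rdname FrameStack-class
#' @param red,green height x width x frames numeric arrays.
#' @param frameInterval seconds between frames.
#' @param pixelSize micrometres per pixel.
#' @export
FrameStack <- function(red, green, frameInterval = 0.5, pixelSize = NA_real_) {
  new("FrameStack", red = red, green = green,
      frameInterval = frameInterval, pixelSize = pixelSize)
}

#' @rdname ConfocalImage-class
#' @param membrane,reporter,nuclear numeric matrices of equal dimension.
#' @param pixelSize micrometres per pixel.
#' @export
ConfocalImage <- function(membrane, reporter, nuclear = NULL,
                          pixelSize = NA_real_) {
  if (is.null(nuclear)) nuclear <- matrix(0, nrow(membrane), ncol(membrane))
  new("ConfocalImage", membrane = membrane, reporter = reporter,
      nuclear = nuclear, pixelSize = pixelSize)
}

setMethod("show", "MotifPattern", function(object) {
  cat(sprintf("MotifPattern '%s': (%s)-X%d-%d-(%s)-X%d-%d-(%s)\n",
              object@name, paste(object@apolar, collapse = "/"),
              object@gapMin, object@gapMax,
              paste(object@aromatic, collapse = "/"),
              object@gapMin, object@gapMax,
              paste(object@basic, collapse = "/")))
})

setMethod("show", "TMTopology", function(object) {
  seg <- object@segments
  cat("TMTopology with", length(seg), "segment(s):\n")
  for (i in seq_along(seg))
    cat(sprintf("  %s: %d-%d\n", names(seg)[i],
                IRanges::start(seg)[i], IRanges::end(seg)[i]))
})

setMethod("show", "FractionProfile", function(object) {
  cat(sprintf("FractionProfile '%s' [%s, %s], %d fractions\n",
              object@label, object@condition, object@source,
              length(object@intensities)))
  print(stats::setNames(object@intensities,
                        paste0("F", seq_along(object@intensities))))
})

setMethod("show", "PartitionStats", function(object) {
  cat(sprintf("PartitionStats: peak F%d%s, centroid %.3f, raft share %.3f (fractions %s)\n",
              object@peakFraction, if (object@peakTie) " (tie)" else "",
              object@centroidIndex, object@raftShare,
              paste(object@raftFractions, collapse = ",")))
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@red)
  cat(sprintf("FrameStack: %d frames of %dx%d, two channels, interval %.3g s\n",
              d[3], d[1], d[2], object@frameInterval))
})

setMethod("show", "ConfocalImage", function(object) {
  d <- dim(object@membrane)
  cat(sprintf("ConfocalImage: %dx%d, channels membrane/reporter/nuclear\n",
              d[1], d[2]))
})

setMethod("show", "ColocResult", function(object) {
  cat(sprintf("ColocResult: %d/%d red tracks colocalized (%s%%)\n",
              object@nColocRedTracks, object@nRedTracks,
              ifelse(is.na(object@percentage), "NA",
                     sprintf("%.1f", object@percentage))))
})

setMethod("show", "HillFit", function(object) {
  e <- object@estimates; s <- object@se
  cat(sprintf("HillFit (n = %d cells)%s\n", object@nCells,
              if (!object@converged) "  ** NOT CONVERGED **" else ""))
  cat(sprintf("  Max  = %.4g +/- %.3g\n  EC50 = %.4g +/- %.3g\n  H_S  = %.4g +/- %.3g\n",
              e["Max"], s["Max"], e["EC50"], s["EC50"], e["H_S"], s["H_S"]))
})

setMethod("show", "CellQuant", function(object) {
  cat(sprintf("CellQuant: membrane fraction %.3f (membrane %.4g / total %.4g), perimeter CV %.3f\n",
              object@membraneFraction, object@membraneReporter,
              object@totalReporter, object@membraneCv))
})

## plain accessors -----------------------------------------------------------

#' Accessors for raftCRAC result objects
#'
#' @param object a package S4 object.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
centroidIndex <- function(object) object@centroidIndex
#' @rdname accessors
#' @export
peakFraction <- function(object) object@peakFraction
#' @rdname accessors
#' @export
raftShare <- function(object) object@raftShare
#' @rdname accessors
#' @export
colocPercentage <- function(object) object@percentage
#' @rdname accessors
#' @export
hillEstimates <- function(object) object@estimates
#' @rdname accessors
#' @export
hillSe <- function(object) object@se
#' @rdname accessors
#' @export
membraneFractionValue <- function(object) object@membraneFraction
#' @rdname accessors
#' @export
tmSegments <- function(object) object@segments
#' @rdname accessors
#' @export
profileIntensities <- function(object) object@intensities
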