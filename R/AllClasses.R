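#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' CRAC-family motif pattern
#'
#' A variable-gap linear motif of the CRAC (Cholesterol Recognition/interaction
#' Amino acid Consensus) family: an apolar anchor, an aromatic anchor and a
#' basic anchor read N-terminus to C-terminus, separated by two gaps of
#' unconstrained residues.  Gap bounds count residues strictly between two
#' anchors.
#'
#' @slot name pattern name.
#' @slot apolar,aromatic,basic character vectors of one-letter residue codes
#'   allowed at each anchor; all three must be non-empty.
#' @slot gapMin,gapMax inclusive bounds on the number of residues strictly
#'   between consecutive anchors, \code{1 <= gapMin <= gapMax}.
#' @seealso [cracPattern()] for the canonical and extended presets.
#' @export
setClass("MotifPattern",
  representation(name = "character", apolar = "character",
                 aromatic = "character", basic = "character",
                 gapMin = "integer", gapMax = "integer"))

setValidity("MotifPattern", function(object) {
  msg <- character()
  if (length(object@apolar) == 0 || length(object@aromatic) == 0 ||
      length(object@basic) == 0)
    msg <- c(msg, "all three anchor sets must be non-empty")
  if (object@gapMin < 1L) msg <- c(msg, "gapMin must be >= 1")
  if (object@gapMin > object@gapMax) msg <- c(msg, "gapMin must be <= gapMax")
  if (length(msg)) msg else TRUE
})

#' Transmembrane topology of a protein
#'
#' Ordered, non-overlapping transmembrane segments in 1-based inclusive
#' residue coordinates, stored as an \linkS4class{IRanges} with segment ids
#' as names.
#'
#' @slot segments an [IRanges::IRanges] whose names are segment ids.
#' @seealso [TMTopology()], [trpa1Topology()], [tmWindows()]
#' @export
setClass("TMTopology", representation(segments = "IRanges"))

setValidity("TMTopology", function(object) {
  seg <- object@segments
  if (length(seg) == 0) return("at least one segment required")
  if (is.null(names(seg)) || anyDuplicated(names(seg)))
    return("segments must carry unique segment ids as names")
  st <- IRanges::start(seg); en <- IRanges::end(seg)
  if (any(st > en)) return("segment start must be <= end")
  if (is.unsorted(st)) return("segments must be sorted by start")
  if (length(seg) > 1 && any(st[-1] <= en[-length(seg)]))
    return("segments must be non-overlapping")
  TRUE
})

#' Per-fraction density-gradient profile
#'
#' Intensities of one marker across the fractions of a flotation gradient
#' (fraction 1 = top, lowest density).
#'
#' @slot label marker name (e.g. channel construct, flotillin-2).
#' @slot condition experimental condition, e.g. \code{"control"} or
#'   \code{"MCD"} for cholesterol depletion.
#' @slot intensities non-negative numeric vector indexed by fraction.
#' @slot source blot / replicate identifier.
#' @export
setClass("FractionProfile",
  representation(label = "character", condition = "character",
                 intensities = "numeric", source = "character"))

setValidity("FractionProfile", function(object) {
  x <- object@intensities
  if (length(x) < 2) return("need at least 2 fractions")
  if (any(!is.finite(x)) || any(x < 0))
    return("intensities must be finite and non-negative")
  if (all(x == 0)) return("at least one intensity must be positive")
  TRUE
})

#' Partition summary of a gradient profile
#'
#' @slot normalizedProfile fractions of total intensity per fraction (sums
#'   to 1).
#' @slot peakFraction index of the maximal fraction (ties resolved to the
#'   lowest index).
#' @slot peakTie TRUE when the peak was tied.
#' @slot centroidIndex intensity-weighted mean fraction index.
#' @slot raftShare share of total intensity in the designated raft fractions.
#' @slot raftFractions the raft fraction set used.
#' @export
setClass("PartitionStats",
  representation(normalizedProfile = "numeric", peakFraction = "integer",
                 peakTie = "logical", centroidIndex = "numeric",
                 raftShare = "numeric", raftFractions = "integer"))

#' Two-channel time-lapse image stack
#'
#' @slot red,green numeric arrays of shape height x width x frames.
#' @slot frameInterval seconds between frames.
#' @slot pixelSize micrometres per pixel (NA when unknown).
#' @export
setClass("FrameStack",
  representation(red = "array", green = "array",
                 frameInterval = "numeric", pixelSize = "numeric"))

setValidity("FrameStack", function(object) {
  if (!identical(dim(object@red), dim(object@green)))
    return("red and green channels must have the same dimensions")
  if (length(dim(object@red)) != 3) return("channels must be H x W x T arrays")
  if (dim(object@red)[3] < 1) return("at least one frame required")
  TRUE
})

#' Multi-channel confocal image of a single cell
#'
#' @slot membrane,reporter,nuclear numeric matrices (height x width):
#'   membrane dye, reporter fluorophore and nuclear stain channels.
#' @slot pixelSize micrometres per pixel (NA when unknown).
#' @export
setClass("ConfocalImage",
  representation(membrane = "matrix", reporter = "matrix",
                 nuclear = "matrix", pixelSize = "numeric"))

setValidity("ConfocalImage", function(object) {
  d <- dim(object@membrane)
  if (!identical(d, dim(object@reporter)) || !identical(d, dim(object@nuclear)))
    return("all channels must share the same dimensions")
  TRUE
})

#' Dynamic colocalization result
#'
#' Summary of the co-movement rule: a red track counts as colocalized when a
#' green track stays within the pairing radius for at least the required
#' number of consecutive shared frames.
#'
#' @slot nRedTracks number of red tracks passing the minimum-length filter.
#' @slot nColocRedTracks number of those classified colocalized.
#' @slot percentage 100 * nColoc / nRed (NA when no red tracks).
#' @slot episodes a [S4Vectors::DataFrame] of co-movement episodes
#'   (red_id, green_id, start_frame, length).
#' @slot parameters the scoring parameters used.
#' @export
setClass("ColocResult",
  representation(nRedTracks = "integer", nColocRedTracks = "integer",
                 percentage = "numeric", episodes = "DataFrame",
                 parameters = "list"))

#' Hill dose-response fit
#'
#' Parameters of the Hill model Max * c^H / (c^H + EC50^H) fitted to pooled
#' per-cell responses by nonlinear least squares.
#'
#' @slot estimates named numeric: Max, EC50, H_S.
#' @slot se asymptotic standard errors on the same scale.
#' @slot residualSd residual standard deviation.
#' @slot nCells number of cells used.
#' @slot converged logical; FALSE flags an unreliable fit.
#' @slot diagnostics message from the optimizer when not converged.
#' @slot data the fitted responses (kept for bootstrap resampling).
#' @export
setClass("HillFit",
  representation(estimates = "numeric", se = "numeric", residualSd = "numeric",
                 nCells = "integer", converged = "logical",
                 diagnostics = "character", data = "data.frame"))

#' Membrane-versus-cell reporter quantification
#'
#' @slot totalReporter background-excluded reporter intensity over the whole
#'   cell.
#' @slot membraneReporter background-excluded reporter intensity within the
#'   membrane ring.
#' @slot membraneFraction membraneReporter / totalReporter.
#' @slot membraneCv coefficient of variation of reporter intensity along the
#'   ring perimeter (clustering index).
#' @slot backgroundLevel the background estimate used.
#' @slot ringMask,cellMask logical matrices recording mask provenance.
#' @export
setClass("CellQuant",
  representation(totalReporter = "numeric", membraneReporter = "numeric",
                 membraneFraction = "numeric", membraneCv = "numeric",
                 backgroundLevel = "numeric", ringMask = "matrix",
                 cellMask = "matrix"))
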