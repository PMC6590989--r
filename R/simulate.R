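## Ground-truthed synthetic data generators.
##
## Every generator takes a mandatory seed, is bit-reproducible given the
## seed, and returns its ground truth alongside the data so downstream
## recovery tests never re-derive truth from the data.  Noise model
## throughout: Gaussian read noise added to an ideal noise-free image;
## intensity budgets are conserved exactly before noise injection.

.STANDARD_AA <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                  "P","S","T","W","Y","V")

#' Simulate an aligned ortholog panel with planted CRAC anchors
#'
#' Generates \code{nSpecies} equal-length sequences (no indels: the
#' alignment is the identity) from a template.  Anchor sites of every CRAC
#' match found in the template's transmembrane windows are preserved with
#' probability \code{anchorFidelity} and otherwise substituted to a residue
#' outside their anchor class; all other sites are substituted uniformly
#' with probability \code{substitutionRate}.  The first row is the
#' unmutated template (the reference carrying motif numbering), emulating a
#' mammalian ortholog panel around a conserved channel.
#'
#' @param template amino-acid string.
#' @param topology a \linkS4class{TMTopology} within the template's range.
#' @param nSpecies number of rows (default 24).
#' @param substitutionRate per-site substitution probability outside
#'   anchors.
#' @param anchorFidelity per-site retention probability at anchors.
#' @param pattern \linkS4class{MotifPattern} used to plant anchors.
#' @param flank flank width for the transmembrane windows.
#' @param offset residue number of the first template character.
#' @param seed RNG seed (mandatory).
#' @return list: \code{alignment} (named character vector, reference row
#'   first), \code{referenceId}, \code{matches} (planted match table),
#'   \code{truth} (DataFrame: position, class, residue), \code{offset}.
#' @export
simOrthologSet <- function(template, topology, nSpecies = 24L,
                           substitutionRate = 0.1, anchorFidelity = 0.9,
                           pattern = cracPattern("extended"), flank = 5L,
                           offset = 1L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (substitutionRate < 0 || substitutionRate > 1 ||
      anchorFidelity < 0 || anchorFidelity > 1)
    stop("rates must lie in [0, 1]")
  if (nSpecies < 1) stop("nSpecies must be >= 1")
  n <- nchar(template)
  seg <- topology@segments
  if (any(IRanges::end(seg) > offset + n - 1L) ||
      any(IRanges::start(seg) < offset))
    stop("template shorter than a topology segment (segment outside range)")
  scan <- scanTM(template, topology, pattern, offset = offset, flank = flank)
  matches <- scan$matches
  classSets <- list(apolar = pattern@apolar, aromatic = pattern@aromatic,
                    basic = pattern@basic)
  anchors <- unique(rbind(
    data.frame(position = matches$apolar_pos, class = "apolar"),
    data.frame(position = matches$aromatic_pos, class = "aromatic"),
    data.frame(position = matches$basic_pos, class = "basic")))
  tmpl <- strsplit(template, "")[[1]]
  anchors$residue <- tmpl[anchors$position - offset + 1L]
  anchorIdx <- anchors$position - offset + 1L

  set.seed(seed)
  ids <- sprintf("species%02d", seq_len(nSpecies))
  rows <- character(nSpecies)
  rows[1] <- template
  if (nSpecies > 1) for (s in 2:nSpecies) {
    chars <- tmpl
    for (a in seq_along(anchorIdx)) {
      if (stats::runif(1) > anchorFidelity) {
        outside <- setdiff(.STANDARD_AA, classSets[[anchors$class[a]]])
        chars[anchorIdx[a]] <- sample(outside, 1)
      }
    }
    nonAnchor <- setdiff(seq_len(n), anchorIdx)
    mut <- nonAnchor[stats::runif(length(nonAnchor)) < substitutionRate]
    for (i in mut) chars[i] <- sample(setdiff(.STANDARD_AA, chars[i]), 1)
    rows[s] <- paste(chars, collapse = "")
  }
  names(rows) <- ids
  list(alignment = rows, referenceId = ids[1], matches = matches,
       truth = DataFrame(anchors), offset = as.integer(offset))
}

.reflect <- function(x, lo, hi) {
  # reflect a coordinate into [lo, hi]
  rng <- hi - lo
  y <- (x - lo) %% (2 * rng)
  lo + ifelse(y > rng, 2 * rng - y, y)
}

.renderSpots <- function(size, xs, ys, amplitude, psfSigma) {
  img <- matrix(0, size[1], size[2])
  r <- ceiling(4 * psfSigma)
  for (s in seq_along(xs)) {
    ii <- max(1, floor(xs[s]) - r):min(size[1], ceiling(xs[s]) + r)
    jj <- max(1, floor(ys[s]) - r):min(size[2], ceiling(ys[s]) + r)
    gx <- exp(-(ii - xs[s])^2 / (2 * psfSigma^2))
    gy <- exp(-(jj - ys[s])^2 / (2 * psfSigma^2))
    img[ii, jj] <- img[ii, jj] + amplitude * outer(gx, gy)
  }
  img
}

#' Simulate a two-channel TIRF movie with a controlled co-moving fraction
#'
#' Structures diffuse as reflected Gaussian random walks.  Co-moving pairs
#' share one base trajectory; each channel observes it with independent
#' per-frame jitter.  Channel-exclusive structures move independently.
#' Spots are rendered as isotropic Gaussians (sigma \code{psfSigma}) on a
#' constant background with Gaussian read noise.
#'
#' @param nFrames frames (>= 3, the co-movement rule needs 3).
#' @param frameInterval seconds between frames (default 0.5).
#' @param imageSize c(height, width) pixels.
#' @param nColocPairs,nRedOnly,nGreenOnly structure counts.
#' @param diffusionSigma random-walk step SD per axis, pixels/frame
#'   (default 1.0, about D = 0.005 um^2/s for 65 nm pixels at 2 Hz — a
#'   mobile membrane-proximal vesicle).
#' @param pairJitter per-channel jitter SD of co-moving pairs, pixels.
#' @param spotAmplitude,background,noiseSd intensity units; SNR is
#'   spotAmplitude / noiseSd.
#' @param psfSigma point-spread sigma in pixels (default 1.5).
#' @param pairingRadius radius used only for the density warning.
#' @param seed RNG seed (mandatory).
#' @return list: \code{stack} (\linkS4class{FrameStack}), \code{truth} with
#'   \code{tracks} (structure_id, channel, coloc, frame, x, y),
#'   \code{labels} (structure_id, channel, coloc) and the planted
#'   colocalized red fraction \code{colocFraction}.
#' @export
simTirfMovie <- function(nFrames = 40L, frameInterval = 0.5,
                         imageSize = c(192L, 192L), nColocPairs = 5L,
                         nRedOnly = 5L, nGreenOnly = 3L,
                         diffusionSigma = 1.0, pairJitter = 0.3,
                         spotAmplitude = 200, background = 100, noiseSd = 5,
                         psfSigma = 1.5, pairingRadius = 3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (nFrames < 3) stop("nFrames must be >= 3 (co-movement rule needs 3 frames)")
  set.seed(seed)
  margin <- ceiling(4 * psfSigma) + 1
  lo <- margin; hiX <- imageSize[1] - margin; hiY <- imageSize[2] - margin

  walk <- function() {
    x <- numeric(nFrames); y <- numeric(nFrames)
    x[1] <- stats::runif(1, lo, hiX); y[1] <- stats::runif(1, lo, hiY)
    if (nFrames > 1) for (t in 2:nFrames) {
      x[t] <- .reflect(x[t - 1] + stats::rnorm(1, 0, diffusionSigma), lo, hiX)
      y[t] <- .reflect(y[t - 1] + stats::rnorm(1, 0, diffusionSigma), lo, hiY)
    }
    cbind(x, y)
  }
  jitter2 <- function(base) {
    cbind(.reflect(base[, 1] + stats::rnorm(nFrames, 0, pairJitter), lo, hiX),
          .reflect(base[, 2] + stats::rnorm(nFrames, 0, pairJitter), lo, hiY))
  }

  tracks <- list()
  addTrack <- function(id, channel, coloc, xy)
    data.frame(structure_id = id, channel = channel, coloc = coloc,
               frame = seq_len(nFrames), x = xy[, 1], y = xy[, 2])
  for (p in seq_len(nColocPairs)) {
    base <- walk()
    tracks[[length(tracks) + 1]] <- addTrack(sprintf("pair%02d", p), "red",
                                             TRUE, jitter2(base))
    tracks[[length(tracks) + 1]] <- addTrack(sprintf("pair%02d", p), "green",
                                             TRUE, jitter2(base))
  }
  for (p in seq_len(nRedOnly))
    tracks[[length(tracks) + 1]] <- addTrack(sprintf("redonly%02d", p), "red",
                                             FALSE, walk())
  for (p in seq_len(nGreenOnly))
    tracks[[length(tracks) + 1]] <- addTrack(sprintf("greenonly%02d", p),
                                             "green", FALSE, walk())
  truthTracks <- do.call(rbind, tracks)

  # density sanity: tracking is ill-posed when structures are too crowded
  for (ch in c("red", "green")) {
    t1 <- truthTracks[truthTracks$frame == 1 & truthTracks$channel == ch, ]
    if (nrow(t1) > 1) {
      d <- as.matrix(stats::dist(t1[, c("x", "y")]))
      diag(d) <- Inf
      if (mean(apply(d, 1, min)) < 2 * pairingRadius)
        warning(sprintf("%s-channel spot density too high: mean nearest-neighbor distance < 2 x pairing radius; tracking may be ill-posed", ch))
    }
  }

  red <- array(0, c(imageSize, nFrames))
  green <- array(0, c(imageSize, nFrames))
  for (t in seq_len(nFrames)) {
    tr <- truthTracks[truthTracks$frame == t, ]
    rr <- tr[tr$channel == "red", ]; gg <- tr[tr$channel == "green", ]
    red[, , t] <- .renderSpots(imageSize, rr$x, rr$y, spotAmplitude, psfSigma) +
      background + stats::rnorm(prod(imageSize), 0, noiseSd)
    green[, , t] <- .renderSpots(imageSize, gg$x, gg$y, spotAmplitude, psfSigma) +
      background + stats::rnorm(prod(imageSize), 0, noiseSd)
  }
  labels <- unique(truthTracks[, c("structure_id", "channel", "coloc")])
  nRed <- nColocPairs + nRedOnly
  list(stack = FrameStack(red, green, frameInterval),
       truth = list(tracks = truthTracks, labels = labels,
                    colocFraction = if (nRed > 0) nColocPairs / nRed else NA))
}

#' Simulate a confocal cell image with a controlled membrane fraction
#'
#' A circular cell: the membrane-dye channel is an annulus, the nuclear
#' channel a central disk, and the reporter channel splits a fixed photon
#' budget exactly as \code{fMembrane} on the annulus versus the interior
#' (before noise).  Membrane signal can be clustered along the perimeter
#' with a von Mises angular profile (\code{clusteringConcentration} = 0
#' gives a uniform ring).
#'
#' @param imageSize c(height, width) pixels.
#' @param cellRadius,membraneThickness annulus geometry in pixels; the
#'   annulus spans radii (cellRadius - membraneThickness, cellRadius].
#' @param fMembrane fraction of the reporter budget on the membrane, in
#'   [0, 1].
#' @param clusteringConcentration von Mises kappa for perimeter clustering
#'   (0 = uniform).
#' @param photonBudget total ideal reporter intensity.
#' @param membraneDye amplitude of the membrane-dye annulus.
#' @param nuclearRadius radius of the nuclear disk.
#' @param noiseSd Gaussian read noise SD, all channels.
#' @param seed RNG seed (mandatory).
#' @return list: \code{image} (\linkS4class{ConfocalImage}) and
#'   \code{truth} (fMembrane, ringMask, cellMask, budget).
#' @export
simConfocalCell <- function(imageSize = c(96L, 96L), cellRadius = 30,
                            membraneThickness = 3, fMembrane = 0.6,
                            clusteringConcentration = 0,
                            photonBudget = 2e5, membraneDye = 150,
                            nuclearRadius = 10, noiseSd = 5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (fMembrane < 0 || fMembrane > 1) stop("fMembrane must lie in [0, 1]")
  if (membraneThickness < 1) stop("membraneThickness must be >= 1 pixel")
  cx <- (imageSize[1] + 1) / 2; cy <- (imageSize[2] + 1) / 2
  if (cellRadius + 2 > min(cx, cy)) stop("cell does not fit in the image")
  set.seed(seed)
  ii <- matrix(seq_len(imageSize[1]), imageSize[1], imageSize[2])
  jj <- matrix(seq_len(imageSize[2]), imageSize[1], imageSize[2], byrow = TRUE)
  rr <- sqrt((ii - cx)^2 + (jj - cy)^2)
  ring <- rr <= cellRadius & rr > cellRadius - membraneThickness
  interior <- rr <= cellRadius - membraneThickness
  nucleus <- rr <= nuclearRadius

  membrane <- matrix(0, imageSize[1], imageSize[2])
  membrane[ring] <- membraneDye
  nuclear <- matrix(0, imageSize[1], imageSize[2])
  nuclear[nucleus] <- membraneDye

  reporter <- matrix(0, imageSize[1], imageSize[2])
  if (any(ring)) {
    w <- if (clusteringConcentration > 0) {
      mu <- stats::runif(1, -pi, pi)
      theta <- atan2(jj[ring] - cy, ii[ring] - cx)
      exp(clusteringConcentration * cos(theta - mu))
    } else rep(1, sum(ring))
    reporter[ring] <- fMembrane * photonBudget * w / sum(w)
  }
  if (any(interior))
    reporter[interior] <- (1 - fMembrane) * photonBudget / sum(interior)

  addNoise <- function(m) m + stats::rnorm(length(m), 0, noiseSd)
  img <- ConfocalImage(addNoise(membrane), addNoise(reporter),
                       addNoise(nuclear))
  list(image = img,
       truth = list(fMembrane = fMembrane, ringMask = ring,
                    cellMask = ring | interior, budget = photonBudget))
}

#' Simulate a density-gradient fraction profile
#'
#' Mixture of two discretized Gaussian components: a raft component
#' floating at \code{raftCenter} and a non-raft component at
#' \code{nonraftCenter}, mixed with weight \code{raftWeight}, scaled to
#' \code{totalIntensity}, plus truncated Gaussian noise.  A component width
#' of 0 collapses that component to a delta at its (rounded) center.
#'
#' @param nFractions number of fractions (default 6, top first).
#' @param raftWeight mixture weight of the raft component in [0, 1].
#' @param raftCenter,nonraftCenter component centers, fraction indices in
#'   [1, nFractions].
#' @param componentWidth Gaussian SD in fractions.
#' @param totalIntensity profile total before noise.
#' @param noiseSd additive noise SD per fraction (clamped at 0).
#' @param label,condition,source metadata for the profile.
#' @param seed RNG seed (mandatory).
#' @return list: \code{profile} (\linkS4class{FractionProfile}) and
#'   \code{truth} (ideal profile and its analytic centroid).
#' @export
simGradientProfile <- function(nFractions = 6L, raftWeight = 0.7,
                               raftCenter = 3, nonraftCenter = 6,
                               componentWidth = 0.8, totalIntensity = 100,
                               noiseSd = 2, label = "channel",
                               condition = "control", source = "blot1", seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (raftWeight < 0 || raftWeight > 1) stop("raftWeight must lie in [0, 1]")
  if (raftCenter < 1 || raftCenter > nFractions ||
      nonraftCenter < 1 || nonraftCenter > nFractions)
    stop("component centers must lie in [1, nFractions]")
  ideal <- expectedGradientProfile(nFractions, raftWeight, raftCenter,
                                   nonraftCenter, componentWidth) *
           totalIntensity
  set.seed(seed)
  noisy <- pmax(ideal + stats::rnorm(nFractions, 0, noiseSd), 0)
  if (all(noisy == 0)) noisy[which.max(ideal)] <- totalIntensity * 1e-6
  list(profile = FractionProfile(label, condition, noisy, source),
       truth = list(ideal = ideal,
                    centroid = sum(seq_len(nFractions) * ideal) / sum(ideal)))
}

#' @rdname simGradientProfile
#' @details \code{expectedGradientProfile} returns the normalized noiseless
#'   mixture profile, from which the analytic expectation of the centroid
#'   (and hence of centroid shifts between two parameterizations) follows.
#' @export
expectedGradientProfile <- function(nFractions = 6L, raftWeight = 0.7,
                                    raftCenter = 3, nonraftCenter = 6,
                                    componentWidth = 0.8) {
  idx <- seq_len(nFractions)
  comp <- function(center) {
    if (componentWidth <= 0) as.numeric(idx == round(center))
    else {
      d <- stats::dnorm(idx, center, componentWidth)
      d / sum(d)
    }
  }
  p <- raftWeight * comp(raftCenter) + (1 - raftWeight) * comp(nonraftCenter)
  p / sum(p)
}

#' Simulate per-cell Hill dose responses
#'
#' Each cell's response is Hill(concentration; Max, EC50, H_S) plus
#' Gaussian noise.  Defaults are the wild-type channel conditions
#' (EC50 11.8 uM, Max 0.79 uM; the Hill coefficient is a free parameter,
#' default 2).
#'
#' @param concentrations agonist concentrations in uM (strictly positive).
#' @param nCellsPerConc cells per concentration (>= 1).
#' @param max,ec50,hs Hill parameters.
#' @param noiseSd per-cell Gaussian noise SD in uM.
#' @param condition,genotype metadata columns.
#' @param seed RNG seed (mandatory).
#' @return data.frame with concentration, delta_ca, condition, genotype.
#' @export
simDoseResponse <- function(concentrations = c(1, 3, 10, 30, 100, 300),
                            nCellsPerConc = 50L, max = 0.79, ec50 = 11.8,
                            hs = 2, noiseSd = 0.1, condition = "control",
                            genotype = "WT", seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (any(concentrations <= 0)) stop("concentrations must be strictly positive")
  if (nCellsPerConc < 1) stop("nCellsPerConc must be >= 1")
  set.seed(seed)
  conc <- rep(concentrations, each = nCellsPerConc)
  mu <- predictHill(conc, max, ec50, hs)
  data.frame(concentration = conc,
             delta_ca = mu + stats::rnorm(length(conc), 0, noiseSd),
             condition = condition, genotype = genotype)
}
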