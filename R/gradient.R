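## Density-gradient partition analysis.
##
## Profiles are per-fraction intensities of one marker in one condition,
## fraction 1 at the top of the tube (lowest density).  Raft-resident
## markers float into the low-density fractions (default raft set {3,4});
## cholesterol depletion shifts them toward denser fractions.

#' Partition statistics of a gradient profile
#'
#' @param profile a \linkS4class{FractionProfile}.
#' @param raftFractions integer set of raft fraction indices (default 3:4,
#'   the low-density flotation fractions where raft markers peak).
#' @return a \linkS4class{PartitionStats}: normalized profile, peak fraction
#'   (ties resolved to the lowest index and flagged), centroid index
#'   \eqn{\sum i I_i / \sum I_i}, and raft share.
#' @examples
#' p <- FractionProfile("flotillin-2", "control", c(5, 10, 60, 20, 3, 2))
#' partitionStats(p)
#' @export
partitionStats <- function(profile, raftFractions = c(3L, 4L)) {
  x <- profile@intensities
  if (all(x == 0)) stop("all-zero profile")
  raftFractions <- as.integer(raftFractions)
  if (any(raftFractions < 1 | raftFractions > length(x)))
    stop("raft fractions outside profile range")
  norm <- x / sum(x)
  pk <- which(x == max(x))
  new("PartitionStats",
      normalizedProfile = norm,
      peakFraction = pk[1],
      peakTie = length(pk) > 1,
      centroidIndex = sum(seq_along(x) * norm),
      raftShare = sum(norm[raftFractions]),
      raftFractions = raftFractions)
}

#' Fraction shift between control and treated profiles
#'
#' Positive values mean a shift toward denser (higher-index) fractions,
#' the signature of raft exit after cholesterol depletion.
#'
#' @param control,treated \linkS4class{FractionProfile}s with the same
#'   number of fractions and label.
#' @return list with \code{centroid_shift} (real) and \code{peak_shift}
#'   (integer), treated minus control.
#' @export
fractionShift <- function(control, treated) {
  if (length(control@intensities) != length(treated@intensities))
    stop("profiles have different numbers of fractions")
  if (control@label != treated@label)
    stop("profiles carry different labels")
  sc <- partitionStats(control); st <- partitionStats(treated)
  list(centroid_shift = st@centroidIndex - sc@centroidIndex,
       peak_shift = st@peakFraction - sc@peakFraction)
}

#' Summarize control-versus-treated partitioning per marker
#'
#' Pairs replicate profiles (same label and source) across the two
#' conditions, computes per-pair shifts, and reports the replicate mean and
#' s.e.m. of the peak shift (the headline statistic) and the centroid
#' shift.  Labels missing either condition are skipped with a warning;
#' single-pair labels report s.e.m. as NA.
#'
#' @param profiles list of \linkS4class{FractionProfile}s.
#' @param control,treated condition strings identifying the two conditions.
#' @return data.frame with one row per label: n_pairs, mean/sem of peak and
#'   centroid shifts, and the mean raft shares per condition.
#' @export
summarizeConditions <- function(profiles, control = "control", treated = "MCD") {
  if (length(profiles) == 0)
    return(data.frame(label = character(), n_pairs = integer(),
                      mean_peak_shift = numeric(), sem_peak_shift = numeric(),
                      mean_centroid_shift = numeric(),
                      sem_centroid_shift = numeric(),
                      raft_share_control = numeric(),
                      raft_share_treated = numeric()))
  lab <- vapply(profiles, function(p) p@label, character(1))
  cond <- vapply(profiles, function(p) p@condition, character(1))
  src <- vapply(profiles, function(p) p@source, character(1))
  rows <- list()
  for (L in unique(lab)) {
    ctl <- profiles[lab == L & cond == control]
    trt <- profiles[lab == L & cond == treated]
    if (length(ctl) == 0 || length(trt) == 0) {
      warning(sprintf("label '%s': missing %s condition, skipped", L,
                      if (length(ctl) == 0) control else treated))
      next
    }
    ctlSrc <- src[lab == L & cond == control]
    trtSrc <- src[lab == L & cond == treated]
    common <- intersect(ctlSrc, trtSrc)
    if (length(common) == 0) {
      warning(sprintf("label '%s': no paired replicates, skipped", L))
      next
    }
    shifts <- lapply(common, function(s)
      fractionShift(ctl[[match(s, ctlSrc)]], trt[[match(s, trtSrc)]]))
    pk <- vapply(shifts, function(s) as.numeric(s$peak_shift), numeric(1))
    ce <- vapply(shifts, function(s) s$centroid_shift, numeric(1))
    sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    rows[[L]] <- data.frame(
      label = L, n_pairs = length(common),
      mean_peak_shift = mean(pk), sem_peak_shift = sem(pk),
      mean_centroid_shift = mean(ce), sem_centroid_shift = sem(ce),
      raft_share_control = mean(vapply(common, function(s)
        partitionStats(ctl[[match(s, ctlSrc)]])@raftShare, numeric(1))),
      raft_share_treated = mean(vapply(common, function(s)
        partitionStats(trt[[match(s, trtSrc)]])@raftShare, numeric(1))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read gradient profiles from a long-format CSV
#'
#' Expected columns: label, condition, fraction, intensity, and optionally
#' source (defaults to "blot1").
#'
#' @param file CSV path.
#' @return list of \linkS4class{FractionProfile}s.
#' @export
readFractionCSV <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (is.null(df$source)) df$source <- "blot1"
  key <- interaction(df$label, df$condition, df$source, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$fraction), ]
    FractionProfile(g$label[1], g$condition[1], g$intensity, g$source[1])
  })
}

#' @rdname readFractionCSV
#' @param profiles list of \linkS4class{FractionProfile}s.
#' @export
writeFractionCSV <- function(profiles, file) {
  rows <- lapply(profiles, function(p)
    data.frame(label = p@label, condition = p@condition,
               fraction = seq_along(p@intensities),
               intensity = p@intensities, source = p@source))
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}
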