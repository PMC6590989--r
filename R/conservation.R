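## Alignment conservation / consensus scoring.
##
## Conservation is scored with a transparent residue property-class scheme:
## a column's score is the share of property classes that every residue in
## the column belongs to (1 when the column is strictly identical).  The '*'
## (identity) and '+' (all properties preserved) flags follow the usual
## alignment-annotation semantics; gaps always break both flags.

#' Default residue property classes
#'
#' Seven overlapping classes used for conservation scoring: hydrophobic,
#' aromatic, positively charged, negatively charged, polar, small, and the
#' proline/glycine special class.  A custom table may be supplied as a named
#' list of one-letter residue vectors (JSON-serializable).
#'
#' @return named list of character vectors.
#' @export
defaultPropertyTable <- function() {
  list(
    hydrophobic = c("A", "C", "F", "I", "L", "M", "V", "W", "Y"),
    aromatic    = c("F", "H", "W", "Y"),
    positive    = c("H", "K", "R"),
    negative    = c("D", "E"),
    polar       = c("C", "D", "E", "H", "K", "N", "Q", "R", "S", "T", "W", "Y"),
    small       = c("A", "C", "D", "G", "N", "P", "S", "T", "V"),
    special     = c("G", "P"))
}

## Coerce alignment input (named character vector, AAStringSet or
## AAMultipleAlignment) to a character matrix, rows = records.
.alnMatrix <- function(alignment) {
  if (is(alignment, "AAMultipleAlignment"))
    alignment <- as.character(Biostrings::unmasked(alignment))
  else if (is(alignment, "AAStringSet"))
    alignment <- as.character(alignment)
  if (!is.character(alignment) || length(alignment) == 0)
    stop("empty alignment")
  w <- unique(nchar(alignment))
  if (length(w) != 1) stop("aligned rows must all have the same length")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Per-column conservation statistics of an alignment
#'
#' For each column reports the consensus residue and its frequency among
#' non-gap rows, the identity flag ('*': all rows identical, no gaps), the
#' property flag ('+': all rows share at least one property class, no
#' gaps), and a conservation score in [0, 1]: the number of property
#' classes shared by every residue in the column divided by the number of
#' classes, set to 1 for strict identity.  Columns containing gaps can
#' never be flagged.
#'
#' @param alignment named character vector of equal-length aligned rows
#'   ('-' gaps), an [Biostrings::AAStringSet] or
#'   [Biostrings::AAMultipleAlignment].
#' @param propertyTable named list of residue classes; see
#'   [defaultPropertyTable()].
#' @return a [S4Vectors::DataFrame] with one row per column: column_index,
#'   consensus_residue, consensus_fraction, ambiguous, identity_flag,
#'   property_flag, conservation_score.
#' @export
columnStats <- function(alignment, propertyTable = defaultPropertyTable()) {
  m <- .alnMatrix(alignment)
  nClasses <- length(propertyTable)
  cons <- .consensusColumns(m)
  nc <- ncol(m)
  identity <- logical(nc); property <- logical(nc); score <- numeric(nc)
  for (j in seq_len(nc)) {
    col <- m[, j]
    hasGap <- any(col == "-")
    res <- col[col != "-"]
    ident <- length(res) > 0 && length(unique(res)) == 1
    if (length(res) == 0) { score[j] <- 0; next }
    shared <- sum(vapply(propertyTable, function(cls) all(res %in% cls),
                         logical(1)))
    identity[j] <- ident && !hasGap
    property[j] <- shared > 0 && !hasGap
    score[j] <- if (ident && !hasGap) 1 else shared / nClasses
  }
  DataFrame(column_index = seq_len(nc),
            consensus_residue = cons$residue,
            consensus_fraction = cons$fraction,
            ambiguous = cons$ambiguous,
            identity_flag = identity,
            property_flag = property,
            conservation_score = score)
}

.consensusColumns <- function(m) {
  nc <- ncol(m)
  residue <- character(nc); fraction <- numeric(nc); ambiguous <- logical(nc)
  for (j in seq_len(nc)) {
    res <- m[, j][m[, j] != "-"]
    if (length(res) == 0) {
      residue[j] <- "-"; fraction[j] <- 0; ambiguous[j] <- FALSE
    } else {
      tab <- table(res)
      top <- tab[tab == max(tab)]
      residue[j] <- sort(names(top))[1]           # alphabetical tie-break
      fraction[j] <- max(tab) / length(res)
      ambiguous[j] <- length(top) > 1
    }
  }
  list(residue = residue, fraction = fraction, ambiguous = ambiguous)
}

#' Consensus sequence of an alignment
#'
#' Modal non-gap residue per column, ties broken alphabetically and marked
#' ambiguous; all-gap columns yield '-' with fraction 0.
#'
#' @inheritParams columnStats
#' @return list with \code{consensus} (string) and \code{stats} (DataFrame:
#'   column_index, residue, fraction, ambiguous).
#' @export
consensusSequence <- function(alignment) {
  m <- .alnMatrix(alignment)
  cons <- .consensusColumns(m)
  list(consensus = paste(cons$residue, collapse = ""),
       stats = DataFrame(column_index = seq_len(ncol(m)),
                         residue = cons$residue, fraction = cons$fraction,
                         ambiguous = cons$ambiguous))
}

#' Anchor-class conservation of motif matches across an alignment
#'
#' Maps each anchor of each match from reference-row residue numbering to
#' alignment columns and reports, per anchor, the fraction of rows whose
#' residue in that column belongs to the anchor's pattern class (apolar,
#' aromatic or basic).  Gaps count as non-conserving.  The reference row
#' must be ungapped at every anchor.
#'
#' @inheritParams columnStats
#' @param matches a match DataFrame from [scanSequence()] in the reference
#'   row's residue numbering.
#' @param pattern the \linkS4class{MotifPattern} defining anchor classes.
#' @param referenceId name of the reference row.
#' @param referenceOffset residue number of the reference row's first
#'   (ungapped) residue.
#' @return a [S4Vectors::DataFrame], one row per match: anchor positions and
#'   apolar_frac, aromatic_frac, basic_frac, mean_frac.
#' @export
anchorConservation <- function(alignment, matches,
                               pattern = cracPattern("extended"),
                               referenceId, referenceOffset = 1L) {
  m <- .alnMatrix(alignment)
  if (!(referenceId %in% rownames(m)))
    stop(sprintf("reference row '%s' not found in alignment", referenceId))
  ref <- m[referenceId, ]
  ungapped <- which(ref != "-")
  # residue number -> alignment column for the reference row
  toColumn <- function(pos) {
    idx <- pos - as.integer(referenceOffset) + 1L
    if (any(idx < 1 | idx > length(ungapped)))
      stop("anchor position outside the reference row's residue range")
    ungapped[idx]
  }
  classFrac <- function(col, classSet) mean(m[, col] %in% classSet)
  n <- nrow(matches)
  ap <- ar <- ba <- numeric(n)
  for (i in seq_len(n)) {
    cols <- toColumn(c(matches$apolar_pos[i], matches$aromatic_pos[i],
                       matches$basic_pos[i]))
    ap[i] <- classFrac(cols[1], pattern@apolar)
    ar[i] <- classFrac(cols[2], pattern@aromatic)
    ba[i] <- classFrac(cols[3], pattern@basic)
  }
  DataFrame(apolar_pos = matches$apolar_pos,
            aromatic_pos = matches$aromatic_pos,
            basic_pos = matches$basic_pos,
            apolar_frac = ap, aromatic_frac = ar, basic_frac = ba,
            mean_frac = (ap + ar + ba) / 3)
}

#' Read an alignment from aligned FASTA or Clustal format
#'
#' @param file path; format sniffed from the first line (Clustal files start
#'   with "CLUSTAL").
#' @return named character vector of aligned rows.
#' @export
readAlignment <- function(file) {
  first <- readLines(file, n = 1)
  if (grepl("^CLUSTAL", first)) {
    aln <- Biostrings::readAAMultipleAlignment(file, format = "clustal")
    as.character(Biostrings::unmasked(aln))
  } else {
    as.character(Biostrings::readAAStringSet(file))
  }
}

#' Write per-column or per-motif conservation tables as TSV
#'
#' @param x a DataFrame from [columnStats()] or [anchorConservation()].
#' @param file output path.
#' @export
writeConservationTable <- function(x, file) {
  utils::write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
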