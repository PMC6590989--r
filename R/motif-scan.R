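## CRAC motif scanning over transmembrane windows.
##
## Coordinates are 1-based inclusive residue numbers throughout; a sequence
## string carries an `offset` giving the residue number of its first
## character, so a construct fragment can keep full-length channel numbering.

.AA_CODES <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
               "P","S","T","W","Y","V","X")

.checkResidues <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!(chars %in% .AA_CODES))
  if (length(bad))
    stop(sprintf("invalid residue code '%s' at sequence position %d",
                 chars[bad[1]], bad[1]))
  chars
}

#' Scan a protein sequence for CRAC-family motif matches
#'
#' Enumerates every anchor triple (apolar, aromatic, basic positions, in
#' N-to-C order) satisfying the pattern's residue sets and gap bounds.
#' Overlapping triples sharing residues are all reported: distinct triples
#' are distinct motifs.
#'
#' @param sequence amino-acid string (one-letter codes; 'X' = unknown, which
#'   matches no anchor set but any gap position), or an
#'   [Biostrings::AAString].
#' @param pattern a \linkS4class{MotifPattern}; default the extended CRAC
#'   pattern.
#' @param offset residue number of the first sequence character (1-based).
#' @param region optional c(start, end) residue interval; a triple counts
#'   only if all three anchors lie inside it.
#' @param segmentId optional id recorded in the result.
#' @return a [S4Vectors::DataFrame] with columns \code{segment_id},
#'   \code{apolar_pos}, \code{aromatic_pos}, \code{basic_pos}, \code{start},
#'   \code{end}, \code{subsequence}, sorted by
#'   (apolar_pos, aromatic_pos, basic_pos).
#' @examples
#' scanSequence("VFLSSIFGYCK", cracPattern("extended"), offset = 780)
#' @export
scanSequence <- function(sequence, pattern = cracPattern("extended"),
                         offset = 1L, region = NULL, segmentId = NA_character_) {
  sequence <- as.character(sequence)
  offset <- as.integer(offset)
  if (offset < 1L) stop("offset must be >= 1")
  if (nchar(sequence) == 0) return(.emptyMatches())
  chars <- .checkResidues(sequence)
  n <- length(chars)
  resno <- offset + seq_len(n) - 1L
  if (!is.null(region)) {
    if (region[1] < offset || region[2] > offset + n - 1L)
      stop("region lies outside the record's numbered range")
    inReg <- resno >= region[1] & resno <= region[2]
  } else inReg <- rep(TRUE, n)

  iAp <- which(chars %in% pattern@apolar & inReg)
  iAr <- which(chars %in% pattern@aromatic & inReg)
  iBa <- which(chars %in% pattern@basic & inReg)
  gmin <- pattern@gapMin; gmax <- pattern@gapMax

  out <- vector("list", length(iAp))
  k <- 0L
  for (i in iAp) {
    js <- iAr[iAr - i - 1L >= gmin & iAr - i - 1L <= gmax]
    for (j in js) {
      ks <- iBa[iBa - j - 1L >= gmin & iBa - j - 1L <= gmax]
      if (length(ks)) {
        k <- k + 1L
        out[[k]] <- cbind(i, j, ks)
      }
    }
  }
  if (k == 0L) return(.emptyMatches())
  trip <- do.call(rbind, out[seq_len(k)])
  ord <- order(trip[, 1], trip[, 2], trip[, 3])
  trip <- trip[ord, , drop = FALSE]
  DataFrame(
    segment_id = segmentId,
    apolar_pos = resno[trip[, 1]],
    aromatic_pos = resno[trip[, 2]],
    basic_pos = resno[trip[, 3]],
    start = resno[trip[, 1]],
    end = resno[trip[, 3]],
    subsequence = vapply(seq_len(nrow(trip)), function(r)
      paste(chars[trip[r, 1]:trip[r, 3]], collapse = ""), character(1)))
}

.emptyMatches <- function() {
  DataFrame(segment_id = character(), apolar_pos = integer(),
            aromatic_pos = integer(), basic_pos = integer(),
            start = integer(), end = integer(), subsequence = character())
}

#' Flanked transmembrane search windows
#'
#' Expands each transmembrane segment by `flank` residues on both sides
#' (the juxtamembrane stretches at the lipid-water interfaces) and clips to
#' the available sequence range.  Overlapping windows are kept separate,
#' each under its own segment id.
#'
#' @param topology a \linkS4class{TMTopology}.
#' @param flank non-negative flank width in residues (default 5).
#' @param sequenceRange c(first, last) residue numbers available.
#' @return an [IRanges::IRanges] named by segment id.
#' @export
tmWindows <- function(topology, flank = 5L, sequenceRange) {
  if (flank < 0) stop("flank must be >= 0")
  seg <- topology@segments
  st <- pmax(IRanges::start(seg) - as.integer(flank), sequenceRange[1])
  en <- pmin(IRanges::end(seg) + as.integer(flank), sequenceRange[2])
  IRanges::IRanges(start = st, end = en, names = names(seg))
}

#' Scan transmembrane segments (plus flanks) of a protein
#'
#' Runs [scanSequence()] over each segment's flanked window.  A match is
#' attributed to the segment whose window contains its full span; windows
#' that overlap each report their own matches.
#'
#' @inheritParams scanSequence
#' @param topology a \linkS4class{TMTopology} within the record's range.
#' @param flank flank width in residues (default 5, the juxtamembrane
#'   stretch).
#' @return list with \code{matches} (one DataFrame, segment-attributed) and
#'   \code{counts} (named integer vector per segment).
#' @examples
#' top <- TMTopology("TM2", 780, 790)
#' scanTM("VFLSSIFGYCK", top, offset = 780, flank = 0)$counts
#' @export
scanTM <- function(sequence, topology, pattern = cracPattern("extended"),
                   offset = 1L, flank = 5L) {
  sequence <- as.character(sequence)
  n <- nchar(sequence)
  rng <- c(offset, offset + n - 1L)
  seg <- topology@segments
  if (any(IRanges::start(seg) < rng[1]) || any(IRanges::end(seg) > rng[2]))
    stop("topology segments lie outside the record's numbered range")
  win <- tmWindows(topology, flank, rng)
  res <- lapply(seq_along(win), function(i)
    scanSequence(sequence, pattern, offset = offset,
                 region = c(IRanges::start(win)[i], IRanges::end(win)[i]),
                 segmentId = names(win)[i]))
  matches <- do.call(rbind, res)
  counts <- vapply(res, nrow, integer(1))
  names(counts) <- names(win)
  list(matches = matches, counts = counts, windows = win)
}

#' Write or read a motif match table
#'
#' Serializes matches as TSV with columns segment_id, apolar_pos,
#' aromatic_pos, basic_pos, span, subsequence, in stable scan order.
#'
#' @param matches a match DataFrame from [scanSequence()] or
#'   [scanTM()]\code{$matches}.
#' @param file output path.
#' @return \code{reportMatches}: the path, invisibly. \code{readMatches}:
#'   the match DataFrame.
#' @export
reportMatches <- function(matches, file) {
  df <- data.frame(
    segment_id = as.character(matches$segment_id),
    apolar_pos = matches$apolar_pos,
    aromatic_pos = matches$aromatic_pos,
    basic_pos = matches$basic_pos,
    span = if (nrow(matches)) paste0(matches$start, "-", matches$end)
           else character(),
    subsequence = as.character(matches$subsequence))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname reportMatches
#' @export
readMatches <- function(file) {
  df <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(segment_id = "character",
                                         span = "character",
                                         subsequence = "character"))
  span <- strsplit(df$span, "-", fixed = TRUE)
  DataFrame(segment_id = df$segment_id, apolar_pos = as.integer(df$apolar_pos),
            aromatic_pos = as.integer(df$aromatic_pos),
            basic_pos = as.integer(df$basic_pos),
            start = if (nrow(df)) as.integer(vapply(span, `[`, "", 1)) else integer(),
            end = if (nrow(df)) as.integer(vapply(span, `[`, "", 2)) else integer(),
            subsequence = df$subsequence)
}

#' Read a transmembrane topology table
#'
#' Accepts a TSV with columns (id, start, end) or a JSON file holding an
#' array of objects with those fields.
#'
#' @param file path to TSV or JSON.
#' @return a \linkS4class{TMTopology}.
#' @export
readTopology <- function(file) {
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(file)
    TMTopology(x$id, x$start, x$end)
  } else {
    x <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE)
    TMTopology(x$id, x$start, x$end)
  }
}

#' Fetch a protein sequence from UniProt
#'
#' Downloads the FASTA record for an accession from the UniProt REST
#' service.  Requires network access; offline use should supply sequences
#' as local FASTA via [Biostrings::readAAStringSet()].
#'
#' @param accession UniProt accession, e.g. \code{"Q8BLA8"} (mouse TRPA1).
#' @param timeout seconds before giving up.
#' @return a named character vector of length 1 (the sequence).
#' @export
fetchUniProt <- function(accession, timeout = 30) {
  url <- sprintf("https://rest.uniprot.org/uniprotkb/%s.fasta", accession)
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  old <- getOption("timeout"); options(timeout = timeout)
  on.exit(options(timeout = old), add = TRUE)
  status <- tryCatch(utils::download.file(url, tmp, quiet = TRUE, mode = "wb"),
                     error = function(e) stop(
                       sprintf("UniProt fetch for %s failed: %s",
                               accession, conditionMessage(e)), call. = FALSE))
  if (status != 0) stop(sprintf("UniProt fetch for %s failed", accession))
  aa <- Biostrings::readAAStringSet(tmp)
  stats::setNames(as.character(aa[1]), names(aa)[1])
}
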