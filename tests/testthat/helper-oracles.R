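# Independent brute-force oracles and small fixture builders.

# Exhaustive triple enumeration checked directly against the pattern sets
# and gap bounds; deliberately naive and independent of scanSequence.
bruteScan <- function(sequence, pattern, offset = 1L) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  hits <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (!(i < j && j < k)) next
    if (!(chars[i] %in% pattern@apolar)) next
    if (!(chars[j] %in% pattern@aromatic)) next
    if (!(chars[k] %in% pattern@basic)) next
    g1 <- j - i - 1; g2 <- k - j - 1
    if (g1 < pattern@gapMin || g1 > pattern@gapMax) next
    if (g2 < pattern@gapMin || g2 > pattern@gapMax) next
    hits[[length(hits) + 1]] <- c(i, j, k) + offset - 1L
  }
  if (!length(hits)) return(matrix(integer(), 0, 3))
  m <- do.call(rbind, hits)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

randomProtein <- function(len) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V"), len, replace = TRUE),
        collapse = "")
}

# matrix form of scanSequence anchors for oracle comparison
anchorMatrix <- function(matches) {
  m <- cbind(matches$apolar_pos, matches$aromatic_pos, matches$basic_pos)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# a tiny synthetic channel-like template with motif-bearing TM windows
demoTemplate <- function() raftCRAC:::.demoTemplate()

# minimal hand-built track data.frame
makeTrack <- function(id, frames, x, y) {
  data.frame(track_id = rep(id, length(frames)), frame = frames,
             x = rep_len(x, length(frames)), y = rep_len(y, length(frames)),
             intensity = rep(1, length(frames)))
}
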