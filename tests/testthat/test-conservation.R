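idPanel <- function(n = 24, seq = "VFLSSIFGYCK") {
  stats::setNames(rep(seq, n), sprintf("sp%02d", seq_len(n)))
}

test_that("identical rows are fully conserved", {
  cs <- columnStats(idPanel())
  expect_true(all(cs$identity_flag))
  expect_true(all(cs$property_flag))
  expect_true(all(cs$conservation_score == 1))
  expect_true(all(cs$consensus_fraction == 1))
})

test_that("property flag survives class-preserving substitutions", {
  aln <- c(a = "L", b = "V")   # both hydrophobic/small
  cs <- columnStats(aln)
  expect_false(cs$identity_flag)
  expect_true(cs$property_flag)
  expect_lt(cs$conservation_score, 1)
  expect_gt(cs$conservation_score, 0)
})

test_that("gaps break both flags and are excluded from consensus", {
  aln <- c(a = "LK", b = "-K")
  cs <- columnStats(aln)
  expect_false(cs$identity_flag[1])
  expect_false(cs$property_flag[1])
  expect_true(cs$identity_flag[2])
  # consensus of the gapped column counts only the non-gap row
  cons <- consensusSequence(aln)
  expect_equal(cons$consensus, "LK")
  expect_equal(cons$stats$fraction[1], 1)
})

test_that("scores match a brute-force property-intersection oracle", {
  tbl <- defaultPropertyTable()
  set.seed(11)
  for (rep in 1:20) {
    rows <- vapply(1:10, function(i) randomProtein(15), character(1))
    names(rows) <- paste0("r", 1:10)
    cs <- columnStats(rows, tbl)
    m <- do.call(rbind, strsplit(rows, ""))
    for (j in 1:15) {
      col <- m[, j]
      shared <- sum(vapply(tbl, function(cls) all(col %in% cls), logical(1)))
      want <- if (length(unique(col)) == 1) 1 else shared / length(tbl)
      expect_equal(cs$conservation_score[j], want)
    }
  }
})

test_that("consensus ties break alphabetically and are flagged", {
  aln <- stats::setNames(c(rep("L", 12), rep("V", 12)), sprintf("s%02d", 1:24))
  cons <- consensusSequence(aln)
  expect_equal(cons$consensus, "L")
  expect_equal(cons$stats$fraction, 0.5)
  expect_true(cons$stats$ambiguous)
})

test_that("all-gap columns give '-' with fraction 0", {
  cons <- consensusSequence(c(a = "A-", b = "A-"))
  expect_equal(cons$consensus, "A-")
  expect_equal(cons$stats$fraction[2], 0)
})

test_that("outputs are invariant to row order and monotone in duplicates", {
  set.seed(3)
  rows <- stats::setNames(vapply(1:8, function(i) randomProtein(12),
                                 character(1)), paste0("r", 1:8))
  a <- columnStats(rows)
  b <- columnStats(rev(rows))
  expect_equal(a$conservation_score, b$conservation_score)
  expect_equal(a$consensus_residue, b$consensus_residue)

  dup <- c(rows, r9 = unname(rows[1]))
  d <- columnStats(dup)
  expect_true(all(d$conservation_score >= a$conservation_score - 1e-12))

  single <- columnStats(rows[1])
  expect_true(all(single$identity_flag))
})

test_that("anchor conservation counts class membership across species", {
  pat <- cracPattern("extended")
  m <- scanSequence("VFLSSIFGYCK", pat, offset = 780)

  aln <- idPanel(24)
  ac <- anchorConservation(aln, m, pat, "sp01", referenceOffset = 780)
  expect_true(all(ac$apolar_frac == 1 & ac$aromatic_frac == 1 &
                  ac$basic_frac == 1))

  # one species loses an aromatic anchor (F786 -> A)
  aln2 <- aln
  aln2["sp24"] <- "VFLSSIAGYCK"
  ac2 <- anchorConservation(aln2, m, pat, "sp01", referenceOffset = 780)
  hit <- ac2[ac2$aromatic_pos == 786, ]
  expect_equal(hit$aromatic_frac, rep(23 / 24, nrow(hit)))

  # reference gapped at an anchor is rejected
  aln3 <- aln
  aln3["sp01"] <- "VFLSSI-GYCK"
  expect_error(anchorConservation(aln3, m, pat, "sp01",
                                  referenceOffset = 780))
})

test_that("planted panels recover the planted conservation level", {
  demo <- demoTemplate()
  p <- simOrthologSet(demo$sequence, demo$topology, nSpecies = 24,
                      substitutionRate = 0.1, anchorFidelity = 0.9,
                      offset = demo$offset, seed = 99)
  ac <- anchorConservation(p$alignment, p$matches, cracPattern("extended"),
                           p$referenceId, p$offset)
  expect_lt(abs(mean(ac$mean_frac) - 0.9), 0.1)

  full <- simOrthologSet(demo$sequence, demo$topology, nSpecies = 12,
                         substitutionRate = 0.3, anchorFidelity = 1,
                         offset = demo$offset, seed = 5)
  acf <- anchorConservation(full$alignment, full$matches,
                            cracPattern("extended"), full$referenceId,
                            full$offset)
  expect_true(all(acf$apolar_frac == 1 & acf$aromatic_frac == 1 &
                  acf$basic_frac == 1))

  # consensus equals the template at every site under full fidelity and
  # zero substitution
  none <- simOrthologSet(demo$sequence, demo$topology, nSpecies = 10,
                         substitutionRate = 0, anchorFidelity = 1,
                         offset = demo$offset, seed = 2)
  expect_equal(consensusSequence(none$alignment)$consensus, demo$sequence)
})

test_that("alignments read from FASTA and Clustal", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "VFLSSIFGYCK", ">b", "VFLSSIFGYCK"), fa)
  aln <- readAlignment(fa)
  expect_equal(unname(aln), rep("VFLSSIFGYCK", 2))

  cl <- tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "", "",
               "a   VFLSSIFGYCK", "b   VFLSSIFGYCK"), cl)
  aln2 <- readAlignment(cl)
  expect_equal(unname(aln2), rep("VFLSSIFGYCK", 2))
})
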