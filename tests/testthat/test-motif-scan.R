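ext <- cracPattern("extended")
can <- cracPattern("canonical")

test_that("the printed TM2 and TM4 stretches yield their known motifs", {
  m <- scanSequence("VFLSSIFGYCK", ext, offset = 780)
  expect_equal(nrow(m), 3)
  expect_equal(anchorMatrix(m),
               rbind(c(780L, 786L, 790L), c(782L, 786L, 790L),
                     c(782L, 788L, 790L)))
  expect_true(all(m$end == 790))

  m4 <- scanSequence("LLYLQR", ext, offset = 850)
  expect_equal(anchorMatrix(m4), rbind(c(850L, 852L, 855L)))

  # the Y-only canonical pattern loses the two F-anchored variants
  mc <- scanSequence("VFLSSIFGYCK", can, offset = 780)
  expect_equal(anchorMatrix(mc), rbind(c(782L, 788L, 790L)))
})

test_that("sequences without anchor residues give no matches", {
  expect_equal(nrow(scanSequence("AAAAAAA", ext)), 0)
  expect_equal(nrow(scanSequence("", ext)), 0)
  noBasic <- motifPattern("nb", basic = "K")
  expect_equal(nrow(scanSequence("VALYAAG", noBasic)), 0)
})

test_that("invalid residues are rejected with their position", {
  expect_error(scanSequence("VFLZSIK", ext), "position 4")
  expect_error(scanSequence("VFLSSIFGYCK", ext, offset = 780,
                            region = c(700, 790)),
               "outside")
})

test_that("scanner agrees with brute-force enumeration on random sequences", {
  set.seed(42)
  for (rep in 1:200) {
    s <- randomProtein(sample(5:60, 1))
    off <- sample(1:500, 1)
    got <- anchorMatrix(scanSequence(s, ext, offset = off))
    want <- bruteScan(s, ext, offset = off)
    expect_equal(unname(got), unname(want))
  }
})

test_that("match counts are monotone in region and aromatic set", {
  set.seed(7)
  for (rep in 1:25) {
    s <- randomProtein(40)
    full <- nrow(scanSequence(s, ext))
    sub <- nrow(scanSequence(s, ext, region = c(5, 35)))
    expect_lte(sub, full)
    expect_lte(nrow(scanSequence(s, can)), full)
  }
})

test_that("positions covary with the offset", {
  s <- "VFLSSIFGYCK"
  m1 <- anchorMatrix(scanSequence(s, ext, offset = 1))
  m2 <- anchorMatrix(scanSequence(s, ext, offset = 101))
  expect_equal(m2, m1 + 100L)
})

test_that("the pattern is directional: reversed sequences scan differently", {
  fwd <- scanSequence("VFLSSIFGYCK", ext, offset = 780)
  rev <- scanSequence("KCYGFISSLFV", ext, offset = 780)
  expect_equal(nrow(fwd), 3)
  expect_false(nrow(rev) == 3 &&
               identical(anchorMatrix(rev), anchorMatrix(fwd)))
})

test_that("X matches no anchor but may sit in gaps", {
  # V-X-Y..K: X in the gap is fine
  expect_equal(nrow(scanSequence("VXYAK", ext)), 1)
  # X cannot serve as the aromatic anchor
  expect_equal(nrow(scanSequence("VAXAK", ext)), 0)
})

test_that("tm windows expand, clip, and stay unmerged", {
  top <- TMTopology("TM2", 766, 793)
  w <- tmWindows(top, 5, c(761, 800))
  expect_equal(IRanges::start(w), 761L)
  expect_equal(IRanges::end(w), 798L)

  wl <- tmWindows(TMTopology("s", 1, 10), 5, c(1, 12))
  expect_equal(c(IRanges::start(wl), IRanges::end(wl)), c(1L, 12L))

  two <- TMTopology(c("a", "b"), c(10, 30), c(15, 40))
  w0 <- tmWindows(two, 0, c(1, 50))
  expect_equal(IRanges::start(w0), c(10L, 30L))
  expect_equal(IRanges::end(w0), c(15L, 40L))
  expect_equal(names(w0), c("a", "b"))
})

test_that("scanTM attributes matches per segment and counts them", {
  r1 <- scanTM("VFLSSIFGYCK", TMTopology("TM2", 780, 790), ext,
               offset = 780, flank = 0)
  expect_equal(unname(r1$counts["TM2"]), 3L)
  r2 <- scanTM("LLYLQR", TMTopology("TM4", 850, 855), ext,
               offset = 850, flank = 0)
  expect_equal(unname(r2$counts["TM4"]), 1L)
  expect_true(all(r1$matches$segment_id == "TM2"))

  demo <- demoTemplate()
  rd <- scanTM(demo$sequence, demo$topology, ext, offset = demo$offset)
  expect_named(rd$counts, c("TM2", "TM4"))
  expect_error(scanTM("VFLSSIFGYCK", TMTopology("TM2", 780, 820), ext,
                      offset = 780),
               "outside")
})

test_that("match tables round-trip through TSV", {
  f <- tempfile(fileext = ".tsv")
  m <- scanSequence("VFLSSIFGYCK", ext, offset = 780, segmentId = "TM2")
  reportMatches(m, f)
  back <- readMatches(f)
  expect_equal(as.data.frame(back), as.data.frame(m))

  reportMatches(scanSequence("AAAA", ext), f)
  expect_equal(length(readLines(f)), 1)   # header only
  expect_equal(nrow(readMatches(f)), 0)
})

test_that("topology files read from TSV and JSON", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("id\tstart\tend", "TM2\t766\t793", "TM4\t828\t858"), tsv)
  t1 <- readTopology(tsv)
  expect_equal(names(tmSegments(t1)), c("TM2", "TM4"))

  js <- tempfile(fileext = ".json")
  jsonlite::write_json(data.frame(id = c("TM2", "TM4"),
                                  start = c(766, 828), end = c(793, 858)), js)
  t2 <- readTopology(js)
  expect_equal(IRanges::start(tmSegments(t2)), c(766L, 828L))
})

test_that("topology presets expose both TM2 boundary conventions", {
  ta <- trpa1Topology("alignment")
  expect_equal(IRanges::start(tmSegments(ta))[1], 766L)
  tm <- trpa1Topology("modeling")
  expect_equal(IRanges::start(tmSegments(tm))[1], 765L)
})
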