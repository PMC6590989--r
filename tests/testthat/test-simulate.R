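test_that("generators are reproducible and demand a seed", {
  demo <- demoTemplate()
  expect_error(simOrthologSet(demo$sequence, demo$topology), "seed")
  expect_error(simTirfMovie(), "seed")
  expect_error(simConfocalCell(), "seed")
  expect_error(simGradientProfile(), "seed")
  expect_error(simDoseResponse(), "seed")

  a <- simOrthologSet(demo$sequence, demo$topology, offset = demo$offset,
                      seed = 5)
  b <- simOrthologSet(demo$sequence, demo$topology, offset = demo$offset,
                      seed = 5)
  expect_identical(a$alignment, b$alignment)

  m1 <- simTirfMovie(nFrames = 5, imageSize = c(48L, 48L), nColocPairs = 2,
                     nRedOnly = 1, nGreenOnly = 1, seed = 9)
  m2 <- simTirfMovie(nFrames = 5, imageSize = c(48L, 48L), nColocPairs = 2,
                     nRedOnly = 1, nGreenOnly = 1, seed = 9)
  expect_identical(m1$stack@red, m2$stack@red)
  expect_identical(simDoseResponse(seed = 4), simDoseResponse(seed = 4))
})

test_that("ortholog panels honour their mutation model", {
  demo <- demoTemplate()
  none <- simOrthologSet(demo$sequence, demo$topology, nSpecies = 8,
                         substitutionRate = 0, anchorFidelity = 1,
                         offset = demo$offset, seed = 1)
  expect_true(all(none$alignment == demo$sequence))

  # fidelity 1: every anchor column stays class-conserved at any rate
  pat <- cracPattern("extended")
  noisy <- simOrthologSet(demo$sequence, demo$topology, nSpecies = 16,
                          substitutionRate = 0.4, anchorFidelity = 1,
                          offset = demo$offset, seed = 2)
  sets <- list(apolar = pat@apolar, aromatic = pat@aromatic,
               basic = pat@basic)
  tr <- as.data.frame(noisy$truth)
  for (r in seq_len(nrow(tr))) {
    col <- substr(noisy$alignment, tr$position[r] - demo$offset + 1,
                  tr$position[r] - demo$offset + 1)
    expect_true(all(col %in% sets[[tr$class[r]]]))
  }

  # perturbed anchors leave their class
  low <- simOrthologSet(demo$sequence, demo$topology, nSpecies = 24,
                        substitutionRate = 0, anchorFidelity = 0,
                        offset = demo$offset, seed = 3)
  trl <- as.data.frame(low$truth)
  for (r in seq_len(nrow(trl))) {
    col <- substr(low$alignment[-1], trl$position[r] - demo$offset + 1,
                  trl$position[r] - demo$offset + 1)
    expect_false(any(col %in% sets[[trl$class[r]]]))
  }

  expect_error(simOrthologSet("VFLSS", TMTopology("TM", 1, 20), seed = 1),
               "shorter")
  # scanner recall of planted motifs on the reference row
  p <- simOrthologSet(demo$sequence, demo$topology, offset = demo$offset,
                      seed = 11)
  ref <- scanTM(p$alignment[[p$referenceId]], demo$topology,
                offset = demo$offset)
  expect_equal(as.data.frame(ref$matches), as.data.frame(p$matches))
})

test_that("movie truth matches its construction", {
  sim <- suppressWarnings(    # small field: the density warning is expected
    simTirfMovie(nFrames = 8, imageSize = c(64L, 64L), nColocPairs = 5,
                 nRedOnly = 5, nGreenOnly = 0, noiseSd = 0,
                 diffusionSigma = 0, seed = 13))
  expect_equal(sim$truth$colocFraction, 0.5)
  lb <- sim$truth$labels
  expect_equal(sum(lb$channel == "red"), 10)
  expect_equal(sum(lb$coloc[lb$channel == "red"]), 5)

  tt <- sim$truth$tracks
  expect_true(all(tt$x >= 1 & tt$x <= 64 & tt$y >= 1 & tt$y <= 64))

  # co-moving partners stay within jitter range of each other
  pairs <- tt[tt$coloc, ]
  for (id in unique(pairs$structure_id)) {
    r <- pairs[pairs$structure_id == id & pairs$channel == "red", ]
    g <- pairs[pairs$structure_id == id & pairs$channel == "green", ]
    expect_true(all(sqrt((r$x - g$x)^2 + (r$y - g$y)^2) < 3))
  }

  expect_error(simTirfMovie(nFrames = 2, seed = 1), "3")
  warns <- capture_warnings(simTirfMovie(nFrames = 3,
                                         imageSize = c(32L, 32L),
                                         nColocPairs = 10, nRedOnly = 10,
                                         nGreenOnly = 0, seed = 1))
  expect_true(any(grepl("density", warns)))
})

test_that("confocal photon budget splits exactly before noise", {
  sim <- simConfocalCell(fMembrane = 0.6, noiseSd = 0, seed = 21)
  img <- sim$image
  expect_equal(sum(img@reporter), sim$truth$budget, tolerance = 1e-9)
  expect_equal(sum(img@reporter[sim$truth$ringMask]) / sum(img@reporter),
               0.6, tolerance = 1e-9)

  expect_error(simConfocalCell(fMembrane = 1.3, seed = 1), "0, 1")
  expect_error(simConfocalCell(cellRadius = 100, imageSize = c(64L, 64L),
                               seed = 1), "fit")
  expect_error(simConfocalCell(membraneThickness = 0.2, seed = 1), "1 pixel")
})

test_that("gradient profiles honour their mixture parameters", {
  d <- simGradientProfile(raftWeight = 1, componentWidth = 0,
                          raftCenter = 3, noiseSd = 0, seed = 2)
  expect_equal(which(profileIntensities(d$profile) > 0), 3L)

  n <- simGradientProfile(raftWeight = 0, nonraftCenter = 6,
                          componentWidth = 0, noiseSd = 0, seed = 2)
  expect_equal(centroidIndex(partitionStats(n$profile)), 6)

  expect_error(simGradientProfile(raftCenter = 9, seed = 1), "centers")
  expect_true(all(profileIntensities(
    simGradientProfile(noiseSd = 50, seed = 3)$profile) >= 0))
})

test_that("dose-response draws sit on the Hill curve without noise", {
  d <- simDoseResponse(concentrations = 11.8, nCellsPerConc = 10,
                       noiseSd = 0, seed = 5)
  expect_true(all(d$delta_ca == 0.79 / 2))
  expect_error(simDoseResponse(concentrations = c(-1, 2), seed = 1),
               "positive")
  expect_error(simDoseResponse(nCellsPerConc = 0, seed = 1), ">= 1")
})
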