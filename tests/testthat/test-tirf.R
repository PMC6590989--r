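test_that("isolated spots are detected with sub-pixel accuracy", {
  img <- raftCRAC:::.renderSpots(c(64, 64), 20, 30, 200, 1.5) + 100
  d <- detectSpots(img)
  expect_equal(nrow(d), 1)
  expect_lt(sqrt((d$x - 20)^2 + (d$y - 30)^2), 0.5)

  flat <- matrix(100, 64, 64)
  expect_equal(nrow(detectSpots(flat)), 0)
})

test_that("detection recall and precision exceed 0.95 at SNR 10", {
  sim <- simTirfMovie(nFrames = 10, spotAmplitude = 100, noiseSd = 10,
                      seed = 31)
  sp <- detectSpots(sim$stack@red)
  tt <- sim$truth$tracks
  tt <- tt[tt$channel == "red", ]
  tp <- 0
  for (f in unique(tt$frame)) {
    tr <- tt[tt$frame == f, ]; de <- sp[sp$frame == f, ]
    for (i in seq_len(nrow(tr)))
      if (nrow(de) &&
          min(sqrt((de$x - tr$x[i])^2 + (de$y - tr$y[i])^2)) <= 2)
        tp <- tp + 1
  }
  expect_gte(tp / nrow(tt), 0.95)         # recall
  expect_gte(tp / nrow(sp), 0.95)         # precision (vs all detections)
})

test_that("linking follows moving spots and never swaps distant ones", {
  mov <- do.call(rbind, lapply(1:10, function(f)
    data.frame(frame = f, x = 10 + f, y = 20, intensity = 1)))
  tr <- linkTracks(mov, rLink = 3)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)

  two <- do.call(rbind, lapply(1:10, function(f)
    data.frame(frame = f, x = c(10, 30), y = 20, intensity = 1)))
  tr2 <- linkTracks(two, rLink = 3)
  expect_equal(length(unique(tr2$track_id)), 2)
  byTrack <- split(tr2$x, tr2$track_id)
  expect_true(all(vapply(byTrack, function(v) length(unique(v)) == 1,
                         logical(1))))
})

test_that("most planted trajectories are recovered as single tracks", {
  sim <- simTirfMovie(seed = 205)
  tr <- linkTracks(detectSpots(sim$stack@red), rLink = 4)
  lens <- vapply(split(tr, tr$track_id), nrow, integer(1))
  expect_gte(sum(lens >= 38) / 10, 0.9)
})

test_that("the co-movement rule classifies canonical cases", {
  red <- makeTrack(1, 1:10, 10, 10)
  greenSame <- makeTrack(1, 1:10, 10.5, 10)
  greenFar <- makeTrack(2, 1:10, 50, 50)

  expect_equal(colocPercentage(scoreComovement(red, greenSame)), 100)
  expect_equal(colocPercentage(scoreComovement(red, greenFar)), 0)

  # paired on frames {1,2} and {5,6} only: max run 2 < 3 -> rejected
  g <- data.frame(track_id = 3, frame = 1:10,
                  x = c(10, 10, 50, 50, 10, 10, 50, 50, 50, 50),
                  y = 10, intensity = 1)
  expect_equal(colocPercentage(scoreComovement(red, g)), 0)
  # same geometry but three consecutive paired frames -> accepted
  g$x[3] <- 10
  r <- scoreComovement(red, g)
  expect_equal(colocPercentage(r), 100)
  expect_equal(as.data.frame(r@episodes)$length[1], 3)
})

test_that("no red tracks reports an undefined percentage", {
  empty <- makeTrack(1, integer(0), numeric(0), numeric(0))
  r <- scoreComovement(empty, makeTrack(1, 1:5, 1, 1))
  expect_true(is.na(colocPercentage(r)))
})

test_that("comovement score is translation invariant and monotone", {
  set.seed(9)
  red <- do.call(rbind, lapply(1:4, function(id)
    makeTrack(id, 1:12, cumsum(rnorm(12, 0, 1)) + 20 * id,
              cumsum(rnorm(12, 0, 1)) + 30)))
  green <- do.call(rbind, lapply(1:3, function(id)
    makeTrack(id + 10, 1:12, cumsum(rnorm(12, 0, 1)) + 20 * id + 1,
              cumsum(rnorm(12, 0, 1)) + 30)))
  base <- colocPercentage(scoreComovement(red, green, rPair = 3))

  shifted <- red; shifted$x <- shifted$x + 7; shifted$y <- shifted$y - 4
  gshift <- green; gshift$x <- gshift$x + 7; gshift$y <- gshift$y - 4
  expect_equal(colocPercentage(scoreComovement(shifted, gshift, rPair = 3)),
               base)

  expect_gte(colocPercentage(scoreComovement(red, green, rPair = 6)), base)
  expect_gte(colocPercentage(scoreComovement(red, green, rPair = 3,
                                             minConsecutive = 2)), base)
  # degenerate upper bound
  expect_equal(colocPercentage(scoreComovement(red, green, rPair = 1e6,
                                               minConsecutive = 1)), 100)
})

test_that("the full pipeline recovers a planted colocalized fraction", {
  sim <- simTirfMovie(seed = 7)
  r <- tirfColoc(sim$stack)
  expect_lte(abs(colocPercentage(r$result) - 100 * sim$truth$colocFraction),
             10)
})

test_that("frame stacks round-trip through multi-page TIFF", {
  sim <- simTirfMovie(nFrames = 3, imageSize = c(32L, 32L), nColocPairs = 1,
                      nRedOnly = 0, nGreenOnly = 0, seed = 1)
  for (dialect in c("stacked", "interleaved")) {
    f <- tempfile(fileext = ".tif")
    writeFrameStack(sim$stack, f, dialect)
    back <- readFrameStack(f, dialect)
    expect_equal(dim(back@red), dim(sim$stack@red))
    expect_lt(max(abs(back@red - sim$stack@red)), 1)   # 16-bit quantization
    expect_lt(max(abs(back@green - sim$stack@green)), 1)
  }
})
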