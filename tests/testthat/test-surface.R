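test_that("a clean step surface is detected exactly at its first bright slice", {
  s <- stepStack(step = 5L)
  hm <- detectSurface(s, SurfaceParams(threshold = 50, preSmoothSigma = 0))
  expect_true(all(validMask(hm)))
  expect_true(all(heightValues(hm) == 5))
  # any threshold strictly between background and signal gives the same answer
  for (thr in c(1, 25, 99)) {
    hmT <- detectSurface(s, SurfaceParams(threshold = thr, preSmoothSigma = 0))
    expect_true(all(heightValues(hmT) == 5))
  }
})

test_that("columns without a qualifying run are invalid", {
  s <- stepStack(step = 5L)
  v <- voxels(s)
  v[1, , 3, 4] <- 0                       # one all-dark column
  s <- ImageStack(array(v[1, , , ], dim(v)[2:4]))
  hm <- detectSurface(s, SurfaceParams(threshold = 50, preSmoothSigma = 0))
  expect_false(validMask(hm)[3, 4])
  expect_true(is.na(heightValues(hm)[3, 4]))
  expect_true(all(heightValues(hm)[validMask(hm)] == 5))
})

test_that("minRun rejects isolated bright slices", {
  v <- array(0, c(10, 4, 4))
  v[3, , ] <- 100                         # single bright slice at z = 2
  v[7:8, , ] <- 100                       # two-slice run at z = 6
  s <- ImageStack(v)
  hm1 <- detectSurface(s, SurfaceParams(threshold = 50, preSmoothSigma = 0,
                                        minRun = 1))
  hm2 <- detectSurface(s, SurfaceParams(threshold = 50, preSmoothSigma = 0,
                                        minRun = 2))
  expect_true(all(heightValues(hm1) == 2))
  expect_true(all(heightValues(hm2) == 6))
})

test_that("otsu on a constant channel is a detection error", {
  s <- ImageStack(array(42, c(5, 4, 4)))
  expect_error(detectSurface(s, SurfaceParams(preSmoothSigma = 0)),
               class = "peelstackDetectionError")
  expect_error(detectSurface(s, SurfaceParams(preSmoothSigma = 0)),
               "no surface contrast")
})

test_that("raising the threshold never yields a shallower surface", {
  set.seed(21)
  v <- array(runif(12 * 10 * 10) * 100, c(12, 10, 10))
  s <- ImageStack(v)
  prev <- NULL
  for (thr in c(20, 40, 60, 80)) {
    hm <- detectSurface(s, SurfaceParams(threshold = thr, preSmoothSigma = 0,
                                         minRun = 1))
    h <- heightValues(hm)
    h[is.na(h)] <- Inf                     # lost columns count as deepest
    if (!is.null(prev)) expect_true(all(h >= prev))
    prev <- h
  }
})

test_that("fillGaps matches the brute-force nearest-neighbour oracle", {
  # single invalid pixel surrounded by height 5
  h <- matrix(5, 5, 5)
  h[3, 3] <- NA
  filled <- fillGaps(HeightMap(h, nz = 10L))
  expect_true(all(heightValues(filled) == 5))
  expect_true(all(validMask(filled)))

  # left half 2, right half invalid -> right half filled with 2
  h2 <- matrix(NA_real_, 6, 8)
  h2[, 1:4] <- 2
  filled2 <- fillGaps(HeightMap(h2, nz = 10L))
  expect_true(all(heightValues(filled2) == 2))

  # random maps against the oracle (values distinct so sources are traceable)
  for (seed in 1:5) {
    set.seed(seed)
    ny <- 7L; nx <- 9L
    h3 <- matrix(sample(seq_len(ny * nx)) / 7, ny, nx)
    valid <- matrix(runif(ny * nx) < 0.4, ny, nx)
    if (!any(valid)) valid[1, 1] <- TRUE
    h3[!valid] <- NA
    got <- heightValues(fillGaps(HeightMap(h3, valid, nz = 64L)))
    expect_identical(got, bruteForceFill(h3, valid))
  }
})

test_that("fillGaps keeps valid pixels and is identity on full maps", {
  h <- matrix(runif(30) * 5, 5, 6)
  hm <- HeightMap(h, nz = 8L)
  expect_identical(fillGaps(hm), hm)
  h[2, 2] <- NA
  hm2 <- HeightMap(h, nz = 8L)
  out <- fillGaps(hm2)
  ok <- validMask(hm2)
  expect_identical(heightValues(out)[ok], h[ok])
})

test_that("fillGaps with zero valid pixels is a detection error", {
  hm <- HeightMap(matrix(NA_real_, 4, 4), nz = 5L)
  expect_error(fillGaps(hm), class = "peelstackDetectionError")
  expect_error(fillGaps(hm), "no surface found")
})

test_that("regularize: identity at zero parameters, constants fixed, spikes removed", {
  h <- matrix(runif(100) * 9, 10, 10)
  hm <- HeightMap(h, nz = 10L)
  p0 <- SurfaceParams(mapMedianRadius = 0, mapSmoothSigma = 0)
  expect_identical(regularizeHeightMap(hm, p0), hm)

  flat <- HeightMap(matrix(4, 12, 12), nz = 10L)
  for (p in list(SurfaceParams(), SurfaceParams(mapMedianRadius = 3,
                                                mapSmoothSigma = 5))) {
    out <- heightValues(regularizeHeightMap(flat, p))
    expect_equal(out, heightValues(flat), tolerance = 1e-8)
    expect_lt(diff(range(out)), 1e-8)
  }

  spiky <- matrix(3, 9, 9)
  spiky[5, 5] <- 13
  got <- regularizeHeightMap(HeightMap(spiky, nz = 20L),
                             SurfaceParams(mapMedianRadius = 1,
                                           mapSmoothSigma = 0))
  expect_identical(heightValues(got), bruteForceMedian(spiky, 1L))
  expect_true(all(heightValues(got) == 3))
})

test_that("regularize median filter matches the brute-force oracle on random maps", {
  for (seed in 1:3) {
    set.seed(seed)
    h <- matrix(runif(80) * 7, 8, 10)
    got <- regularizeHeightMap(HeightMap(h, nz = 8L),
                               SurfaceParams(mapMedianRadius = 2,
                                             mapSmoothSigma = 0))
    expect_equal(heightValues(got), bruteForceMedian(h, 2L))
  }
})

test_that("regularize is contractive on range and errors on gappy input", {
  set.seed(5)
  h <- matrix(runif(256) * 9, 16, 16)
  hm <- HeightMap(h, nz = 10L)
  out <- regularizeHeightMap(hm, SurfaceParams())
  expect_gte(min(heightValues(out)), min(h))
  expect_lte(max(heightValues(out)), max(h))
  h[1, 1] <- NA
  expect_error(regularizeHeightMap(HeightMap(h, nz = 10L), SurfaceParams()),
               class = "peelstackInputError")
})

test_that("detection is deterministic and validates its inputs", {
  sim <- simulateStack(phantomSpec(shape = c(12L, 24L, 24L), seed = 8L))
  a <- detectSurface(sim$stack, SurfaceParams())
  b <- detectSurface(sim$stack, SurfaceParams())
  expect_identical(heightValues(a), heightValues(b))
  expect_error(detectSurface(sim$stack, SurfaceParams(channel = 5)),
               class = "peelstackInputError")
  expect_error(detectSurface(sim$stack, SurfaceParams(minRun = 50)),
               class = "peelstackInputError")
})

test_that("tilted-plane phantom is recovered within half a slice under noise", {
  rmse <- vapply(1:3, function(seed) {
    sim <- simulateStack(phantomSpec(
      surfaceModel = "plane", baseDepth = 2, tiltX = 0.02, tiltY = 0,
      shape = c(30L, 128L, 128L), noiseSigma = 5, seed = seed))
    hm <- extractSurface(sim$stack)
    sqrt(mean((heightValues(hm) - trueHeight(sim$truth))^2))
  }, numeric(1))
  expect_lt(mean(rmse), 0.5)
})
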