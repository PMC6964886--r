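flatHeight <- function(h, ny = 8L, nx = 8L, nz = 12L)
  HeightMap(matrix(h, ny, nx), nz = nz)

test_that("layer mask selects [h + offset, h + offset + depth) per column", {
  hm <- flatHeight(5)
  m <- maskArray(makeLayerMask(c(12L, 8L, 8L), hm, PeelSpec(0, 3)))
  for (yy in 1:8) expect_identical(which(m[, yy, 1]) - 1L, 5:7)
  # deep offset clips to an empty selection without error
  hmDeep <- flatHeight(11)
  mEmpty <- maskArray(makeLayerMask(c(12L, 8L, 8L), hmDeep, PeelSpec(2, 3)))
  expect_identical(sum(mEmpty), 0L)
})

test_that("fractional bounds follow the half-open interval rule", {
  hm <- flatHeight(4.3, nz = 12L)
  m <- maskArray(makeLayerMask(c(12L, 8L, 8L), hm, PeelSpec(0, 2)))
  expect_identical(which(m[, 1, 1]) - 1L, c(5L, 6L))   # [4.3, 6.3) -> {5, 6}
  expect_identical(maskArray(makeLayerMask(c(12L, 8L, 8L), hm,
                                           PeelSpec(0, 2))),
                   bruteForceMask(heightValues(hm), 0, 2, 12L))
})

test_that("micrometre specs convert with the z voxel pitch", {
  v <- array(1, c(1, 12, 8, 8))
  s <- ImageStack(v, voxelSize = c(0.5, 0.2, 0.2))
  hm <- flatHeight(5)
  mUm <- makeLayerMask(s, hm, PeelSpec(offset = 1, depth = 2, units = "um"))
  mSl <- makeLayerMask(s, hm, PeelSpec(offset = 2, depth = 4))
  expect_identical(maskArray(mUm), maskArray(mSl))
})

test_that("masks match the brute-force half-open oracle for arbitrary height maps", {
  set.seed(31)
  h <- matrix(runif(8 * 8) * 9 + 1, 8, 8)
  hm <- HeightMap(h, nz = 12L)
  for (od in list(c(0, 3), c(1.5, 2.25), c(4, 8), c(0.7, 0.3))) {
    got <- maskArray(makeLayerMask(c(12L, 8L, 8L), hm,
                                   PeelSpec(od[1], od[2])))
    expect_identical(got, bruteForceMask(h, od[1], od[2], 12L))
  }
})

test_that("adjacent layers tile each column exactly", {
  set.seed(32)
  h <- matrix(runif(16 * 16) * 10, 16, 16)
  hm <- HeightMap(h, nz = 12L)
  dims <- c(12L, 16L, 16L)
  for (d1 in c(1, 2.5, 4)) {
    for (d2 in c(1, 3.75)) {
      a <- maskArray(makeLayerMask(dims, hm, PeelSpec(0, d1)))
      b <- maskArray(makeLayerMask(dims, hm, PeelSpec(d1, d2)))
      u <- maskArray(makeLayerMask(dims, hm, PeelSpec(0, d1 + d2)))
      expect_false(any(a & b))
      expect_identical(a | b, u)
    }
  }
})

test_that("increasing the offset weakly deepens the mean selected z", {
  set.seed(33)
  h <- matrix(runif(10 * 10) * 5, 10, 10)
  hm <- HeightMap(h, nz = 16L)
  meanZ <- vapply(c(0, 1, 2.5, 4, 6), function(o) {
    m <- maskArray(makeLayerMask(c(16L, 10L, 10L), hm, PeelSpec(o, 3)))
    mean(slice.index(m, 1)[m] - 1)
  }, numeric(1))
  expect_true(all(diff(meanZ) >= 0))
})

test_that("peel keeps masked voxels, zeroes the rest, and is idempotent", {
  s <- randomIntStack(8L, 10L, 10L, nc = 2L, seed = 41L)
  m <- randomRunMask(8L, 10L, 10L, seed = 42L)
  full <- LayerMask(array(TRUE, stackDim(s)))
  none <- LayerMask(array(FALSE, stackDim(s)))
  expect_identical(voxels(peelStack(s, full)), voxels(s))
  expect_true(all(voxels(peelStack(s, none)) == 0))
  p <- peelStack(s, m)
  expect_identical(voxels(peelStack(p, m)), voxels(p))
  # conservation: peeled total equals masked-voxel total, per channel
  for (ci in 1:2) {
    expect_identical(sum(voxels(p)[ci, , , ]),
                     sum(voxels(s)[ci, , , ][maskArray(m)]))
  }
  bad <- LayerMask(array(TRUE, c(3L, 3L, 3L)))
  expect_error(peelStack(s, bad), class = "peelstackInputError")
})

test_that("sum projection conserves masked intensity exactly on integer stacks", {
  s <- randomIntStack(8L, 10L, 10L, nc = 2L, seed = 43L)
  m <- randomRunMask(8L, 10L, 10L, seed = 44L)
  proj <- projectLayer(s, m, method = "sum")
  for (ci in 1:2) {
    expect_identical(sum(projectionPixels(proj)[ci, , ]),
                     sum(voxels(s)[ci, , , ][maskArray(m)]))
  }
  # all-ones channel under a flat 4-deep mask projects to constant 4
  ones <- ImageStack(array(1, c(6, 5, 5)))
  flat <- makeLayerMask(c(6L, 5L, 5L), flatHeight(1, 5L, 5L, 6L),
                        PeelSpec(0, 4))
  expect_true(all(projectionPixels(projectLayer(ones, flat)) == 4))
  # empty mask -> all-zero projection
  none <- LayerMask(array(FALSE, c(6L, 5L, 5L)))
  expect_true(all(projectionPixels(projectLayer(ones, none)) == 0))
})

test_that("full-mask sum projection equals the classic Z-sum projection", {
  s <- randomIntStack(7L, 9L, 9L, seed = 45L)
  proj <- projectLayer(s, mask = NULL, method = "sum")
  classic <- apply(voxels(s)[1, , , ], c(2, 3), sum)
  expect_identical(projectionPixels(proj)[1, , ], classic)
})

test_that("max projection takes the layer maximum and 0 on empty columns", {
  v <- array(0, c(4, 3, 3))
  v[, 1, 1] <- c(5, 9, 2, 7)
  s <- ImageStack(v)
  m <- array(FALSE, c(4, 3, 3))
  m[1:3, 1, 1] <- TRUE                     # column (1,1): max over z 0..2
  proj <- projectLayer(s, LayerMask(m), method = "max")
  expect_identical(projectionPixels(proj)[1, 1, 1], 9)
  expect_identical(projectionPixels(proj)[1, 2, 2], 0)
  expect_error(projectLayer(s, LayerMask(m), method = "median"),
               class = "peelstackInputError")
})

test_that("quantifyLayer returns count, total and mean per channel", {
  s <- ImageStack(array(3, c(6, 4, 4)))
  m <- makeLayerMask(c(6L, 4L, 4L), flatHeight(1, 4L, 4L, 6L), PeelSpec(0, 2))
  st <- quantifyLayer(s, m)
  expect_identical(st$voxel_count, 32L)
  expect_identical(st$total_intensity, 96)
  expect_identical(st$mean_intensity, 3)
  expect_equal(st$mean_intensity * st$voxel_count, st$total_intensity)
  none <- LayerMask(array(FALSE, c(6L, 4L, 4L)))
  expect_error(quantifyLayer(s, none), "empty layer")
})
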