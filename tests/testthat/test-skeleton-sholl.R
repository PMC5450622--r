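test_that("a single voxel is its own skeleton", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  sk <- skeletonize3d(m)
  expect_equal(nrow(sk@voxels), 1L)
  expect_equal(nrow(sk@edges), 0L)
  expect_equal(unname(sk@voxels[1, ]), c(2, 2, 2))
})

test_that("a solid tube thins to a single path reaching the tube ends", {
  sk <- skeletonize3d(digitalTube(radius = 2L, x0 = 4L, x1 = 53L))
  expect_equal(nrow(sk@edges), nrow(sk@voxels) - 1L)   # a tree
  deg <- tabulate(c(sk@edges), nbins = nrow(sk@voxels))
  ends <- sk@voxels[deg == 1L, , drop = FALSE]
  expect_equal(nrow(ends), 2L)
  expect_lte(min(abs(ends[, 1] - 4)), 3)
  expect_lte(min(abs(ends[, 1] - 53)), 3)
})

test_that("thinning preserves the 26-connected component count", {
  m <- digitalBall(5L, dims = c(40L, 40L, 40L), center = c(10, 10, 10)) |
       digitalBall(5L, dims = c(40L, 40L, 40L), center = c(29, 29, 29))
  sk <- skeletonize3d(m)
  lab <- array(FALSE, dim(m))
  lab[cbind(sk@voxels[, 2] + 1L, sk@voxels[, 1] + 1L, sk@voxels[, 3] + 1L)] <- TRUE
  expect_equal(countComponents26(lab), countComponents26(m))
  expect_equal(countComponents26(m), 2L)
})

test_that("skeleton voxels are a subset of the mask", {
  set.seed(31)
  m <- digitalBall(7L)
  sk <- skeletonize3d(m)
  expect_true(all(m[cbind(sk@voxels[, 2] + 1L, sk@voxels[, 1] + 1L,
                          sk@voxels[, 3] + 1L)]))
  expect_error(skeletonize3d(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("soma center is the distance-transform argmax", {
  m <- digitalBall(10L, dims = c(64L, 64L, 33L), center = c(32, 32, 16))
  expect_equal(unname(somaCenter(m, voxelGeometry(1, 1, 1))), c(32, 32, 16))
  # thin tube plus a clearly larger ball: center lands in the ball
  m2 <- digitalTube(radius = 2L, x0 = 5L, x1 = 55L, dims = c(40L, 70L, 40L),
                    yc = 20L, zc = 20L)
  m2 <- m2 | digitalBall(8L, dims = c(40L, 70L, 40L), center = c(20, 60, 20))
  cen <- somaCenter(m2, voxelGeometry(1, 1, 1))
  expect_lt(sqrt(sum((cen - c(60, 20, 20))^2)), 3)
  # single voxel: the only candidate
  m3 <- array(FALSE, c(4, 4, 4)); m3[2, 3, 4] <- TRUE
  expect_equal(unname(somaCenter(m3)), c(2, 1, 3))
})

test_that("a straight ray crosses every sphere exactly once", {
  thin <- array(FALSE, c(5L, 105L, 5L)); thin[3, 3:103, 3] <- TRUE
  sk <- skeletonFromMask(thin, voxelGeometry(1, 1, 1))
  p <- shollProfile(sk, center = c(2, 2, 2), radii = seq(10, 90, 10))
  expect_equal(p@counts, rep(1L, 9))
  # beyond the skeleton: zero
  p2 <- shollProfile(sk, center = c(2, 2, 2), radii = c(150, 200))
  expect_equal(p2@counts, c(0L, 0L))
})

test_that("a Y-skeleton steps from 1 to 2 crossings at the bifurcation", {
  # stem of 40 voxels along x, forking into two diagonal branches
  thin2 <- array(FALSE, c(120L, 120L, 3L))
  thin2[60, 3:43, 2] <- TRUE
  for (k in 1:50) {
    thin2[60 + k, 43 + k, 2] <- TRUE
    thin2[60 - k, 43 + k, 2] <- TRUE
  }
  sk <- skeletonFromMask(thin2, voxelGeometry(1, 1, 1))
  cen <- c(2, 59, 1)                            # stem origin (x, y, z)
  p <- shollProfile(sk, center = cen, radii = c(10, 20, 30, 40, 50, 60, 70, 80, 90))
  expect_equal(p@counts[1:4], rep(1L, 4))       # before the fork at 40
  expect_equal(p@counts[5:9], rep(2L, 5))       # after the fork
})

test_that("edge-crossing counts equal the brute-force oracle on random skeletons", {
  set.seed(202)
  for (i in 1:25) {
    # random-walk skeleton
    dims <- c(40L, 40L, 20L)
    pos <- c(20L, 20L, 10L)
    thin <- array(FALSE, dims)
    for (s in 1:60) {
      thin[pos[2] + 1L, pos[1] + 1L, pos[3] + 1L] <- TRUE
      step <- sample(c(-1L, 0L, 1L), 3, replace = TRUE)
      pos <- pmin(pmax(pos + step, 0L), c(39L, 39L, 19L))
    }
    geo <- voxelGeometry(1, 1, sample(c(1, 2), 1))
    sk <- skeletonFromMask(thin, geo)
    cen <- c(runif(1, 0, 39), runif(1, 0, 39), runif(1, 0, 19 * geo@dz))
    radii <- sort(runif(5, 1, 40))
    p <- shollProfile(sk, cen, radii)
    expect_identical(p@counts, as.integer(oracleSholl(sk, cen, radii)))
  }
})

test_that("counts are invariant under rigid translation of skeleton and center", {
  thin <- array(FALSE, c(30L, 30L, 10L)); thin[5, 3:20, 4] <- TRUE
  sk <- skeletonFromMask(thin, voxelGeometry(1, 1, 1))
  p1 <- shollProfile(sk, c(2, 4, 3), radii = c(3, 6, 9, 12))
  shifted <- array(FALSE, c(30L, 30L, 10L)); shifted[10, 8:25, 6] <- TRUE
  sk2 <- skeletonFromMask(shifted, voxelGeometry(1, 1, 1))
  p2 <- shollProfile(sk2, c(7, 9, 5), radii = c(3, 6, 9, 12))
  expect_identical(p1@counts, p2@counts)
})

test_that("distances use physical units under anisotropic geometry", {
  # a ray along z of 30 voxels at dz = 2 um spans 60 um: it crosses r = 50
  thin <- array(FALSE, c(3L, 3L, 31L)); thin[2, 2, 1:31] <- TRUE
  sk <- skeletonFromMask(thin, voxelGeometry(1, 1, 2))
  p <- shollProfile(sk, c(1, 1, 0), radii = c(50))
  expect_equal(p@counts, 1L)
})

test_that("the log-log fit recovers the power law", {
  # constant counts: density ~ r^-3 exactly
  pr <- new("ShollProfile", center = c(0, 0, 0),
            radii = seq(10, 90, 10), counts = rep(100L, 9))
  f <- shollFit(pr)@fit
  expect_equal(unname(f["slope"]), -3, tolerance = 1e-12)
  expect_equal(unname(f["r.squared"]), 1, tolerance = 1e-12)
  # counts ~ r^3: flat density
  r <- seq(10, 50, 10)
  pr2 <- new("ShollProfile", center = c(0, 0, 0), radii = r,
             counts = as.integer(round(0.001 * r^3)))
  f2 <- shollFit(pr2)@fit
  expect_lt(abs(f2["slope"]), 0.05)
  # one usable point: error
  pr3 <- new("ShollProfile", center = c(0, 0, 0), radii = c(10, 20, 30),
             counts = c(0L, 5L, 0L))
  expect_error(shollFit(pr3), "2 radii")
})

test_that("shollTable exports the fitted quantities", {
  pr <- new("ShollProfile", center = c(0, 0, 0),
            radii = c(10, 20), counts = c(4L, 0L))
  tab <- shollTable(pr)
  expect_equal(tab$log10_r, log10(c(10, 20)))
  expect_true(is.na(tab$log10_count_per_volume[2]))
  expect_equal(tab$log10_count_per_volume[1], log10(4 / (4 / 3 * pi * 1000)))
})
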