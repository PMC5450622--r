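test_that("digital balls recover analytic area and volume", {
  # r = 10 and 12 here keep this fast; the full r in {10,15,20,25} sweep runs
  # in the acceptance tests
  for (r in c(10L, 12L)) {
    mesh <- extractMesh(digitalBall(r), voxelGeometry(1, 1, 1))
    expect_true(meshIsClosed(mesh))
    expect_lt(abs(meshVolume(mesh) / (4 / 3 * pi * r^3) - 1), 0.03)
    expect_lt(abs(meshArea(mesh) / (4 * pi * r^2) - 1), 0.035)
  }
})

test_that("a single voxel meshes to a closed surface with Euler characteristic 2", {
  m <- array(FALSE, c(5L, 5L, 5L)); m[3, 3, 3] <- TRUE
  mesh <- extractMesh(m, voxelGeometry(1, 1, 1))
  expect_true(meshIsClosed(mesh))
  nv <- nrow(vertices(mesh)); nf <- nrow(faces(mesh))
  ne <- nf * 3 / 2                        # closed: each edge shared by 2 faces
  expect_equal(nv - ne + nf, 2)
})

test_that("boundary-touching masks still mesh closed (padding)", {
  m <- array(TRUE, c(4L, 4L, 4L))
  mesh <- extractMesh(m, voxelGeometry(1, 1, 1))
  expect_true(meshIsClosed(mesh))
  expect_gt(meshVolume(mesh), 0)
})

test_that("meshing an empty mask errors", {
  expect_error(extractMesh(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("area and volume obey similarity and rigid motion exactly", {
  mesh <- extractMesh(digitalBall(6L), voxelGeometry(1, 1, 1))
  a1 <- meshArea(mesh); v1 <- meshVolume(mesh)
  scaled <- new("TriangleMesh", vertices = mesh@vertices * 2, faces = mesh@faces)
  expect_equal(meshArea(scaled), 4 * a1)
  expect_equal(meshVolume(scaled), 8 * v1)
  shifted <- new("TriangleMesh",
                 vertices = sweep(mesh@vertices, 2, c(100, -50, 3), "+"),
                 faces = mesh@faces)
  expect_equal(meshVolume(shifted), v1)
  expect_equal(meshArea(shifted), a1)
})

test_that("anisotropic geometry scales mesh coordinates per axis", {
  mesh <- extractMesh(digitalBall(6L), voxelGeometry(0.62, 0.62, 1.24))
  iso <- extractMesh(digitalBall(6L), voxelGeometry(1, 1, 1))
  expect_equal(meshVolume(mesh), meshVolume(iso) * 0.62 * 0.62 * 1.24)
})

test_that("two flat triangles have the closed-form area and an open-mesh error", {
  sq <- new("TriangleMesh",
            vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
            faces = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  expect_equal(meshArea(sq), 1)
  expect_false(meshIsClosed(sq))
  expect_error(meshVolume(sq), "not closed")
})

test_that("voxel volume is count times voxel size", {
  m <- array(FALSE, c(4, 4, 4)); m[2, 2, 2] <- TRUE
  expect_equal(voxelVolume(m, voxelGeometry(1, 1, 1)), 1)
  cub <- array(TRUE, c(10, 10, 10))
  expect_equal(voxelVolume(cub, voxelGeometry(0.62, 0.62, 1.24)),
               1000 * 0.62 * 0.62 * 1.24)
  expect_equal(voxelVolume(array(FALSE, c(3, 3, 3))), 0)
})

test_that("mesh and voxel volume agree on balls within 3%", {
  for (r in c(10L, 12L)) {
    m <- digitalBall(r)
    mv <- meshVolume(extractMesh(m, voxelGeometry(1, 1, 1)))
    expect_lt(abs(mv / voxelVolume(m, voxelGeometry(1, 1, 1)) - 1), 0.03)
  }
})

test_that("GU index matches its definition on constructed stacks", {
  g <- voxelGeometry(1, 1, 1)
  # constant stack: 1 regardless of mask
  st <- imageStack(array(80L, c(8, 8, 4)), 8L, g)
  mask <- array(FALSE, c(8, 8, 4)); mask[1:4, , ] <- TRUE
  expect_equal(guIndex(st, mask), 1)
  # exact two-level segmentation: 1
  vol <- array(50L, c(8, 8, 4)); vol[mask] <- 200L
  expect_equal(guIndex(imageStack(vol, 8L, g), mask), 1)
  expect_equal(guIndex(imageStack(vol, 8L, g), mask, mode = "foreground"), 1)
  # half-half {0, 255} foreground over constant background: 0.5
  vol2 <- array(100L, c(8, 8, 4))
  mask2 <- array(FALSE, c(8, 8, 4)); mask2[, , 1:2] <- TRUE
  vol2[, , 1] <- 0L; vol2[, , 2] <- 255L
  expect_equal(guIndex(imageStack(vol2, 8L, g), mask2), 0.5)
})

test_that("GU is bounded, rescaling-invariant, and falls with noise", {
  set.seed(5)
  g <- voxelGeometry(1, 1, 1)
  mask <- digitalBall(6L)
  base <- array(40, dim(mask)); base[mask] <- 200
  gus <- vapply(c(5, 20, 50), function(sg) {
    noisy <- pmin(pmax(floor(base + rnorm(length(base), sd = sg) + 0.5), 0), 255)
    guIndex(imageStack(array(as.integer(noisy), dim(mask)), 8L, g), mask)
  }, 0)
  expect_true(all(gus >= 0 & gus <= 1))
  expect_true(all(diff(gus) < 0))         # more noise, lower GU
  # affine intensity rescaling leaves GU unchanged (12-bit head-room)
  vol <- array(as.integer(base), dim(mask))
  g1 <- guIndex(imageStack(vol, 8L, g), mask)
  g2 <- guIndex(imageStack(vol * 2L + 100L, 12L, g), mask)
  expect_equal(g1, g2)
  expect_error(guIndex(imageStack(vol, 8L, g), array(FALSE, c(2, 2, 2))),
               "dimensions")
})

test_that("metricsTable reports one consistent row per object", {
  st <- zeroStack(c(32L, 32L, 8L))
  st@data[10:20, 10:20, 3:5] <- 180L
  s <- newSession(st); s <- addObject(s, "cube"); s@timerRunning <- TRUE
  for (z in 2:4) s <- drawRegion(s, z, squarePts(9, 9, 19, 19))
  tab <- metricsTable(s, st)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$voxel_count, 11 * 11 * 3)
  expect_gt(tab$gu, 0.99)
  expect_lt(abs(tab$mesh_volume_um3 / tab$voxel_volume_um3 - 1), 0.25)
})
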