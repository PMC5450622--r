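test_that("elapsed time sums the active intervals from the timestamps", {
  st <- zeroStack()
  sq <- squarePts(5, 5, 10, 10)
  s <- replayScript(st, list(
    action("new_object", 0),
    action("draw", 5, slice = 1, points = sq),
    action("pause", 10),
    action("resume", 50),
    action("draw", 60, slice = 1, points = sq),
    action("pause", 70)))
  expect_identical(elapsedSeconds(s, 1), 30)   # (10-0) + (70-50)
})

test_that("time is attributed to the object active during each interval", {
  st <- zeroStack()
  s <- replayScript(st, list(
    action("new_object", 0),                 # obj 1 active 0..20
    action("new_object", 20),                # obj 2 active 20..25
    action("select_object", 25, object = 1L),  # obj 1 active 25..32
    action("pause", 32)))
  expect_equal(elapsedSeconds(s), c(27, 5))
})

test_that("an unterminated script closes at the final timestamp", {
  st <- zeroStack()
  s <- replayScript(st, list(
    action("new_object", 0),
    action("draw", 12, slice = 0, points = squarePts(1, 1, 4, 4))))
  expect_identical(elapsedSeconds(s, 1), 12)
})

test_that("times round to millisecond resolution and never decrease", {
  st <- zeroStack()
  s <- replayScript(st, list(action("new_object", 0),
                             action("pause", 1.23456)))
  expect_identical(elapsedSeconds(s, 1), 1.235)
})

test_that("an empty script yields an empty session", {
  s <- replayScript(zeroStack(), list())
  expect_equal(nObjects(s), 0L)
})

test_that("draw then undo inside composes to an empty mask", {
  st <- zeroStack()
  s <- replayScript(st, list(
    action("new_object", 0),
    action("draw", 1, slice = 2, points = squarePts(10, 10, 20, 20)),
    action("undo", 2, slice = 2, points = rbind(c(15, 15)))))
  expect_false(any(objectMask(s, 1)))
})

test_that("invalid scripts raise identifiable errors", {
  st <- zeroStack()
  expect_error(replayScript(st, list(
    action("draw", 0, slice = 0, points = squarePts(1, 1, 3, 3)))),
    "active object")
  expect_error(replayScript(st, list(
    action("new_object", 5),
    action("pause", 1))), "non-decreasing")
  expect_error(replayScript(st, list(
    action("new_object", 0),
    action("select_object", 1, object = 3L))), "out of range")
})

test_that("replay is deterministic and slice-local for random scripts", {
  set.seed(123)
  st <- zeroStack(c(64L, 64L, 5L))
  for (rep in 1:100) {
    nact <- sample(2:6, 1)
    t <- 0
    script <- list(action("new_object", 0))
    touched <- integer(0)
    for (i in seq_len(nact)) {
      t <- t + runif(1, 0.1, 2)
      z <- sample(0:4, 1)
      kind <- sample(c("draw", "undo", "split"), 1)
      a <- switch(kind,
        draw = action("draw", t, slice = z, points = starPolygon(5, 2, 61)),
        undo = action("undo", t, slice = z,
                      points = cbind(runif(1, 0, 63), runif(1, 0, 63))),
        split = action("split", t, slice = z,
                       points = rbind(runif(2, 0, 63), runif(2, 0, 63))))
      script <- c(script, list(a))
      touched <- c(touched, z)
    }
    s1 <- suppressWarnings(replayScript(st, script))
    s2 <- suppressWarnings(replayScript(st, script))
    expect_identical(s1@objects[[1]]@mask, s2@objects[[1]]@mask)
    expect_identical(elapsedSeconds(s1), elapsedSeconds(s2))
    # slice-locality of the final edit: replay all but the last action,
    # then the full script; all other slices must be bit-identical
    sPre <- suppressWarnings(replayScript(st, script[-length(script)]))
    zLast <- touched[length(touched)]
    for (z in setdiff(0:4, zLast))
      expect_identical(s1@objects[[1]]@mask[, , z + 1],
                       sPre@objects[[1]]@mask[, , z + 1])
  }
})

test_that("draw only adds and undo/split only remove foreground", {
  set.seed(77)
  s <- freshSession()
  for (i in 1:10) {
    before <- objectMask(s, 1)
    s <- drawRegion(s, 2, starPolygon(6, 2, 61))
    expect_true(all(objectMask(s, 1)[before]))      # monotone
  }
  before <- objectMask(s, 1)
  s <- splitLine(s, 2, rbind(c(0, 30), c(63, 33)))
  expect_true(all(before[objectMask(s, 1)]))        # anti-monotone
  suppressWarnings(s <- undoClick(s, 2, c(31, 31)))
  expect_true(all(before[objectMask(s, 1)]))
})

test_that("action scripts survive a JSON round-trip", {
  dir <- withr::local_tempdir()
  script <- list(
    action("new_object", 0),
    action("draw", 1.5, slice = 2, points = squarePts(3, 3, 9, 9)),
    action("undo", 2.25, slice = 2, points = rbind(c(5.5, 5.5))),
    action("pause", 3))
  p <- file.path(dir, "script.json")
  writeActionScript(script, p)
  back <- readActionScript(p)
  s1 <- replayScript(zeroStack(), script)
  s2 <- replayScript(zeroStack(), back)
  expect_identical(s1@objects[[1]]@mask, s2@objects[[1]]@mask)
  expect_identical(elapsedSeconds(s1), elapsedSeconds(s2))
})

test_that("sessions survive a container round-trip", {
  dir <- withr::local_tempdir()
  s <- freshSession()
  s <- drawRegion(s, 1, squarePts(5, 5, 20, 20))
  s@objects[[1]]@elapsedSeconds <- 12.345
  s <- addObject(s, name = "second")
  s <- drawRegion(s, 3, squarePts(30, 30, 40, 44))
  s@objects[[1]]@mesh <- extractMesh(objectMask(s, 1), voxelGeometry(1, 1, 1))
  p <- file.path(dir, "sess.tar")
  saveSession(s, p)
  r <- loadSession(p)
  expect_equal(nObjects(r), 2L)
  expect_identical(objectMask(r, 1), objectMask(s, 1))
  expect_identical(objectMask(r, 2), objectMask(s, 2))
  expect_equal(elapsedSeconds(r), elapsedSeconds(s), tolerance = 1e-9)
  expect_equal(objectNames(r), objectNames(s))
  # cached mesh preserved (vertex/face counts)
  expect_equal(dim(vertices(r@objects[[1]]@mesh)),
               dim(vertices(s@objects[[1]]@mesh)))
  expect_equal(dim(faces(r@objects[[1]]@mesh)),
               dim(faces(s@objects[[1]]@mesh)))
})

test_that("a session can be loaded, extended by replay, and saved again", {
  dir <- withr::local_tempdir()
  st <- zeroStack()
  s <- replayScript(st, list(
    action("new_object", 0),
    action("draw", 2, slice = 0, points = squarePts(5, 5, 10, 10)),
    action("pause", 3)))
  p <- file.path(dir, "a.tar")
  saveSession(s, p)
  r <- loadSession(p)
  r <- replayScript(st, list(
    action("resume", 0),
    action("select_object", 0, object = 1L),
    action("draw", 1, slice = 2, points = squarePts(30, 30, 40, 40)),
    action("pause", 2)), session = r)
  p2 <- file.path(dir, "b.tar")
  saveSession(r, p2)
  r2 <- loadSession(p2)
  expect_true(any(objectMask(r2, 1)[, , 3]))
  expect_true(any(objectMask(r2, 1)[, , 1]))
})

test_that("corrupt containers are rejected", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.tar")
  writeLines("not a tar archive", p)
  expect_error(loadSession(p), "corrupt")
  # truncated container
  s <- freshSession(c(16L, 16L, 2L))
  s <- drawRegion(s, 0, squarePts(2, 2, 8, 8))
  p2 <- file.path(dir, "good.tar")
  saveSession(s, p2)
  sz <- file.size(p2)
  con <- file(p2, "rb"); bytes <- readBin(con, "raw", sz %/% 3); close(con)
  p3 <- file.path(dir, "trunc.tar")
  writeBin(bytes, p3)
  expect_error(loadSession(p3), "corrupt|missing|manifest")
})
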