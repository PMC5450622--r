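test_that("drawing unions regions and is idempotent and monotone", {
  s <- freshSession()
  s <- drawRegion(s, 3, squarePts(5, 5, 10, 10))
  s <- drawRegion(s, 3, squarePts(30, 30, 40, 40))
  lab <- mansegkit:::.label2d8(objectMask(s, 1)[, , 4])
  expect_equal(max(lab), 2)               # two disjoint components
  before <- objectMask(s, 1)
  s <- drawRegion(s, 3, squarePts(5, 5, 10, 10))   # same square again
  expect_identical(objectMask(s, 1), before)       # idempotent union
  # overlapping squares: inclusion-exclusion on pixel counts
  a <- rasterizePolygon(squarePts(5, 5, 15, 15), 64, 64)
  b <- rasterizePolygon(squarePts(10, 10, 20, 20), 64, 64)
  s2 <- freshSession()
  s2 <- drawRegion(s2, 0, squarePts(5, 5, 15, 15))
  s2 <- drawRegion(s2, 0, squarePts(10, 10, 20, 20))
  expect_equal(sum(objectMask(s2, 1)[, , 1]),
               sum(a) + sum(b) - sum(a & b))
})

test_that("undo removes exactly the clicked 8-connected region", {
  s <- freshSession()
  s <- drawRegion(s, 1, squarePts(5, 5, 10, 10))
  s <- undoClick(s, 1, c(7, 7))
  expect_false(any(objectMask(s, 1)))     # full removal
  # locality: other region untouched bit-for-bit
  s <- drawRegion(s, 1, squarePts(5, 5, 10, 10))
  s <- drawRegion(s, 1, squarePts(30, 5, 40, 12))
  keep <- objectMask(s, 1)[, 31:41, 2]
  s <- undoClick(s, 1, c(7, 7))
  expect_identical(objectMask(s, 1)[, 31:41, 2], keep)
  expect_false(any(objectMask(s, 1)[, 1:20, 2]))
})

test_that("undo on background warns and changes nothing", {
  s <- freshSession()
  s <- drawRegion(s, 0, squarePts(5, 5, 10, 10))
  before <- objectMask(s, 1)
  expect_warning(s <- undoClick(s, 0, c(50, 50)), "background")
  expect_identical(objectMask(s, 1), before)
})

test_that("a supercover split separates a solid rectangle into 2 components", {
  s <- freshSession()
  s <- drawRegion(s, 0, squarePts(0, 0, 20, 4))
  s <- splitLine(s, 0, rbind(c(10, -1), c(10, 5)))
  expect_equal(max(mansegkit:::.label2d8(objectMask(s, 1)[, , 1])), 2)
})

test_that("a diagonal split leaves no 8-connected leak", {
  s <- freshSession()
  s <- drawRegion(s, 0, squarePts(10, 10, 30, 30))
  s <- splitLine(s, 0, rbind(c(9, 9), c(31, 31)))
  expect_equal(max(mansegkit:::.label2d8(objectMask(s, 1)[, , 1])), 2)
})

test_that("splitting over background is a no-op", {
  s <- freshSession()
  s <- drawRegion(s, 0, squarePts(5, 5, 10, 10))
  before <- objectMask(s, 1)
  s <- splitLine(s, 0, rbind(c(40, 0), c(40, 60)))
  expect_identical(objectMask(s, 1), before)
})

test_that("edits require a running timer and an active object", {
  s <- newSession(dims = c(16L, 16L, 2L))
  expect_error(drawRegion(s, 0, squarePts(1, 1, 5, 5)), "active object")
  s <- addObject(s)                        # timer still paused
  s@timerRunning <- FALSE
  expect_error(drawRegion(s, 0, squarePts(1, 1, 5, 5)), "timer")
  s@timerRunning <- TRUE
  expect_error(drawRegion(s, 5, squarePts(1, 1, 5, 5)), "slice")
})

test_that("overlay blends per the stated formula", {
  st <- zeroStack(c(8L, 8L, 3L))
  st@data[, , 1] <- 100L
  s <- newSession(st)
  s <- addObject(s); s@timerRunning <- TRUE
  s <- drawRegion(s, 1, squarePts(1, 1, 6, 6))
  ov <- renderOverlay(s, st, 0, direction = 1L, alpha = 0.4)
  expect_equal(ov[3, 3, 2], 162)          # 0.6*100 + 0.4*255
  expect_equal(ov[3, 3, 1], 100)
  expect_equal(ov[1, 1, 2], 100)          # mask false there: original shows
  # alpha = 0: original replicated
  ov0 <- renderOverlay(s, st, 0, direction = 1L, alpha = 0)
  for (ch in 1:3) expect_true(all(ov0[, , ch] == 100))
  # empty mask: original replicated for any alpha
  s2 <- newSession(st); s2 <- addObject(s2)
  ov2 <- renderOverlay(s2, st, 0, direction = 1L, alpha = 0.7)
  for (ch in 1:3) expect_true(all(ov2[, , ch] == 100))
  expect_error(renderOverlay(s, st, 2, direction = 1L), "range")
})

test_that("overlay rescales 16-bit intensities to 8 bits", {
  vol <- array(0L, c(4L, 4L, 2L)); vol[, , 1] <- 65535L
  st <- imageStack(vol, 16L, voxelGeometry(1, 1, 1))
  s <- addObject(newSession(st))
  ov <- renderOverlay(s, st, 0, direction = 1L, alpha = 0)
  expect_true(all(ov[, , 1] == 255))
})

test_that("merge-highlight saturates foreground and only foreground", {
  vol <- array(37L, c(8L, 8L, 2L))
  st <- imageStack(vol, 8L, voxelGeometry(1, 1, 1))
  mask <- array(FALSE, c(8L, 8L, 2L)); mask[2, 3, 1] <- TRUE
  obj <- new("SegmentedObject", mask = mask, elapsedSeconds = 0,
             name = "o", mesh = NULL)
  out <- mergeHighlight(st, obj)
  expect_equal(stackData(out)[2, 3, 1], 255L)
  expect_equal(sum(stackData(out) == 255L), 1L)
  # 12-bit saturates to 4095
  st12 <- imageStack(vol, 12L, voxelGeometry(1, 1, 1))
  expect_equal(stackData(mergeHighlight(st12, obj))[2, 3, 1], 4095L)
  # empty mask: identity
  obj0 <- new("SegmentedObject", mask = array(FALSE, c(8L, 8L, 2L)),
              elapsedSeconds = 0, name = "o", mesh = NULL)
  expect_identical(stackData(mergeHighlight(st, obj0)), stackData(st))
  # dimension mismatch
  objBad <- new("SegmentedObject", mask = array(FALSE, c(4L, 4L, 2L)),
                elapsedSeconds = 0, name = "o", mesh = NULL)
  expect_error(mergeHighlight(st, objBad), "dimensions")
})
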