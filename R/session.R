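# The headless editing core. A session ("datamatrix") owns per-object binary
# volumes; edits address one slice of the active object and are only legal
# while the timer runs. All slice/pixel coordinates are 0-based.

#' Create an empty segmentation session
#'
#' @param stack an \linkS4class{ImageStack}, or NULL if \code{dims} and
#'   \code{geometry} are given directly.
#' @param dims integer (M, N, Z); ignored when \code{stack} is given.
#' @param geometry a \linkS4class{VoxelGeometry}; ignored when \code{stack}
#'   is given.
#' @return a \linkS4class{SegSession} with no objects and the timer paused.
#' @export
newSession <- function(stack = NULL, dims = NULL, geometry = voxelGeometry()) {
  if (!is.null(stack)) {
    stopifnot(is(stack, "ImageStack"))
    dims <- dim(stack@data)
    geometry <- stack@geometry
  }
  new("SegSession", dims = as.integer(dims), geometry = geometry,
      objects = list(), activeObject = 0L, timerRunning = FALSE)
}

#' Add a new (empty) segmented object and make it active
#'
#' @param session a \linkS4class{SegSession}.
#' @param name label for the object.
#' @return the updated session.
#' @export
addObject <- function(session, name = sprintf("object_%d", length(session@objects) + 1L)) {
  obj <- new("SegmentedObject",
             mask = array(FALSE, dim = session@dims),
             elapsedSeconds = 0, name = name, mesh = NULL)
  session@objects <- c(session@objects, obj)
  session@activeObject <- length(session@objects)
  session
}

#' Select the active object
#'
#' @param session a \linkS4class{SegSession}.
#' @param i 1-based object index.
#' @return the updated session.
#' @export
selectObject <- function(session, i) {
  i <- as.integer(i)
  if (i < 1L || i > length(session@objects))
    stop("object index out of range: ", i, call. = FALSE)
  session@activeObject <- i
  session
}

checkEdit <- function(session, slice) {
  if (session@activeObject == 0L)
    stop("no active object; add one before editing", call. = FALSE)
  if (!session@timerRunning)
    stop("edits are only allowed while the timer runs", call. = FALSE)
  if (slice < 0 || slice >= session@dims[3])
    stop("slice index out of range: ", slice, call. = FALSE)
}

# edits invalidate any cached mesh of the touched object
touchObject <- function(session, sliceMask) {
  i <- session@activeObject
  session@objects[[i]]@mask[, , attr(sliceMask, "z") + 1L] <- sliceMask
  session@objects[[i]]@mesh <- NULL
  session
}

#' Draw a freehand region on one slice
#'
#' Rasterizes the auto-closed polygon (see \code{\link{rasterizePolygon}})
#' and ORs it into the active object's slice mask; drawing can only add
#' foreground. Multiple regions per slice accumulate.
#'
#' @param session a \linkS4class{SegSession} with a running timer.
#' @param slice 0-based z index.
#' @param vertices n x 2 matrix of (x, y), n >= 3.
#' @return the updated session.
#' @export
drawRegion <- function(session, slice, vertices) {
  checkEdit(session, slice)
  add <- rasterizePolygon(vertices, width = session@dims[2], height = session@dims[1])
  cur <- session@objects[[session@activeObject]]@mask[, , slice + 1L]
  out <- cur | add
  attr(out, "z") <- slice
  touchObject(session, out)
}

#' Remove the clicked 8-connected region on one slice
#'
#' Clears the 8-connected 2D component of the active object's slice mask that
#' contains the clicked pixel. Removal is slice-local by design: clicking
#' operates on the slice being viewed, so work on other slices is never
#' destroyed. Clicking background is a warning no-op (a missed click, not
#' corruption).
#'
#' @param session a \linkS4class{SegSession} with a running timer.
#' @param slice 0-based z index.
#' @param point numeric length-2 (x, y); rounded half-up to a pixel.
#' @return the updated session.
#' @export
undoClick <- function(session, slice, point) {
  checkEdit(session, slice)
  x <- roundHalfUp(point[1]); y <- roundHalfUp(point[2])
  if (x < 0 || x >= session@dims[2] || y < 0 || y >= session@dims[1])
    stop("click outside the image", call. = FALSE)
  cur <- session@objects[[session@activeObject]]@mask[, , slice + 1L]
  if (!cur[y + 1L, x + 1L]) {
    warning("undo click hit background; nothing removed")
    return(session)
  }
  lab <- .label2d8(cur)
  out <- cur & (lab != lab[y + 1L, x + 1L])
  attr(out, "z") <- slice
  touchObject(session, out)
}

#' Erase along a drawn line to split touching structures
#'
#' Sets every mask pixel on the 4-connected supercover rasterization of the
#' polyline to background on the given slice. The polyline is not closed.
#' Because the erased chain is 4-connected, the two sides end up in different
#' 8-connected components; both remain in the same object.
#'
#' @param session a \linkS4class{SegSession} with a running timer.
#' @param slice 0-based z index.
#' @param points n x 2 matrix of (x, y), n >= 2.
#' @return the updated session.
#' @export
splitLine <- function(session, slice, points) {
  checkEdit(session, slice)
  pts <- supercoverLine(points)
  keep <- pts[, 1] >= 0 & pts[, 1] < session@dims[2] &
          pts[, 2] >= 0 & pts[, 2] < session@dims[1]
  cur <- session@objects[[session@activeObject]]@mask[, , slice + 1L]
  if (any(keep))
    cur[cbind(pts[keep, 2] + 1L, pts[keep, 1] + 1L)] <- FALSE
  attr(cur, "z") <- slice
  touchObject(session, cur)
}

#' Blend a slice with the mask of an adjacent slice
#'
#' Overlays the grayscale slice i with the active object's binary mask at
#' slice i + direction, the aid used to keep track of structures across
#' consecutive planes. Per pixel the overlay channel (default green) carries
#' \code{round((1 - alpha) * g8 + alpha * 255 * m)} and the other channels
#' carry \code{g8}, where \code{g8} is the intensity rescaled to 0..255.
#'
#' @param session a \linkS4class{SegSession} with at least one object.
#' @param stack the parent \linkS4class{ImageStack}.
#' @param slice 0-based z index of the displayed image.
#' @param direction -1 or +1, which neighboring mask to overlay.
#' @param alpha blend weight in [0, 1].
#' @param channel overlay channel, 1 = red, 2 = green, 3 = blue.
#' @return integer array M x N x 3 with values 0..255.
#' @export
renderOverlay <- function(session, stack, slice, direction = 1L, alpha = 0.4,
                          channel = 2L) {
  stopifnot(is(stack, "ImageStack"), direction %in% c(-1L, 1L),
            alpha >= 0, alpha <= 1)
  if (session@activeObject == 0L) stop("no active object", call. = FALSE)
  zm <- slice + direction
  if (slice < 0 || slice >= session@dims[3] || zm < 0 || zm >= session@dims[3])
    stop("slice + direction out of range", call. = FALSE)
  g <- stack@data[, , slice + 1L]
  g8 <- if (stack@bitDepth == 8L) g else
    roundHalfUp(g * 255 / (2^stack@bitDepth - 1))
  m <- session@objects[[session@activeObject]]@mask[, , zm + 1L]
  out <- array(0L, dim = c(dim(g), 3L))
  for (ch in 1:3) out[, , ch] <- as.integer(g8)
  # the translucent mask layer covers only its own pixels; elsewhere the
  # original shows through unchanged
  blend <- roundHalfUp((1 - alpha) * g8 + alpha * 255)
  out[, , channel] <- as.integer(ifelse(m, blend, g8))
  out
}

#' Highlight a segmented object inside the original stack
#'
#' Returns a copy of the stack in which every foreground voxel of the object
#' is saturated to the bit-depth maximum, the "merge" export used for
#' external 3D viewing.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param object a \linkS4class{SegmentedObject} with matching dimensions.
#' @return an \linkS4class{ImageStack}.
#' @export
mergeHighlight <- function(stack, object) {
  stopifnot(is(stack, "ImageStack"), is(object, "SegmentedObject"))
  if (!identical(dim(stack@data), dim(object@mask)))
    stop("stack and mask dimensions differ", call. = FALSE)
  out <- stack@data
  out[object@mask] <- 2L^stack@bitDepth - 1L
  imageStack(out, bitDepth = stack@bitDepth, geometry = stack@geometry)
}
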