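# Freehand-ROI rasterization. Coordinates are 0-based and continuous:
# pixel (x, y) occupies the unit cell centered at integer (x, y),
# x = column, y = row. Rounding is half-up throughout so behaviour does not
# depend on R's banker's rounding.

roundHalfUp <- function(v) floor(v + 0.5)

#' Rasterize a freehand polygon to a pixel mask
#'
#' The polygon is automatically closed (last vertex connects back to the
#' first). A pixel is set if its center is strictly inside the closed polygon
#' under the even-odd rule, or if it lies on the 8-connected rasterized
#' boundary of any edge (including the implicit closing edge), so the drawn
#' stroke itself is always part of the mask. Vertices may be subpixel and may
#' lie outside the image; the mask is clipped to the image.
#'
#' A degenerate (zero-area, collinear) polygon yields just its boundary trace.
#'
#' @param vertices numeric matrix n x 2 of (x, y) coordinates, n >= 3.
#' @param width,height image size in pixels (x in [0, width), y in [0, height)).
#' @return logical matrix height x width; \code{[y + 1, x + 1]} addresses
#'   pixel (x, y).
#' @export
rasterizePolygon <- function(vertices, width, height) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L)
    stop("a polygon needs at least 3 vertices", call. = FALSE)
  if (ncol(vertices) != 2L)
    stop("vertices must be an n x 2 matrix of (x, y)", call. = FALSE)
  mask <- matrix(FALSE, nrow = height, ncol = width)

  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx)
  nxt <- c(seq_len(n)[-1], 1L)

  # interior: even-odd crossing number at pixel centers within the bbox
  x0 <- max(0L, floor(min(vx))); x1 <- min(width - 1L, ceiling(max(vx)))
  y0 <- max(0L, floor(min(vy))); y1 <- min(height - 1L, ceiling(max(vy)))
  if (x0 <= x1 && y0 <= y1) {
    px <- rep(x0:x1, each = y1 - y0 + 1L)
    py <- rep(y0:y1, times = x1 - x0 + 1L)
    crossings <- integer(length(px))
    for (i in seq_len(n)) {
      j <- nxt[i]
      ya <- vy[i]; yb <- vy[j]; xa <- vx[i]; xb <- vx[j]
      straddles <- (ya > py) != (yb > py)
      if (any(straddles)) {
        xi <- xa + (py[straddles] - ya) / (yb - ya) * (xb - xa)
        hit <- straddles
        hit[straddles] <- px[straddles] < xi
        crossings <- crossings + hit
      }
    }
    inside <- crossings %% 2L == 1L
    mask[cbind(py[inside] + 1L, px[inside] + 1L)] <- TRUE
  }

  # boundary: 8-connected DDA between rounded endpoints of every edge
  for (i in seq_len(n)) {
    j <- nxt[i]
    pts <- dda8(vx[i], vy[i], vx[j], vy[j])
    keep <- pts[, 1] >= 0 & pts[, 1] < width & pts[, 2] >= 0 & pts[, 2] < height
    if (any(keep))
      mask[cbind(pts[keep, 2] + 1L, pts[keep, 1] + 1L)] <- TRUE
  }
  mask
}

# 8-connected line between rounded endpoints: sample the segment at
# max(|dx|, |dy|) + 1 evenly spaced points and round half-up.
dda8 <- function(xa, ya, xb, yb) {
  xa <- roundHalfUp(xa); ya <- roundHalfUp(ya)
  xb <- roundHalfUp(xb); yb <- roundHalfUp(yb)
  nsteps <- max(abs(xb - xa), abs(yb - ya))
  if (nsteps == 0) return(cbind(xa, ya))
  t <- 0:nsteps
  cbind(roundHalfUp(xa + t * (xb - xa) / nsteps),
        roundHalfUp(ya + t * (yb - ya) / nsteps))
}

#' 4-connected supercover rasterization of a polyline
#'
#' Returns every pixel whose unit cell the continuous polyline passes
#' through. Consecutive pixels differ in exactly one coordinate, so erasing
#' them severs all 8-connected paths across the line (no diagonal leak).
#' The polyline is not closed.
#'
#' @param points numeric matrix n x 2 of (x, y), n >= 2.
#' @return integer matrix of unique (x, y) pixel addresses (possibly outside
#'   the image; callers clip).
#' @export
supercoverLine <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    stop("a polyline needs at least 2 points", call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(points) - 1L))
    out[[i]] <- supercoverSegment(points[i, 1], points[i, 2],
                                  points[i + 1, 1], points[i + 1, 2])
  pts <- do.call(rbind, out)
  unique(pts)
}

# Grid traversal (cell boundaries at half-integers). At an exact corner
# crossing the x-step is taken before the y-step, inserting the intermediate
# cell and keeping the chain 4-connected.
supercoverSegment <- function(xa, ya, xb, yb) {
  cx <- roundHalfUp(xa); cy <- roundHalfUp(ya)
  ex <- roundHalfUp(xb); ey <- roundHalfUp(yb)
  dx <- xb - xa; dy <- yb - ya
  pts <- matrix(c(cx, cy), ncol = 2)
  if (dx == 0 && dy == 0) return(pts)
  stepx <- if (dx > 0) 1L else -1L
  stepy <- if (dy > 0) 1L else -1L
  # parameter t of the next vertical / horizontal cell-boundary crossing
  tForX <- function(cx) if (dx == 0) Inf else ((cx + 0.5 * stepx) - xa) / dx
  tForY <- function(cy) if (dy == 0) Inf else ((cy + 0.5 * stepy) - ya) / dy
  tx <- tForX(cx); ty <- tForY(cy)
  guard <- 4L * (abs(ex - cx) + abs(ey - cy) + 2L)
  while ((cx != ex || cy != ey) && guard > 0L) {
    guard <- guard - 1L
    if (tx <= ty) {
      cx <- cx + stepx
      tx <- tForX(cx)
    } else {
      cy <- cy + stepy
      ty <- tForY(cy)
    }
    pts <- rbind(pts, c(cx, cy))
  }
  pts
}
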