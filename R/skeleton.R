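# 3D medial-axis thinning and the skeleton graph. Thinning removes simple
# points (26-connectivity for foreground, 6 for background) in six
# directional subiterations with sequential re-checking, preserving curve
# endpoints, until stable. Simple-point deletion provably preserves
# topology, so the skeleton has the same 26-connected component count as the
# source mask.

#' Skeletonize a binary volume
#'
#' @param mask logical 3D array with at least one TRUE voxel.
#' @param geometry a \linkS4class{VoxelGeometry} carried into the skeleton.
#' @return a \linkS4class{Skeleton3D}: 0-based voxel addresses (x, y, z) and
#'   edges between 26-adjacent skeleton voxels.
#' @export
skeletonize3d <- function(mask, geometry = voxelGeometry(1, 1, 1)) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("cannot skeletonize an empty mask", call. = FALSE)
  thin <- .thin3d(mask)
  skeletonFromMask(thin, geometry)
}

#' Build a Skeleton3D from an already-thin mask
#'
#' @param thin logical 3D array of skeleton voxels.
#' @param geometry a \linkS4class{VoxelGeometry}.
#' @return a \linkS4class{Skeleton3D}.
#' @export
skeletonFromMask <- function(thin, geometry = voxelGeometry(1, 1, 1)) {
  idx <- which(thin)
  d <- dim(thin)
  y <- (idx - 1L) %% d[1]
  x <- ((idx - 1L) %/% d[1]) %% d[2]
  z <- (idx - 1L) %/% (d[1] * d[2])
  vox <- cbind(x = x, y = y, z = z)
  edges <- adjacentPairs26(vox)
  new("Skeleton3D", voxels = vox, edges = edges, geometry = geometry)
}

# all pairs of 26-adjacent voxels, found via a hash of linear addresses
adjacentPairs26 <- function(vox) {
  n <- nrow(vox)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  span <- apply(vox, 2, max) + 2L   # (sx, sy, sz)
  key <- function(x, y, z) (as.double(z) * span[1] + x) * span[2] + y
  lookup <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n))
    assign(as.character(key(vox[i, 1], vox[i, 2], vox[i, 3])), i, envir = lookup)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  # only "positive" half of the offsets so each pair appears once
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & (offs$dx > 0 | (offs$dx == 0 & offs$dy > 0))), ]
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    kk <- as.character(key(vox[, 1] + offs$dx[k], vox[, 2] + offs$dy[k],
                           vox[, 3] + offs$dz[k]))
    hit <- vapply(kk, function(s) {
      v <- lookup[[s]]
      if (is.null(v)) NA_integer_ else v
    }, 0L, USE.NAMES = FALSE)
    sel <- !is.na(hit)
    from <- c(from, which(sel))
    to <- c(to, hit[sel])
  }
  cbind(from, to)
}

#' Number of 26-connected components of a binary volume
#'
#' @param mask logical 3D array.
#' @return integer count.
#' @export
countComponents26 <- function(mask) {
  lab <- .label3d26(mask)
  max(lab)
}

#' Locate the soma as the thickest point of the mask
#'
#' Returns the foreground voxel maximizing the anisotropic Euclidean
#' distance to background (the volume border counts as background), the
#' usual stand-in for a user-picked soma center. Ties break to the smallest
#' (z, y, x) address.
#'
#' @param mask logical 3D array with at least one TRUE voxel.
#' @param geometry a \linkS4class{VoxelGeometry}.
#' @return numeric length-3 (x, y, z) in micrometers.
#' @export
somaCenter <- function(mask, geometry = voxelGeometry(1, 1, 1)) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("empty mask has no soma", call. = FALSE)
  d2 <- .edt3dSq(mask, geometry@dy, geometry@dx, geometry@dz)
  d <- dim(mask)
  best <- max(d2)
  idx <- which(d2 == best)
  y <- (idx - 1L) %% d[1]
  x <- ((idx - 1L) %/% d[1]) %% d[2]
  z <- (idx - 1L) %/% (d[1] * d[2])
  ord <- order(z, y, x)
  i <- ord[1]
  c(x = x[i] * geometry@dx, y = y[i] * geometry@dy, z = z[i] * geometry@dz)
}
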