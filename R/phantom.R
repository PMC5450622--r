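# Deterministic synthetic neuron phantoms: a seeded random binary tree
# (soma + tube segments) rasterized as a capsule union into an anisotropic
# voxel grid, then rendered with two intensity levels, Gaussian PSF blur and
# Gaussian noise. Tree coordinates are stored in pixel/slice units so the
# SWC, the ground-truth mask and the rendered stack are mutually consistent.

#' Construct a PhantomSpec
#'
#' Defaults emulate the acquisition this workflow targets: 512 x 512
#' in-plane at 0.62 um/pixel with a z-step twice the in-plane resolution,
#' 8-bit intensities with levels 30 (background) and 200 (foreground),
#' Gaussian PSF sigmas (0.2, 0.2, 0.6) um and noise sigma 10. Test fixtures
#' shrink \code{dims} for speed.
#'
#' @param seed integer RNG seed; all three phantom operations are
#'   deterministic given the seed.
#' @param dims integer (M, N, Z) voxels.
#' @param geometry a \linkS4class{VoxelGeometry}.
#' @param nBifurcations number of bifurcation nodes in the tree.
#' @param segmentLengthRange,tubeRadiusRange uniform sampling ranges, um.
#' @param somaRadius soma ball radius, um.
#' @param psfSigma length-3 Gaussian PSF sigmas (x, y, z), um.
#' @param backgroundLevel,foregroundLevel rendered intensity levels.
#' @param noiseSigma Gaussian noise sigma, intensity units.
#' @param bitDepth 8, 12 or 16.
#' @return a \linkS4class{PhantomSpec}
#' @export
phantomSpec <- function(seed = 11L, dims = c(512L, 512L, 64L),
                        geometry = voxelGeometry(0.62, 0.62, 1.24),
                        nBifurcations = 3L,
                        segmentLengthRange = c(15, 40),
                        tubeRadiusRange = c(1, 2.5),
                        somaRadius = 8,
                        psfSigma = c(0.2, 0.2, 0.6),
                        backgroundLevel = 30, foregroundLevel = 200,
                        noiseSigma = 10, bitDepth = 8L) {
  new("PhantomSpec", seed = as.integer(seed), dims = as.integer(dims),
      geometry = geometry, nBifurcations = as.integer(nBifurcations),
      segmentLengthRange = segmentLengthRange,
      tubeRadiusRange = tubeRadiusRange, somaRadius = somaRadius,
      psfSigma = psfSigma, backgroundLevel = backgroundLevel,
      foregroundLevel = foregroundLevel, noiseSigma = noiseSigma,
      bitDepth = as.integer(bitDepth))
}

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a random neuron tree
#'
#' Grows a seeded binary tree rooted at the soma (volume center): a trunk
#' leaves the soma in a random direction; bifurcation events terminate a
#' randomly chosen tip and spawn two children with perturbed directions.
#' Segment lengths and node radii are drawn uniformly from the spec ranges;
#' directions are drawn on the unit sphere in physical units. The tree has
#' exactly \code{nBifurcations} nodes with two children and is clipped to
#' the volume (regrown up to 100 times before failing).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return an \linkS4class{SwcTree} with coordinates in pixel/slice units;
#'   the root is the soma node (type 1, radius \code{somaRadius}).
#' @export
generateTree <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  withSeed(spec@seed, generateTreeImpl(spec))
}

randUnit <- function() {
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  c(s * cos(phi), s * sin(phi), z)
}

# rotate dir by a random perturbation of at most maxAngle radians
perturb <- function(dir, maxAngle) {
  repeat {
    u <- randUnit()
    axis <- c(dir[2] * u[3] - dir[3] * u[2],
              dir[3] * u[1] - dir[1] * u[3],
              dir[1] * u[2] - dir[2] * u[1])
    nl <- sqrt(sum(axis^2))
    if (nl > 1e-8) { axis <- axis / nl; break }
  }
  th <- stats::runif(1, maxAngle / 3, maxAngle)
  ct <- cos(th); st <- sin(th)
  dir * ct + st * c(axis[2] * dir[3] - axis[3] * dir[2],
                    axis[3] * dir[1] - axis[1] * dir[3],
                    axis[1] * dir[2] - axis[2] * dir[1]) +
    axis * sum(axis * dir) * (1 - ct)
}

generateTreeImpl <- function(spec) {
  g <- spec@geometry
  pitch <- c(g@dx, g@dy, g@dz)
  # physical extent of the volume; coordinates kept in um during growth
  ext <- (spec@dims[c(2, 1, 3)] - 1) * pitch
  center <- ext / 2
  margin <- max(spec@tubeRadiusRange)
  inVolume <- function(p) all(p >= margin) && all(p <= ext - margin)
  for (attempt in seq_len(100L)) {
    nodes <- data.frame(id = 1L, type = 1L,
                        x = center[1], y = center[2], z = center[3],
                        radius = spec@somaRadius, parent = -1L)
    nextId <- 2L
    dir0 <- randUnit()
    nBif <- 0L
    ok <- TRUE
    # draw a candidate endpoint from a tip without committing it
    candidateSegment <- function(fromPos, baseDir, maxAngle) {
      for (try in seq_len(40L)) {
        d <- perturb(baseDir, maxAngle)
        len <- stats::runif(1, spec@segmentLengthRange[1],
                            spec@segmentLengthRange[2])
        p <- fromPos + d * len
        if (!inVolume(p)) next
        r <- stats::runif(1, spec@tubeRadiusRange[1], spec@tubeRadiusRange[2])
        return(list(pos = p, dir = d, radius = r))
      }
      NULL
    }
    commitNode <- function(fromId, cand) {
      nodes <<- rbind(nodes, data.frame(id = nextId, type = 3L,
                                        x = cand$pos[1], y = cand$pos[2],
                                        z = cand$pos[3], radius = cand$radius,
                                        parent = fromId))
      id <- nextId
      nextId <<- nextId + 1L
      id
    }
    # a primary trunk leaves the soma first, so the root is never itself a
    # bifurcation and the downstream point-of-interest census stays exact
    trunk <- candidateSegment(center, dir0, pi / 2)
    if (is.null(trunk)) next
    trunk$id <- commitNode(1L, trunk)
    tips <- list(trunk)
    # grow: each bifurcation terminates one tip and spawns two children;
    # tips are tried in random order and both children are found before
    # either is committed, so the bifurcation and leaf censuses stay exact
    while (nBif < spec@nBifurcations && ok) {
      placed <- FALSE
      for (k in sample.int(length(tips))) {
        tip <- tips[[k]]
        k1 <- candidateSegment(tip$pos, tip$dir, pi / 2)
        k2 <- if (!is.null(k1)) candidateSegment(tip$pos, tip$dir, pi / 2)
        if (is.null(k1) || is.null(k2)) next
        k1$id <- commitNode(tip$id, k1)
        k2$id <- commitNode(tip$id, k2)
        tips <- c(tips[-k], list(k1, k2))
        nBif <- nBif + 1L
        placed <- TRUE
        break
      }
      if (!placed) ok <- FALSE
    }
    if (ok) {
      # convert to pixel/slice units
      nodes$x <- nodes$x / g@dx
      nodes$y <- nodes$y / g@dy
      nodes$z <- nodes$z / g@dz
      nodes$radius <- nodes$radius   # radii stay in um
      return(new("SwcTree", nodes = nodes))
    }
  }
  stop("could not fit a tree into the volume after 100 attempts", call. = FALSE)
}

#' Rasterize a tree into a ground-truth mask
#'
#' A voxel is foreground iff its center lies within the interpolated radius
#' of some parent-to-child segment (a capsule with linearly interpolated
#' radii; the root's soma uses its own radius as a ball). Distances are in
#' physical units.
#'
#' @param tree an \linkS4class{SwcTree} with pixel-unit coordinates and
#'   um radii.
#' @param dims integer (M, N, Z).
#' @param geometry a \linkS4class{VoxelGeometry}.
#' @return logical array (M, N, Z).
#' @export
rasterizeTree <- function(tree, dims, geometry) {
  stopifnot(is(tree, "SwcTree"))
  nd <- tree@nodes
  g <- geometry
  mask <- array(FALSE, dim = as.integer(dims))
  addBall <- function(cx, cy, cz, r) {
    # physical-space ball around (cx, cy, cz) in pixel units
    xr <- floor(cx - r / g@dx):ceiling(cx + r / g@dx)
    yr <- floor(cy - r / g@dy):ceiling(cy + r / g@dy)
    zr <- floor(cz - r / g@dz):ceiling(cz + r / g@dz)
    xr <- xr[xr >= 0 & xr < dims[2]]
    yr <- yr[yr >= 0 & yr < dims[1]]
    zr <- zr[zr >= 0 & zr < dims[3]]
    if (!length(xr) || !length(yr) || !length(zr)) return()
    gx <- (rep(xr, each = length(yr)) - cx) * g@dx
    gy <- (rep(yr, times = length(xr)) - cy) * g@dy
    plane2 <- gx^2 + gy^2
    for (z in zr) {
      dz2 <- ((z - cz) * g@dz)^2
      hit <- plane2 + dz2 <= r^2
      if (any(hit)) {
        sel <- cbind(rep(yr, times = length(xr))[hit] + 1L,
                     rep(xr, each = length(yr))[hit] + 1L)
        mask[cbind(sel, z + 1L)] <<- TRUE
      }
    }
  }
  addCapsule <- function(p0, p1, r0, r1) {
    # bounding box in pixel units, padded by the larger radius
    rmax <- max(r0, r1)
    lo <- pmin(p0, p1) - rmax / c(g@dx, g@dy, g@dz)
    hi <- pmax(p0, p1) + rmax / c(g@dx, g@dy, g@dz)
    xr <- max(0, floor(lo[1])):min(dims[2] - 1, ceiling(hi[1]))
    yr <- max(0, floor(lo[2])):min(dims[1] - 1, ceiling(hi[2]))
    zr <- max(0, floor(lo[3])):min(dims[3] - 1, ceiling(hi[3]))
    if (!length(xr) || !length(yr) || !length(zr)) return()
    # physical coordinates of voxel centers in the box
    px <- rep(xr, each = length(yr)) * g@dx
    py <- rep(yr, times = length(xr)) * g@dy
    a <- p0 * c(g@dx, g@dy, g@dz)
    b <- p1 * c(g@dx, g@dy, g@dz)
    ab <- b - a
    ab2 <- sum(ab^2)
    for (z in zr) {
      pz <- z * g@dz
      # projection parameter clamped to [0, 1]
      t <- if (ab2 == 0) rep(0, length(px)) else
        pmin(1, pmax(0, ((px - a[1]) * ab[1] + (py - a[2]) * ab[2] +
                           (pz - a[3]) * ab[3]) / ab2))
      qx <- a[1] + t * ab[1]; qy <- a[2] + t * ab[2]; qz <- a[3] + t * ab[3]
      rr <- r0 + t * (r1 - r0)
      hit <- (px - qx)^2 + (py - qy)^2 + (pz - qz)^2 <= rr^2
      if (any(hit)) {
        sel <- cbind(rep(yr, times = length(xr))[hit] + 1L,
                     rep(xr, each = length(yr))[hit] + 1L)
        mask[cbind(sel, z + 1L)] <<- TRUE
      }
    }
  }
  for (i in seq_len(nrow(nd))) {
    if (nd$parent[i] == -1L) {
      addBall(nd$x[i], nd$y[i], nd$z[i], nd$radius[i])
    } else {
      p <- nd[nd$id == nd$parent[i], ]
      addCapsule(c(p$x, p$y, p$z), c(nd$x[i], nd$y[i], nd$z[i]),
                 p$radius, nd$radius[i])
    }
  }
  if (!any(mask)) stop("tree rasterized to an empty mask", call. = FALSE)
  mask
}

#' Render a ground-truth mask into a noisy image stack
#'
#' Intensity is \code{backgroundLevel} outside and \code{foregroundLevel}
#' inside the mask, convolved with the anisotropic Gaussian PSF (sigmas in
#' physical units, converted to voxels via the geometry), plus seeded
#' Gaussian noise, clipped to the bit depth and quantized. The noise stream
#' is seeded with \code{spec@seed + 1} so it is independent of tree
#' generation but still fully determined by the spec.
#'
#' @param mask logical (M, N, Z) ground-truth mask.
#' @param spec a \linkS4class{PhantomSpec}.
#' @return an \linkS4class{ImageStack}.
#' @export
renderStack <- function(mask, spec) {
  stopifnot(is(spec, "PhantomSpec"), length(dim(mask)) == 3L)
  mx <- 2^spec@bitDepth - 1
  vol <- spec@backgroundLevel +
    (spec@foregroundLevel - spec@backgroundLevel) * mask
  g <- spec@geometry
  sig <- spec@psfSigma / c(g@dx, g@dy, g@dz)   # (x, y, z) in voxels
  if (any(sig > 0)) vol <- gaussBlur3d(vol, c(sig[2], sig[1], sig[3]))
  if (spec@noiseSigma > 0)
    vol <- vol + withSeed(spec@seed + 1L,
                          array(stats::rnorm(length(vol), sd = spec@noiseSigma),
                                dim = dim(vol)))
  vol <- pmin(pmax(roundHalfUp(vol), 0), mx)
  imageStack(array(as.integer(vol), dim = dim(mask)),
             bitDepth = spec@bitDepth, geometry = g)
}

#' Generate a complete phantom
#'
#' Convenience wrapper chaining \code{\link{generateTree}},
#' \code{\link{rasterizeTree}} and \code{\link{renderStack}}.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with \code{tree}, \code{mask}, \code{stack}.
#' @export
phantomNeuron <- function(spec = phantomSpec()) {
  tree <- generateTree(spec)
  mask <- rasterizeTree(tree, spec@dims, spec@geometry)
  stack <- renderStack(mask, spec)
  list(tree = tree, mask = mask, stack = stack)
}
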