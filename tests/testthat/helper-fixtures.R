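# Fixture generators shared across the suite. Everything is built in code;
# no binary fixtures on disk.

# digital ball: voxel centers within radius r of the volume center
digitalBall <- function(r, pad = 2L, center = NULL, dims = NULL) {
  if (is.null(dims)) {
    n <- 2L * r + 2L * pad + 1L
    dims <- c(n, n, n)
  }
  if (is.null(center)) center <- (dims - 1) / 2   # (y, x, z) order of dims
  out <- array(FALSE, dims)
  gx <- matrix(0:(dims[2] - 1), dims[1], dims[2], byrow = TRUE)
  gy <- matrix(0:(dims[1] - 1), dims[1], dims[2])
  for (z in seq_len(dims[3])) {
    out[, , z] <- (gx - center[2])^2 + (gy - center[1])^2 +
      ((z - 1) - center[3])^2 <= r^2
  }
  out
}

# solid tube of given radius along x
digitalTube <- function(radius = 2L, x0 = 4L, x1 = 53L, dims = c(12L, 60L, 12L),
                        yc = 6L, zc = 6L) {
  out <- array(FALSE, dims)
  for (z in seq_len(dims[3]))
    for (y in seq_len(dims[1]))
      if ((y - 1 - yc)^2 + (z - 1 - zc)^2 <= radius^2)
        out[y, (x0 + 1L):(x1 + 1L), z] <- TRUE
  out
}

# random star-shaped (hence simple) polygon inside [lo, hi]^2
starPolygon <- function(nVerts = 8L, lo = 5, hi = 58) {
  cx <- runif(1, lo + 10, hi - 10)
  cy <- runif(1, lo + 10, hi - 10)
  ang <- sort(runif(nVerts, 0, 2 * pi))
  rad <- runif(nVerts, 2, min(cx - lo, cy - lo, hi - cx, hi - cy))
  cbind(cx + rad * cos(ang), cy + rad * sin(ang))
}

zeroStack <- function(dims = c(64L, 64L, 5L), bitDepth = 8L,
                      geometry = voxelGeometry(1, 1, 1)) {
  imageStack(array(0L, dims), bitDepth = bitDepth, geometry = geometry)
}

squarePts <- function(x0, y0, x1, y1) {
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
}

# a session on an empty stack with one active object and a running timer
freshSession <- function(dims = c(64L, 64L, 5L)) {
  s <- newSession(dims = dims, geometry = voxelGeometry(1, 1, 1))
  s <- addObject(s)
  s@timerRunning <- TRUE
  s
}

# --- independent oracles -----------------------------------------------------

# brute-force polygon mask: strict interior from pracma::inpolygon plus a
# naively stepped 8-connected boundary per (auto-closed) edge
oraclePolygonMask <- function(verts, width, height) {
  vx <- c(verts[, 1], verts[1, 1])
  vy <- c(verts[, 2], verts[1, 2])
  mask <- matrix(FALSE, height, width)
  for (x in 0:(width - 1))
    for (y in 0:(height - 1)) {
      if (pracma::inpolygon(x, y, verts[, 1], verts[, 2], boundary = FALSE))
        mask[y + 1, x + 1] <- TRUE
    }
  rnd <- function(v) floor(v + 0.5)
  for (i in seq_len(length(vx) - 1)) {
    xa <- rnd(vx[i]); ya <- rnd(vy[i]); xb <- rnd(vx[i + 1]); yb <- rnd(vy[i + 1])
    n <- max(abs(xb - xa), abs(yb - ya))
    for (k in 0:max(n, 0)) {
      t <- if (n == 0) 0 else k / n
      px <- rnd(xa + t * (xb - xa)); py <- rnd(ya + t * (yb - ya))
      if (px >= 0 && px < width && py >= 0 && py < height)
        mask[py + 1, px + 1] <- TRUE
    }
  }
  mask
}

# brute-force nearest-point matching: explicit all-pairs scan
oracleMatch <- function(reference, candidates, thetaXY, thetaZ) {
  k <- nrow(reference)
  mxy <- logical(k); mz <- logical(k)
  ord <- order(candidates[, 3], candidates[, 2], candidates[, 1])
  candidates <- candidates[ord, , drop = FALSE]
  for (i in seq_len(k)) {
    best <- Inf; bj <- NA
    for (j in seq_len(nrow(candidates))) {
      d2 <- sum((candidates[j, ] - reference[i, ])^2)
      if (d2 < best) { best <- d2; bj <- j }
    }
    dxy <- sqrt(sum((candidates[bj, 1:2] - reference[i, 1:2])^2))
    dz <- abs(candidates[bj, 3] - reference[i, 3])
    mxy[i] <- dxy <= thetaXY
    mz[i] <- dz <= thetaZ
  }
  c(xy = floor(100 * sum(mxy) / k * 100 + 0.5) / 100,
    z = floor(100 * sum(mz) / k * 100 + 0.5) / 100)
}

# brute-force Sholl: walk every edge, test interval containment per radius
oracleSholl <- function(skeleton, center, radii) {
  g <- skeleton@geometry
  counts <- integer(length(radii))
  for (e in seq_len(nrow(skeleton@edges))) {
    u <- skeleton@voxels[skeleton@edges[e, 1], ]
    v <- skeleton@voxels[skeleton@edges[e, 2], ]
    du <- sqrt(sum(((u - center / c(g@dx, g@dy, g@dz)) * c(g@dx, g@dy, g@dz))^2))
    dv <- sqrt(sum(((v - center / c(g@dx, g@dy, g@dz)) * c(g@dx, g@dy, g@dz))^2))
    lo <- min(du, dv); hi <- max(du, dv)
    for (ri in seq_along(radii))
      if (lo < radii[ri] && radii[ri] <= hi) counts[ri] <- counts[ri] + 1L
  }
  counts
}

# exact permutation p of the Friedman statistic: permute values within every
# block in all k!^n ways, scoring each table with the supplied statistic
oracleFriedmanPermutationP <- function(m, statFun) {
  n <- nrow(m); k <- ncol(m)
  allPerms <- permutationsOf(k)
  obs <- statFun(m)
  idxGrid <- as.matrix(expand.grid(rep(list(seq_len(nrow(allPerms))), n)))
  count <- 0L
  for (r in seq_len(nrow(idxGrid))) {
    mm <- m
    for (b in seq_len(n)) mm[b, ] <- m[b, allPerms[idxGrid[r, b], ]]
    if (statFun(mm) >= obs - 1e-12) count <- count + 1L
  }
  count / nrow(idxGrid)
}

refFriedmanStat <- function(m) unname(stats::friedman.test(m)$statistic)
myFriedmanStat <- function(m) friedmanRankTest(m)$statistic

permutationsOf <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutationsOf(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- seq_len(k)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1L)))
  }
  unname(out)
}

# isolated 3D points: grid with jitter, pairwise distances far above the
# matching thresholds
isolatedPoints <- function(n = 20L, spacing = 60) {
  g <- expand.grid(x = seq(0, by = spacing, length.out = 5),
                   y = seq(0, by = spacing, length.out = 4),
                   z = seq(0, by = spacing, length.out = 2))
  g <- as.matrix(g)[seq_len(n), ]
  g + matrix(runif(3 * n, -2, 2), n, 3)
}
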