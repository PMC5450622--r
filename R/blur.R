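# Separable 3D Gaussian convolution by per-axis banded matrices. Kernels are
# truncated at 3 sigma and edge rows are renormalized (equivalent to
# redistributing truncated mass to the in-range samples), so a constant
# volume stays constant. sigma is in voxels, per axis (y, x, z order follows
# the array layout: sigma[1] along rows, sigma[2] along columns, sigma[3]
# along slices when called with (sy, sx, sz); callers pass physical sigmas
# divided by the voxel pitch).

gaussBlur3d <- function(vol, sigma) {
  stopifnot(length(dim(vol)) == 3L, length(sigma) == 3L, all(sigma >= 0))
  d <- dim(vol)
  convMat <- function(n, s) {
    if (s == 0) return(NULL)
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    C <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      C[i, j[ok]] <- k[ok]
      C[i, ] <- C[i, ] / sum(C[i, ])
    }
    C
  }
  Cy <- convMat(d[1], sigma[1])
  Cx <- convMat(d[2], sigma[2])
  Cz <- convMat(d[3], sigma[3])
  out <- vol
  if (!is.null(Cy) || !is.null(Cx)) {
    for (z in seq_len(d[3])) {
      s <- out[, , z]
      if (!is.null(Cy)) s <- Cy %*% s
      if (!is.null(Cx)) s <- s %*% t(Cx)
      out[, , z] <- s
    }
  }
  if (!is.null(Cz)) {
    m <- matrix(out, nrow = d[1] * d[2], ncol = d[3])
    m <- m %*% t(Cz)
    out <- array(m, dim = d)
  }
  out
}
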