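# Sholl analysis on the skeleton graph. An intersection with the sphere of
# radius r is an edge (u, v) of the 26-adjacency skeleton graph whose
# endpoint distances from the center straddle r: d(u) < r <= d(v) with
# d(u) <= d(v). The rule is parameter-free, counts each crossing once, and
# assigns the boundary tie d = r to the outer side. Distances are physical
# (voxel addresses scaled by the geometry), never raw indices.

#' Sholl intersection profile of a skeleton
#'
#' @param skeleton a \linkS4class{Skeleton3D}.
#' @param center numeric (x, y, z) in micrometers (e.g.
#'   \code{\link{somaCenter}}).
#' @param radii strictly increasing positive radii in micrometers; the
#'   default steps by twice the in-plane pitch from the pitch to the
#'   skeleton's maximal distance from the center.
#' @return a \linkS4class{ShollProfile} (unfitted; see \code{\link{shollFit}}).
#' @export
shollProfile <- function(skeleton, center, radii = NULL) {
  stopifnot(is(skeleton, "Skeleton3D"), length(center) == 3L)
  if (nrow(skeleton@voxels) == 0L)
    stop("empty skeleton", call. = FALSE)
  g <- skeleton@geometry
  px <- skeleton@voxels[, 1] * g@dx
  py <- skeleton@voxels[, 2] * g@dy
  pz <- skeleton@voxels[, 3] * g@dz
  d <- sqrt((px - center[1])^2 + (py - center[2])^2 + (pz - center[3])^2)
  if (is.null(radii)) {
    step <- 2 * max(g@dx, g@dy)
    start <- max(g@dx, g@dy)
    dmax <- max(d)
    radii <- seq(start, max(start, dmax), by = step)
  }
  if (any(radii <= 0) || any(diff(radii) <= 0))
    stop("radii must be positive and strictly increasing", call. = FALSE)
  e <- skeleton@edges
  if (nrow(e) > 0) {
    du <- pmin(d[e[, 1]], d[e[, 2]])
    dv <- pmax(d[e[, 1]], d[e[, 2]])
    counts <- vapply(radii, function(r) sum(du < r & r <= dv), 0L)
  } else {
    counts <- integer(length(radii))
  }
  new("ShollProfile", center = as.numeric(center), radii = as.numeric(radii),
      counts = as.integer(counts))
}

#' Log-log linear fit of a Sholl profile
#'
#' Ordinary least squares of
#' \code{log10(count / ((4/3) pi r^3))} on \code{log10(r)}, i.e. crossing
#' density per sphere volume against radius. Radii with zero counts are
#' excluded (log undefined); at least two usable radii are required. For a
#' profile with constant counts the slope is exactly -3.
#'
#' @param profile a \linkS4class{ShollProfile}.
#' @return the profile with \code{fit = c(slope, intercept, r.squared)}
#'   filled in.
#' @export
shollFit <- function(profile) {
  stopifnot(is(profile, "ShollProfile"))
  use <- profile@counts > 0L
  if (sum(use) < 2L)
    stop("need at least 2 radii with non-zero counts to fit", call. = FALSE)
  r <- profile@radii[use]
  x <- log10(r)
  y <- log10(profile@counts[use] / ((4 / 3) * pi * r^3))
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  profile@fit <- c(slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   r.squared = r2)
  profile
}

#' Export a Sholl profile as a data.frame
#'
#' @param profile a \linkS4class{ShollProfile}.
#' @return data.frame with radius_um, count, log10_r,
#'   log10_count_per_volume (NA where count is 0).
#' @export
shollTable <- function(profile) {
  r <- profile@radii
  cnt <- profile@counts
  dens <- ifelse(cnt > 0, log10(cnt / ((4 / 3) * pi * r^3)), NA_real_)
  data.frame(radius_um = r, count = cnt, log10_r = log10(r),
             log10_count_per_volume = dens)
}
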