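# SWC parsing and the nearest-point segmentation score. SWC is the standard
# 7-column text format for neuron tracings: id, type, x, y, z, radius,
# parent (-1 for a root). Coordinates are taken to be in pixel/slice units
# of the stack the tracing refers to.

#' Read an SWC reconstruction
#'
#' Parses whitespace-separated 7-column records, skipping '#' comments, and
#' validates the forest: unique ids, parents that exist, no cycles.
#'
#' @param path SWC file path.
#' @return an \linkS4class{SwcTree}.
#' @export
readSwc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop("SWC file contains no nodes", call. = FALSE)
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(parts) != 7L)
  if (length(bad))
    stop("malformed SWC line ", bad[1], ": expected 7 fields", call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 7, byrow = TRUE)
  if (anyNA(m))
    stop("malformed SWC line: non-numeric field", call. = FALSE)
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]))
  if (anyDuplicated(nodes$id))
    stop("duplicate SWC node id", call. = FALSE)
  nonroot <- nodes$parent != -1L
  if (any(nonroot & !(nodes$parent %in% nodes$id)))
    stop("SWC parent reference to missing id", call. = FALSE)
  # cycle check: follow parents; a forest terminates at -1 within n steps
  idpos <- match(nodes$parent, nodes$id)
  for (i in seq_len(nrow(nodes))) {
    seen <- 0L; j <- i
    while (nodes$parent[j] != -1L) {
      j <- idpos[j]
      seen <- seen + 1L
      if (seen > nrow(nodes))
        stop("cycle in SWC parent links", call. = FALSE)
    }
  }
  new("SwcTree", nodes = nodes)
}

#' Write an SwcTree to a file
#'
#' Deterministic fixed-format output (identical trees give byte-identical
#' files).
#'
#' @param tree an \linkS4class{SwcTree}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSwc <- function(tree, path) {
  stopifnot(is(tree, "SwcTree"))
  nd <- tree@nodes
  writeLines(sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                     nd$id, nd$type, nd$x, nd$y, nd$z, nd$radius, nd$parent),
             path)
  invisible(path)
}

#' Points of interest of a reconstruction
#'
#' In mode \code{"poi"}: the coordinates of roots, bifurcations (>= 2
#' children) and end-points (0 children), deduplicated by node id; in mode
#' \code{"all"}: every node.
#'
#' @param tree an \linkS4class{SwcTree}.
#' @param mode "poi" (default) or "all".
#' @return numeric matrix k x 3 of (x, y, z).
#' @export
pointsOfInterest <- function(tree, mode = c("poi", "all")) {
  mode <- match.arg(mode)
  nd <- tree@nodes
  if (mode == "all")
    return(as.matrix(nd[, c("x", "y", "z")]))
  nchild <- table(factor(nd$parent[nd$parent != -1L], levels = nd$id))
  nchild <- as.integer(nchild)
  keep <- nd$parent == -1L | nchild >= 2L | nchild == 0L
  as.matrix(nd[keep, c("x", "y", "z")])
}

round2 <- function(v) floor(v * 100 + 0.5) / 100   # half-up to 2 decimals

#' Match reference points against a candidate point cloud
#'
#' For each reference point the candidate minimizing the full 3D Euclidean
#' distance is selected (ties to the smallest (z, y, x)); the in-plane
#' distance \code{d_xy} and axial distance \code{d_z} of that pair are then
#' checked against separate thresholds, reflecting the different in-plane
#' and axial resolutions. A reference point within both thresholds of its
#' nearest candidate is "matched"; beyond a threshold it is "missing" on
#' that axis. Distances are in raw pixel/slice units, matching thresholds
#' stated in pixels; pre-scale the coordinates for physical-unit matching.
#'
#' @param reference k x 3 matrix of (x, y, z) reference points.
#' @param candidates n x 3 matrix of candidate points (e.g. foreground voxel
#'   or skeleton coordinates of a segmented object).
#' @param thetaXY in-plane distance threshold, pixels (default 4.76).
#' @param thetaZ axial distance threshold, slices (default 17).
#' @return list with \code{table} (one row per reference point: reference
#'   and matched coordinates, d_xy, d_z, matched_xy, matched_z) and
#'   \code{pct_matched_xy}, \code{pct_matched_z} (percentages, 2 decimals).
#' @export
matchPoints <- function(reference, candidates, thetaXY = 4.76, thetaZ = 17) {
  reference <- as.matrix(reference); candidates <- as.matrix(candidates)
  if (nrow(reference) == 0L || nrow(candidates) == 0L)
    stop("reference and candidate sets must be non-empty", call. = FALSE)
  if (thetaXY <= 0 || thetaZ <= 0)
    stop("thresholds must be positive", call. = FALSE)
  # candidates pre-sorted by (z, y, x): the first argmin realizes the tie rule
  ord <- order(candidates[, 3], candidates[, 2], candidates[, 1])
  cand <- candidates[ord, , drop = FALSE]
  k <- nrow(reference)
  nearest <- matrix(0, k, 3)
  dxy <- numeric(k); dz <- numeric(k)
  for (i in seq_len(k)) {
    dx <- cand[, 1] - reference[i, 1]
    dy <- cand[, 2] - reference[i, 2]
    dzv <- cand[, 3] - reference[i, 3]
    d2 <- dx * dx + dy * dy + dzv * dzv
    j <- which.min(d2)
    nearest[i, ] <- cand[j, ]
    dxy[i] <- sqrt(dx[j]^2 + dy[j]^2)
    dz[i] <- abs(dzv[j])
  }
  mxy <- dxy <= thetaXY
  mz <- dz <= thetaZ
  tab <- data.frame(ref_x = reference[, 1], ref_y = reference[, 2],
                    ref_z = reference[, 3],
                    cand_x = nearest[, 1], cand_y = nearest[, 2],
                    cand_z = nearest[, 3],
                    d_xy = dxy, d_z = dz,
                    matched_xy = mxy, matched_z = mz)
  list(table = tab,
       pct_matched_xy = round2(100 * sum(mxy) / k),
       pct_matched_z = round2(100 * sum(mz) / k))
}

#' Candidate point cloud of a segmented object
#'
#' @param mask logical 3D array.
#' @param source "voxels" (all foreground voxel addresses, default) or
#'   "skeleton" (skeleton voxels, faster matching for large objects).
#' @return n x 3 matrix of 0-based (x, y, z) addresses.
#' @export
maskPoints <- function(mask, source = c("voxels", "skeleton")) {
  source <- match.arg(source)
  if (source == "skeleton") {
    sk <- skeletonize3d(mask)
    return(sk@voxels)
  }
  idx <- which(mask)
  d <- dim(mask)
  cbind(x = ((idx - 1L) %/% d[1]) %% d[2],
        y = (idx - 1L) %% d[1],
        z = (idx - 1L) %/% (d[1] * d[2]))
}
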