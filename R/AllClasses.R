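#' @useDynLib mansegkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

setClassUnion("TriangleMeshOrNULL", "NULL")

#' Voxel geometry of an image stack
#'
#' Physical size of a voxel in micrometers along each axis. Confocal stacks
#' in this workflow are typically anisotropic: equal in-plane sampling
#' (\code{dx == dy}, e.g. 0.62 um/pixel at 40x) and a z-step twice the
#' in-plane resolution.
#'
#' @slot dx,dy,dz positive numerics, micrometers per voxel along x (columns),
#'   y (rows) and z (slices).
#' @export
setClass("VoxelGeometry",
  representation(dx = "numeric", dy = "numeric", dz = "numeric"),
  prototype(dx = 1, dy = 1, dz = 2),
  validity = function(object) {
    v <- c(object@dx, object@dy, object@dz)
    if (length(v) != 3L || any(!is.finite(v)) || any(v <= 0))
      return("dx, dy, dz must be single positive finite numbers")
    TRUE
  })

#' Construct a VoxelGeometry
#'
#' @param dx,dy,dz micrometers per voxel along x, y and z. The default
#'   \code{(1, 1, 2)} encodes relative units with the usual
#'   z-step = 2 x in-plane convention.
#' @return a \linkS4class{VoxelGeometry}
#' @examples
#' voxelGeometry(0.62, 0.62, 1.24)
#' @export
voxelGeometry <- function(dx = 1, dy = 1, dz = 2 * dx) {
  new("VoxelGeometry", dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz))
}

#' Grayscale image stack
#'
#' An M x N x Z array of non-negative integer intensities with a declared bit
#' depth (8, 12 or 16; 12-bit data live in 16-bit containers on disk) and a
#' voxel geometry. Slice \code{z} of the volume is page \code{z} of the
#' corresponding multi-page TIFF.
#'
#' @slot data integer array, dim (M, N, Z); \code{data[y + 1, x + 1, z + 1]}
#'   is the voxel at 0-based address (x, y, z).
#' @slot bitDepth integer, one of 8, 12, 16.
#' @slot geometry a \linkS4class{VoxelGeometry}.
#' @export
setClass("ImageStack",
  representation(data = "array", bitDepth = "integer", geometry = "VoxelGeometry"),
  validity = function(object) {
    d <- object@data
    if (length(dim(d)) != 3L) return("data must be a 3D array")
    if (any(dim(d) < 1L)) return("all dimensions must be >= 1")
    if (!object@bitDepth %in% c(8L, 12L, 16L))
      return("bitDepth must be 8, 12 or 16")
    if (anyNA(d)) return("data must not contain NA")
    rng <- range(d)
    if (rng[1] < 0) return("intensities must be non-negative")
    if (rng[2] > 2^object@bitDepth - 1)
      return(sprintf("intensity %d exceeds bit depth %d", rng[2], object@bitDepth))
    TRUE
  })

#' Construct an ImageStack
#'
#' @param data numeric or integer 3D array (M, N, Z) of intensities.
#' @param bitDepth 8, 12 or 16.
#' @param geometry a \linkS4class{VoxelGeometry}.
#' @return an \linkS4class{ImageStack}
#' @export
imageStack <- function(data, bitDepth = 8L, geometry = voxelGeometry()) {
  storage.mode(data) <- "integer"
  new("ImageStack", data = data, bitDepth = as.integer(bitDepth), geometry = geometry)
}

#' Triangle surface mesh
#'
#' Vertices are in physical units (micrometers); faces index vertices
#' (1-based). Meshes produced by \code{\link{extractMesh}} are closed and
#' consistently oriented with outward normals.
#'
#' @slot vertices numeric matrix n x 3, columns (x, y, z) in um.
#' @slot faces integer matrix m x 3 of vertex indices.
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix"),
  validity = function(object) {
    if (ncol(object@vertices) != 3L) return("vertices must have 3 columns")
    if (ncol(object@faces) != 3L) return("faces must have 3 columns")
    if (nrow(object@faces) > 0 &&
        (min(object@faces) < 1 || max(object@faces) > nrow(object@vertices)))
      return("face indices out of range")
    TRUE
  })

setIs("TriangleMesh", "TriangleMeshOrNULL")

#' A single segmented object
#'
#' One object of a segmentation session: a boolean volume matching the parent
#' stack's dimensions, the accumulated active editing time, a label, and an
#' optional cached surface mesh.
#'
#' @slot mask logical array (M, N, Z); TRUE = foreground.
#' @slot elapsedSeconds non-negative numeric, active editing time.
#' @slot name character label.
#' @slot mesh a \linkS4class{TriangleMesh} or NULL.
#' @export
setClass("SegmentedObject",
  representation(mask = "array", elapsedSeconds = "numeric", name = "character",
                 mesh = "TriangleMeshOrNULL"),
  prototype(elapsedSeconds = 0, name = "object", mesh = NULL),
  validity = function(object) {
    if (length(dim(object@mask)) != 3L) return("mask must be a 3D array")
    if (!is.logical(object@mask)) return("mask must be logical")
    if (object@elapsedSeconds < 0) return("elapsedSeconds must be >= 0")
    TRUE
  })

#' Segmentation session (the "datamatrix")
#'
#' The per-session store of segmented objects. Each object carries its binary
#' volume, cached mesh and active editing time. Edits apply to the active
#' object and only while the timer runs, mirroring the original tool's
#' green-LED rule.
#'
#' @slot dims integer length-3, (M, N, Z) of the parent stack.
#' @slot geometry a \linkS4class{VoxelGeometry}.
#' @slot objects list of \linkS4class{SegmentedObject}.
#' @slot activeObject integer index into \code{objects} (0 = none).
#' @slot timerRunning logical.
#' @export
setClass("SegSession",
  representation(dims = "integer", geometry = "VoxelGeometry", objects = "list",
                 activeObject = "integer", timerRunning = "logical"),
  prototype(activeObject = 0L, timerRunning = FALSE),
  validity = function(object) {
    if (length(object@dims) != 3L || any(object@dims < 1L))
      return("dims must be three positive integers")
    for (ob in object@objects) {
      if (!is(ob, "SegmentedObject")) return("objects must be SegmentedObject")
      if (!identical(dim(ob@mask), as.integer(object@dims)))
        return("object mask dimensions must equal session dims")
    }
    if (object@activeObject < 0L || object@activeObject > length(object@objects))
      return("activeObject out of range")
    TRUE
  })

#' Voxel skeleton of a segmented object
#'
#' A 1-voxel-thin, topology-preserving medial representation. Voxels are
#' 0-based integer addresses (x, y, z); edges connect 26-adjacent skeleton
#' voxels.
#'
#' @slot voxels integer matrix k x 3, 0-based (x, y, z) addresses.
#' @slot edges integer matrix e x 2 of row indices into \code{voxels}.
#' @slot geometry a \linkS4class{VoxelGeometry}.
#' @export
setClass("Skeleton3D",
  representation(voxels = "matrix", edges = "matrix", geometry = "VoxelGeometry"),
  validity = function(object) {
    if (ncol(object@voxels) != 3L) return("voxels must have 3 columns")
    if (ncol(object@edges) != 2L) return("edges must have 2 columns")
    if (nrow(object@edges) > 0 &&
        (min(object@edges) < 1 || max(object@edges) > nrow(object@voxels)))
      return("edge indices out of range")
    TRUE
  })

#' Sholl intersection profile
#'
#' Counts of skeleton-sphere crossings at increasing radii around a center,
#' with the log-log fit of crossing density (count per sphere volume) against
#' radius.
#'
#' @slot center numeric length-3, (x, y, z) in um.
#' @slot radii strictly increasing positive numerics, um.
#' @slot counts non-negative integers, one per radius.
#' @slot fit numeric length-3 (slope, intercept, r.squared) or NAs before
#'   fitting.
#' @export
setClass("ShollProfile",
  representation(center = "numeric", radii = "numeric", counts = "integer",
                 fit = "numeric"),
  prototype(fit = c(slope = NA_real_, intercept = NA_real_, r.squared = NA_real_)),
  validity = function(object) {
    if (length(object@center) != 3L) return("center must be length 3")
    if (any(object@radii <= 0) || any(diff(object@radii) <= 0))
      return("radii must be strictly increasing and positive")
    if (length(object@counts) != length(object@radii))
      return("counts and radii lengths differ")
    if (any(object@counts < 0)) return("counts must be non-negative")
    TRUE
  })

#' SWC neuron reconstruction
#'
#' A parsed SWC forest. Coordinates are in pixel/slice units of the stack
#' the reconstruction refers to (x = column, y = row, z = slice, 0-based).
#'
#' @slot nodes data.frame with columns id, type, x, y, z, radius, parent.
#' @export
setClass("SwcTree",
  representation(nodes = "data.frame"),
  validity = function(object) {
    nd <- object@nodes
    need <- c("id", "type", "x", "y", "z", "radius", "parent")
    if (!identical(names(nd), need)) return("nodes must have SWC columns")
    if (nrow(nd) == 0L) return("tree must contain at least one node")
    if (anyDuplicated(nd$id)) return("duplicate node ids")
    TRUE
  })

#' Synthetic neuron phantom specification
#'
#' Parameters of the deterministic phantom generator: a seeded random binary
#' tree rasterized as capsules (tubes with spherical caps) plus a soma ball,
#' rendered with two intensity levels, an anisotropic Gaussian point-spread
#' blur and Gaussian noise.
#'
#' @slot seed integer RNG seed.
#' @slot dims integer (M, N, Z) voxels.
#' @slot geometry a \linkS4class{VoxelGeometry}.
#' @slot nBifurcations integer >= 0.
#' @slot segmentLengthRange,tubeRadiusRange numeric length-2 ranges, um.
#' @slot somaRadius positive numeric, um.
#' @slot psfSigma numeric length-3 (x, y, z) Gaussian PSF sigmas, um.
#' @slot backgroundLevel,foregroundLevel intensities within the bit depth.
#' @slot noiseSigma non-negative numeric, intensity units.
#' @slot bitDepth 8, 12 or 16.
#' @export
setClass("PhantomSpec",
  representation(seed = "integer", dims = "integer", geometry = "VoxelGeometry",
                 nBifurcations = "integer", segmentLengthRange = "numeric",
                 tubeRadiusRange = "numeric", somaRadius = "numeric",
                 psfSigma = "numeric", backgroundLevel = "numeric",
                 foregroundLevel = "numeric", noiseSigma = "numeric",
                 bitDepth = "integer"),
  validity = function(object) {
    if (length(object@dims) != 3L || any(object@dims < 8L))
      return("dims must be three integers >= 8")
    if (object@nBifurcations < 0L) return("nBifurcations must be >= 0")
    if (any(object@segmentLengthRange <= 0) || any(object@tubeRadiusRange <= 0))
      return("lengths and radii must be positive")
    if (object@somaRadius <= 0) return("somaRadius must be positive")
    if (length(object@psfSigma) != 3L || any(object@psfSigma < 0))
      return("psfSigma must be three non-negative numbers")
    mx <- 2^object@bitDepth - 1
    lv <- c(object@backgroundLevel, object@foregroundLevel)
    if (any(lv < 0) || any(lv > mx)) return("levels outside bit depth")
    if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
    TRUE
  })
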