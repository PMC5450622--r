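#' @rdname voxelGeometry
#' @param x an object carrying a voxel geometry.
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname imageStack
#' @param x an ImageStack.
#' @export
setGeneric("stackData", function(x) standardGeneric("stackData"))

#' @rdname imageStack
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' Accessors for meshes
#' @param x a TriangleMesh.
#' @return \code{vertices}: n x 3 numeric matrix; \code{faces}: m x 3 integer
#'   matrix.
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname vertices
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))

#' Accessors for sessions and their objects
#'
#' @param x a SegSession or SegmentedObject.
#' @param i object index (1-based).
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' @rdname nObjects
#' @export
setGeneric("objectMask", function(x, i) standardGeneric("objectMask"))

#' @rdname nObjects
#' @export
setGeneric("elapsedSeconds", function(x, i) standardGeneric("elapsedSeconds"))

#' @rdname nObjects
#' @export
setGeneric("objectNames", function(x) standardGeneric("objectNames"))

setMethod("geometry", "ImageStack", function(x) x@geometry)
setMethod("geometry", "SegSession", function(x) x@geometry)
setMethod("geometry", "Skeleton3D", function(x) x@geometry)
setMethod("stackData", "ImageStack", function(x) x@data)
setMethod("bitDepth", "ImageStack", function(x) x@bitDepth)
setMethod("vertices", "TriangleMesh", function(x) x@vertices)
setMethod("faces", "TriangleMesh", function(x) x@faces)
setMethod("nObjects", "SegSession", function(x) length(x@objects))
setMethod("objectMask", "SegSession", function(x, i) {
  stopifnot(i >= 1L, i <= length(x@objects))
  x@objects[[i]]@mask
})
setMethod("elapsedSeconds", "SegSession", function(x, i) {
  if (missing(i)) return(vapply(x@objects, function(o) o@elapsedSeconds, 0))
  x@objects[[i]]@elapsedSeconds
})
setMethod("objectNames", "SegSession", function(x)
  vapply(x@objects, function(o) o@name, ""))

setMethod("show", "VoxelGeometry", function(object) {
  cat(sprintf("VoxelGeometry: dx=%g dy=%g dz=%g um\n",
              object@dx, object@dy, object@dz))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack: %d x %d x %d, %d-bit, voxel %g x %g x %g um\n",
              d[1], d[2], d[3], object@bitDepth,
              object@geometry@dx, object@geometry@dy, object@geometry@dz))
})

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "SegSession", function(object) {
  cat(sprintf("SegSession: %d x %d x %d, %d object(s), timer %s\n",
              object@dims[1], object@dims[2], object@dims[3],
              length(object@objects),
              if (object@timerRunning) "running" else "paused"))
  for (i in seq_along(object@objects)) {
    o <- object@objects[[i]]
    cat(sprintf("  [%d]%s '%s': %d voxels, %.3f s\n", i,
                if (i == object@activeObject) "*" else " ",
                o@name, sum(o@mask), o@elapsedSeconds))
  }
})

setMethod("show", "Skeleton3D", function(object) {
  cat(sprintf("Skeleton3D: %d voxels, %d edges\n",
              nrow(object@voxels), nrow(object@edges)))
})

setMethod("show", "ShollProfile", function(object) {
  cat(sprintf("ShollProfile: %d radii [%g, %g] um, center (%g, %g, %g)\n",
              length(object@radii), min(object@radii), max(object@radii),
              object@center[1], object@center[2], object@center[3]))
  if (!is.na(object@fit[1]))
    cat(sprintf("  log-log fit: slope %.4f, intercept %.4f, r^2 %.4f\n",
                object@fit[1], object@fit[2], object@fit[3]))
})

setMethod("show", "SwcTree", function(object) {
  nd <- object@nodes
  cat(sprintf("SwcTree: %d nodes, %d root(s)\n", nrow(nd), sum(nd$parent == -1)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: seed %d, %d x %d x %d, %d bifurcation(s)\n",
              object@seed, object@dims[1], object@dims[2], object@dims[3],
              object@nBifurcations))
})
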