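# Session container: an uncompressed POSIX tar archive holding manifest.json
# (dims, geometry, object table with elapsed milliseconds, format version),
# one multi-page 8-bit 0/255 TIFF per object mask, and one ASCII PLY per
# cached mesh. Written and read with R's internal tar, so no external
# archiver is needed.

CONTAINER_VERSION <- 1L

#' Save a segmentation session
#'
#' Stores, per object, the boolean volume, the elapsed active time
#' (millisecond resolution) and, when cached, the surface mesh.
#'
#' @param session a \linkS4class{SegSession}.
#' @param path output file path (conventionally \code{.tar}).
#' @return \code{path}, invisibly.
#' @seealso \code{\link{loadSession}}
#' @export
saveSession <- function(session, path) {
  stopifnot(is(session, "SegSession"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  stage <- tempfile("session_stage_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  g <- session@geometry
  objTable <- lapply(seq_along(session@objects), function(i) {
    o <- session@objects[[i]]
    list(name = o@name,
         elapsed_ms = as.integer(round(o@elapsedSeconds * 1000)),
         mask_file = sprintf("mask_%d.tif", i - 1L),
         mesh_file = if (!is.null(o@mesh)) sprintf("mesh_%d.ply", i - 1L),
         voxels = sum(o@mask))
  })
  manifest <- list(format = "mansegkit-session", version = CONTAINER_VERSION,
                   dims = as.integer(session@dims),
                   geometry = list(dx = g@dx, dy = g@dy, dz = g@dz),
                   mask_dialect = "tiff-8bit-0-255",
                   active_object = session@activeObject,
                   objects = objTable)
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (i in seq_along(session@objects)) {
    o <- session@objects[[i]]
    pages <- lapply(seq_len(session@dims[3]), function(z)
      matrix(ifelse(o@mask[, , z], 1, 0),
             nrow = session@dims[1], ncol = session@dims[2]))
    tiff::writeTIFF(pages, file.path(stage, sprintf("mask_%d.tif", i - 1L)),
                    bits.per.sample = 8L, compression = "none")
    if (!is.null(o@mesh))
      writePLY(o@mesh, file.path(stage, sprintf("mesh_%d.ply", i - 1L)))
  }
  target <- file.path(normalizePath(dirname(path)), basename(path))
  owd <- setwd(stage)
  on.exit(setwd(owd), add = TRUE, after = FALSE)
  utils::tar(target, files = list.files(stage), tar = "internal")
  invisible(path)
}

#' Load a previously saved session
#'
#' Reconstructs the session from a container written by
#' \code{\link{saveSession}}; further actions can be replayed onto it.
#'
#' @param path container file path.
#' @return a \linkS4class{SegSession} (timer paused, previous active object
#'   restored).
#' @export
loadSession <- function(path) {
  if (!file.exists(path)) stop("container not found: ", path, call. = FALSE)
  stage <- tempfile("session_load_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  ok <- tryCatch({
    utils::untar(path, exdir = stage, tar = "internal")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  mf <- file.path(stage, "manifest.json")
  if (!ok || !file.exists(mf))
    stop("corrupt session container: missing or unreadable manifest", call. = FALSE)
  manifest <- tryCatch(jsonlite::read_json(mf, simplifyVector = FALSE),
                       error = function(e) NULL)
  if (is.null(manifest) || !identical(manifest$format, "mansegkit-session"))
    stop("corrupt session container: bad manifest", call. = FALSE)
  dims <- as.integer(unlist(manifest$dims))
  g <- manifest$geometry
  session <- newSession(dims = dims, geometry = voxelGeometry(g$dx, g$dy, g$dz))
  for (i in seq_along(manifest$objects)) {
    rec <- manifest$objects[[i]]
    mp <- file.path(stage, rec$mask_file)
    if (!file.exists(mp))
      stop("corrupt session container: missing ", rec$mask_file, call. = FALSE)
    pages <- tiff::readTIFF(mp, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != dims[3] || !identical(dim(pages[[1]]), dims[1:2]))
      stop("mask dimensions inconsistent with manifest", call. = FALSE)
    mask <- array(FALSE, dim = dims)
    for (z in seq_len(dims[3])) mask[, , z] <- pages[[z]] > 0
    mesh <- NULL
    if (!is.null(rec$mesh_file)) {
      mfp <- file.path(stage, rec$mesh_file)
      if (file.exists(mfp)) mesh <- readPLY(mfp)
    }
    obj <- new("SegmentedObject", mask = mask,
               elapsedSeconds = rec$elapsed_ms / 1000,
               name = rec$name, mesh = mesh)
    session@objects <- c(session@objects, obj)
  }
  session@activeObject <- as.integer(manifest$active_object)
  if (session@activeObject > length(session@objects))
    session@activeObject <- 0L
  session@timerRunning <- FALSE
  validObject(session)
  session
}
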