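#' Read a multi-page grayscale TIFF stack
#'
#' Loads an 8-, 12- or 16-bit grayscale multi-page TIFF into an
#' \linkS4class{ImageStack}. Page order defines slice order (page 1 = slice at
#' z = 0). 12-bit data stored in a 16-bit container are accepted when declared
#' via \code{bitDepth = 12}.
#'
#' Voxel geometry is taken from the \code{geometry} argument if given;
#' otherwise from a sidecar file \code{<path>.geometry.json} written by
#' \code{\link{writeStack}}; otherwise it defaults to relative units
#' \code{(1, 1, 2)} (z-step twice the in-plane sampling) with a warning.
#'
#' @param path TIFF file path.
#' @param geometry optional \linkS4class{VoxelGeometry} overriding any stored
#'   geometry.
#' @param bitDepth optional declared bit depth (use 12 for 12-bit data in
#'   16-bit containers). Inferred from the file when missing.
#' @return an \linkS4class{ImageStack}
#' @seealso \code{\link{writeStack}}
#' @export
readStack <- function(path, geometry = NULL, bitDepth = NULL) {
  if (!file.exists(path))
    stop("stack file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF contains no pages", call. = FALSE)
  for (p in pages) {
    if (length(dim(p)) != 2L)
      stop("multi-channel (RGB) TIFF pages are not supported; ",
           "a grayscale stack is required", call. = FALSE)
  }
  d1 <- dim(pages[[1]])
  for (p in pages) if (!identical(dim(p), d1))
    stop("inconsistent page sizes within the TIFF stack", call. = FALSE)
  vol <- array(0L, dim = c(d1[1], d1[2], length(pages)))
  for (z in seq_along(pages)) vol[, , z] <- as.integer(pages[[z]])
  sidecar <- paste0(path, ".geometry.json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  mx <- max(vol)
  if (is.null(bitDepth)) {
    bitDepth <- if (!is.null(meta$bit_depth)) meta$bit_depth
                else if (mx <= 255) 8L else 16L
  }
  bitDepth <- as.integer(bitDepth)
  if (!bitDepth %in% c(8L, 12L, 16L))
    stop("unsupported bit depth: ", bitDepth, call. = FALSE)
  if (mx > 2^bitDepth - 1)
    stop(sprintf("intensities exceed declared %d-bit range", bitDepth),
         call. = FALSE)
  if (is.null(geometry)) {
    if (!is.null(meta)) {
      geometry <- voxelGeometry(meta$dx, meta$dy, meta$dz)
    } else {
      warning("no voxel geometry given or stored; using relative units (1, 1, 2)")
      geometry <- voxelGeometry(1, 1, 2)
    }
  }
  imageStack(vol, bitDepth = bitDepth, geometry = geometry)
}

#' Write an ImageStack as a multi-page grayscale TIFF
#'
#' Values are stored bit-exactly (8-bit container for 8-bit data, 16-bit for
#' 12- and 16-bit). Voxel geometry and declared bit depth are recorded in a
#' sidecar \code{<path>.geometry.json} so that \code{\link{readStack}}
#' round-trips losslessly.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  bps <- if (stack@bitDepth == 8L) 8L else 16L
  denom <- 2^bps - 1
  pages <- lapply(seq_len(dim(stack@data)[3]), function(z)
    stack@data[, , z] / denom)
  tiff::writeTIFF(pages, path, bits.per.sample = bps, compression = "none")
  g <- stack@geometry
  jsonlite::write_json(
    list(dx = g@dx, dy = g@dy, dz = g@dz, bit_depth = stack@bitDepth),
    paste0(path, ".geometry.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' One-line description of a stack file
#'
#' @param path TIFF file path.
#' @return named list with dims, bitDepth and geometry (also printed).
#' @export
stackInfo <- function(path) {
  s <- suppressWarnings(readStack(path))
  d <- dim(s@data)
  cat(sprintf("%s: %d x %d x %d, %d-bit, voxel %g x %g x %g um\n",
              basename(path), d[1], d[2], d[3], s@bitDepth,
              s@geometry@dx, s@geometry@dy, s@geometry@dz))
  invisible(list(dims = d, bitDepth = s@bitDepth, geometry = s@geometry))
}
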