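#' Write a triangle mesh as ASCII PLY
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePLY <- function(mesh, path) {
  stopifnot(is(mesh, "TriangleMesh"))
  v <- mesh@vertices; f <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY triangle mesh written by \code{\link{writePLY}}
#'
#' @param path PLY file path.
#' @return a \linkS4class{TriangleMesh}.
#' @export
readPLY <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || lines[1] != "ply")
    stop("not a PLY file: ", path, call. = FALSE)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face ", lines, value = TRUE)[1]))
  hdr <- which(lines == "end_header")[1]
  vl <- lines[hdr + seq_len(nv)]
  fl <- lines[hdr + nv + seq_len(nf)]
  v <- matrix(as.numeric(unlist(strsplit(vl, " "))), ncol = 3, byrow = TRUE)
  fparts <- matrix(as.integer(unlist(strsplit(fl, " "))), ncol = 4, byrow = TRUE)
  new("TriangleMesh", vertices = v, faces = fparts[, 2:4, drop = FALSE] + 1L)
}

#' Write a triangle mesh as ASCII STL
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param path output path.
#' @param name solid name recorded in the file.
#' @return \code{path}, invisibly.
#' @export
writeSTL <- function(mesh, path, name = "mansegkit") {
  stopifnot(is(mesh, "TriangleMesh"))
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  ny <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  nz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  len <- sqrt(nx^2 + ny^2 + nz^2)
  len[len == 0] <- 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(f))) {
    writeLines(c(sprintf("facet normal %.9g %.9g %.9g",
                         nx[i] / len[i], ny[i] / len[i], nz[i] / len[i]),
                 "  outer loop",
                 sprintf("    vertex %.9g %.9g %.9g",
                         v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}
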