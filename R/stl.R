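# STL (Standard Tessellation Language) reading and writing.
#
# Binary layout: 80-byte header, uint32 little-endian facet count, then 50
# bytes per facet (12 float32: normal + 3 vertices; uint16 attribute = 0).
# STL is unitless; meshes are written in mm and the unit is recorded in the
# header comment.

float32 <- function(x) readBin(writeBin(as.numeric(x), raw(), size = 4L,
                                        endian = "little"),
                               "double", length(x), size = 4L, endian = "little")

#' Write a triangle mesh to an STL file
#'
#' @param m an `rt_mesh`.
#' @param path output file path.
#' @param mode `"binary"` (default; what printers consume) or `"ascii"`.
#' @param header comment recorded in the binary header / solid name
#'   (default records the mm unit).
#' @return invisibly, `path`.
#' @export
write_stl <- function(m, path, mode = c("binary", "ascii"),
                      header = "rtprint mesh (units: mm)") {
  stopifnot(inherits(m, "rt_mesh"))
  mode <- match.arg(mode)
  nf <- nrow(m$facets)
  n <- facet_normals(m)
  a <- m$vertices[m$facets[, 1L], , drop = FALSE]
  b <- m$vertices[m$facets[, 2L], , drop = FALSE]
  c <- m$vertices[m$facets[, 3L], , drop = FALSE]
  if (mode == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    h <- charToRaw(substr(header, 1L, 80L))
    writeBin(c(h, raw(80L - length(h))), con)
    writeBin(as.integer(nf), con, size = 4L, endian = "little")
    flo <- t(cbind(n, a, b, c))                    # 12 floats per facet, facet-major
    fraw <- writeBin(as.numeric(flo), raw(), size = 4L, endian = "little")
    block <- matrix(raw(50L * nf), nrow = 50L)
    block[1:48, ] <- matrix(fraw, nrow = 48L)      # attribute bytes stay 00 00
    writeBin(as.vector(block), con)
  } else {
    # float32-rounded %g so ascii and binary re-reads agree bit-for-bit
    fmt <- function(v) sprintf("%.9g", float32(v))
    lines <- character(7L * nf + 2L)
    lines[1L] <- paste("solid", gsub("[^ -~]", "", header))
    o <- 1L
    for (i in seq_len(nf)) {
      lines[o + 1L] <- sprintf("  facet normal %s %s %s", fmt(n[i, 1L]), fmt(n[i, 2L]), fmt(n[i, 3L]))
      lines[o + 2L] <- "    outer loop"
      lines[o + 3L] <- sprintf("      vertex %s %s %s", fmt(a[i, 1L]), fmt(a[i, 2L]), fmt(a[i, 3L]))
      lines[o + 4L] <- sprintf("      vertex %s %s %s", fmt(b[i, 1L]), fmt(b[i, 2L]), fmt(b[i, 3L]))
      lines[o + 5L] <- sprintf("      vertex %s %s %s", fmt(c[i, 1L]), fmt(c[i, 2L]), fmt(c[i, 3L]))
      lines[o + 6L] <- "    endloop"
      lines[o + 7L] <- "  endfacet"
      o <- o + 7L
    }
    lines[o + 1L] <- "endsolid"
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an STL file (binary or ASCII)
#'
#' The triangle soup is re-indexed: vertices with bit-identical coordinates
#' are merged, so a written mesh reads back with identical facet topology
#' and float32-rounded vertex coordinates.
#'
#' @param path STL file path.
#' @return an `rt_mesh`.
#' @export
read_stl <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15L) stop("not an STL file: ", path)
  con <- file(path, "rb")
  head84 <- readBin(con, "raw", min(84L, sz))
  close(con)
  is_binary <- FALSE
  if (sz >= 84L) {
    nf <- readBin(head84[81:84], "integer", 1L, size = 4L, endian = "little")
    if (sz == 84 + 50 * as.numeric(nf)) is_binary <- TRUE
  }
  if (!is_binary && grepl("^\\s*solid", rawToChar(head84[1:min(40L, sz)]))) {
    return(read_stl_ascii(path))
  }
  if (!is_binary)
    stop(sprintf("corrupt binary STL: size %d does not match 84 + 50 x facet count", sz))
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80L))
  nf <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  body <- readBin(con, "raw", 50L * nf)
  block <- matrix(body, nrow = 50L)
  flo <- readBin(as.vector(block[1:48, ]), "double", 12L * nf, size = 4L,
                 endian = "little")
  flo <- matrix(flo, nrow = 12L)                   # per facet: normal, v1, v2, v3
  soup_to_mesh(t(flo[4:12, , drop = FALSE]))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl) || length(vl) %% 3L != 0L)
    stop("corrupt ASCII STL: vertex count not a multiple of 3")
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(s) as.numeric(s[2:4]), numeric(3)))
  nums[] <- float32(nums)                          # STL carries binary32 precision
  soup_to_mesh(matrix(t(nums), ncol = 9L, byrow = TRUE))
}

# facet-wise 9-column matrix (v1 v2 v3) -> indexed mesh, merging
# bit-identical vertex positions
soup_to_mesh <- function(tri9) {
  v <- rbind(tri9[, 1:3, drop = FALSE], tri9[, 4:6, drop = FALSE],
             tri9[, 7:9, drop = FALSE])
  nf <- nrow(tri9)
  ord <- as.vector(t(matrix(seq_len(3L * nf), ncol = 3L)))  # interleave v1,v2,v3
  v <- v[ord, , drop = FALSE]
  key <- paste(sprintf("%a", v[, 1L]), sprintf("%a", v[, 2L]), sprintf("%a", v[, 3L]))
  uid <- match(key, key)
  keep <- !duplicated(uid)
  verts <- v[keep, , drop = FALSE]
  remap <- match(uid, uid[keep])
  facets <- matrix(remap, ncol = 3L, byrow = TRUE)
  triangle_mesh(verts, facets)
}
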