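# Surface reconstruction: design point clouds -> watertight triangle meshes.

#' Reconstruct a watertight surface from a contour stack
#'
#' The design-to-print conversion for an electron bolus. The stack is
#' refined in-plane (edges below `target_spacing_mm`), put into slice-to-
#' slice vertex correspondence, and interpolated between slices to the same
#' spacing. The lateral wall connects corresponding vertices of adjacent
#' slices with triangle strips; the top and bottom openings are capped with
#' a constrained Delaunay triangulation of the end contours (the
#' empty-circumcircle property holds for the caps). The result is closed,
#' consistently oriented with outward normals, and passes [validate_mesh()].
#'
#' @param s an `rt_contour_stack` with >= 2 simple contours.
#' @param target_spacing_mm in-plane and between-slice sampling target in mm
#'   (default 1, i.e. sub-millimetre edges after subdivision).
#' @return an `rt_mesh`.
#' @export
stack_to_mesh <- function(s, target_spacing_mm = 1.0) {
  stopifnot(inherits(s, "rt_contour_stack"))
  if (length(s$contours) < 2L)
    stop("surface reconstruction needs at least 2 slices")
  for (c in s$contours)
    if (!is_simple_contour(c))
      stop(sprintf("self-intersecting input contour at z = %g mm", c$z_mm))
  sc <- correspond_stack(s, max_spacing_mm = target_spacing_mm)
  z <- stack_z(sc)
  gaps <- diff(z)
  if (any(gaps > target_spacing_mm + 1e-12)) {
    sc <- interpolate_stack(sc, target_spacing_mm)
    z <- stack_z(sc)
  }
  nslice <- length(sc$contours)
  n <- nrow(sc$contours[[1L]]$points)
  verts <- do.call(rbind, lapply(sc$contours, function(c)
    cbind(c$points, c$z_mm)))
  ring <- function(k) (k - 1L) * n + seq_len(n)
  facets <- vector("list", nslice + 1L)
  for (k in seq_len(nslice - 1L)) {
    lo <- ring(k); hi <- ring(k + 1L)
    i <- seq_len(n); ip <- c(2:n, 1L)
    # outward wall strips for CCW rings, z ascending
    facets[[k]] <- rbind(cbind(lo[i], lo[ip], hi[i]),
                         cbind(lo[ip], hi[ip], hi[i]))
  }
  bottom <- triangulate_polygon(sc$contours[[1L]]$points)          # CCW
  top <- triangulate_polygon(sc$contours[[nslice]]$points)         # CCW
  facets[[nslice]] <- matrix(ring(1L)[bottom[, c(1L, 3L, 2L)]], ncol = 3L)  # normal -z
  facets[[nslice + 1L]] <- matrix(ring(nslice)[top], ncol = 3L)             # normal +z
  m <- triangle_mesh(verts, do.call(rbind, facets))
  if (signed_volume(m) < 0) m <- flip_mesh(m)
  m
}

#' Mesh a compensator thickness grid as a watertight solid
#'
#' The design-to-print conversion for a proton compensator: the thickness
#' matrix is treated as a height field on the grid nodes, extruded along -z
#' (away from the source) from a flat base at z = 0. The top (shaped)
#' surface is a triangulation of the grid points' planar positions; the four
#' corners of every rectangular cell are cocircular, so the Delaunay
#' diagonal is tie-broken deterministically (node (r, c) to (r+1, c+1)).
#' Vertical side walls close the perimeter. For this triangulation the
#' enclosed volume equals the prismatoid integral of the thickness field
#' (exact for per-triangle linear interpolation).
#'
#' @param g an `rt_compensator` grid (see [compensator_grid()]).
#' @param flip_z if `TRUE`, extrude along +z instead (tray-mount
#'   convention).
#' @return an `rt_mesh`.
#' @export
grid_to_mesh <- function(g, flip_z = FALSE) {
  stopifnot(inherits(g, "rt_compensator"))
  t <- g$thickness_mm + g$base_thickness_mm
  nr <- nrow(t); nc <- ncol(t)
  if (nr < 2L || nc < 2L)
    stop("compensator grid footprint has zero area (need >= 2 rows and columns)")
  x <- g$origin_mm[1L] + (seq_len(nc) - 1L) * g$pixel_spacing_mm[2L]
  y <- g$origin_mm[2L] + (seq_len(nr) - 1L) * g$pixel_spacing_mm[1L]
  X <- matrix(x, nr, nc, byrow = TRUE)
  Y <- matrix(y, nr, nc)
  sgn <- if (flip_z) 1 else -1
  idx <- function(r, c) (c - 1L) * nr + r           # column-major node index
  nv <- nr * nc
  top_v <- cbind(as.vector(X), as.vector(Y), sgn * as.vector(t))
  base_v <- cbind(as.vector(X), as.vector(Y), 0)
  verts <- rbind(top_v, base_v)
  r <- rep(seq_len(nr - 1L), nc - 1L)
  c_ <- rep(seq_len(nc - 1L), each = nr - 1L)
  a <- idx(r, c_); b <- idx(r + 1L, c_); cc <- idx(r, c_ + 1L); d <- idx(r + 1L, c_ + 1L)
  # diagonal a-d (tie-broken Delaunay for cocircular rectangle corners)
  surf <- rbind(cbind(a, b, d), cbind(a, d, cc))    # CCW in (x, y) plane?
  # orientation fixed globally below via base/surf pairing
  base <- surf + nv
  # base normal must point +z (outward): CCW seen from +z
  # surface normal points -z for sgn = -1: reverse winding of surf
  perim <- c(idx(seq_len(nr - 1L), 1L),                       # left col, down rows
             idx(nr, seq_len(nc - 1L)),                       # bottom row
             idx(seq(nr, 2L), nc),                            # right col up
             idx(1L, seq(nc, 2L)))                            # top row back
  perim_next <- c(perim[-1L], perim[1L])
  walls <- rbind(cbind(perim, perim_next, perim_next + nv),
                 cbind(perim, perim_next + nv, perim + nv))
  m <- triangle_mesh(verts, rbind(surf[, c(1L, 3L, 2L)], base, walls))
  if (signed_volume(m) < 0) m <- flip_mesh(m)
  v <- validate_mesh(m)
  if (!v$watertight)
    stop("internal error: compensator mesh is not watertight")
  m
}

#' Scale, validate and export a mesh as an STL file
#'
#' Final printable export: applies optional anisotropic scaling (the
#' compensator in the study workflow was printed at 0.5 scale per
#' direction), re-validates, and writes an STL file. Non-watertight meshes
#' are refused, with the open edges reported, unless `force = TRUE`.
#'
#' @param m an `rt_mesh`.
#' @param output_path STL file path.
#' @param scale_factors optional (fx, fy, fz), all > 0.
#' @param mode `"binary"` (printer default) or `"ascii"`.
#' @param force write even if validation fails.
#' @return invisibly, the validation report of the written mesh.
#' @export
mesh_to_printable <- function(m, output_path, scale_factors = NULL,
                              mode = c("binary", "ascii"), force = FALSE) {
  mode <- match.arg(mode)
  if (!is.null(scale_factors)) m <- scale_mesh(m, scale_factors)
  v <- validate_mesh(m)
  if (!v$ok && !force) {
    be <- v$boundary_edges
    msg <- if (nrow(be)) sprintf("%d open edge(s): %s", nrow(be),
                                 paste(utils::head(apply(be, 1L, paste, collapse = "-"), 10L),
                                       collapse = ", "))
           else "orientation or degeneracy fault"
    stop(sprintf("refusing to write non-printable mesh (%s); use force = TRUE to override", msg))
  }
  write_stl(m, output_path, mode = mode)
  invisible(v)
}
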