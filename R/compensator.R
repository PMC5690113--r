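# Proton compensator thickness grids.

#' Construct a compensator thickness grid
#'
#' The design representation of a proton range compensator as exported from
#' a treatment planning system: a row x column matrix of material thickness
#' along the beam axis, on a regular planar grid (1 mm resolution in the
#' study workflow).
#'
#' @param thickness_mm numeric n_rows x n_cols matrix, thickness in mm,
#'   all >= 0. Rows advance along +y, columns along +x.
#' @param pixel_spacing_mm length-2 (row, col) grid spacing in mm, > 0.
#' @param origin_mm length-2 (x, y) position of node (1, 1) in mm.
#' @param base_thickness_mm optional uniform base added to every node.
#' @return an object of class `rt_compensator`.
#' @export
compensator_grid <- function(thickness_mm, pixel_spacing_mm = c(1, 1),
                             origin_mm = c(0, 0), base_thickness_mm = 0) {
  thickness_mm <- as.matrix(thickness_mm)
  storage.mode(thickness_mm) <- "double"
  pixel_spacing_mm <- rep_len(as.numeric(pixel_spacing_mm), 2L)
  if (any(pixel_spacing_mm <= 0)) stop("pixel spacing must be > 0")
  if (any(thickness_mm < 0) || base_thickness_mm < 0)
    stop("compensator thickness must be >= 0 everywhere")
  if (all(thickness_mm == 0))
    warning("empty compensator: all-zero thickness matrix")
  structure(list(thickness_mm = thickness_mm,
                 n_rows = nrow(thickness_mm), n_cols = ncol(thickness_mm),
                 pixel_spacing_mm = pixel_spacing_mm,
                 origin_mm = as.numeric(origin_mm)[1:2],
                 base_thickness_mm = as.numeric(base_thickness_mm)),
            class = "rt_compensator")
}

#' @export
print.rt_compensator <- function(x, ...) {
  cat(sprintf("<rt_compensator> %d x %d at (%g, %g) mm spacing, thickness %.2f-%.2f mm (+%.1f base)\n",
              x$n_rows, x$n_cols, x$pixel_spacing_mm[1L], x$pixel_spacing_mm[2L],
              min(x$thickness_mm), max(x$thickness_mm), x$base_thickness_mm))
  invisible(x)
}

#' Bilinear thickness interpolation on a compensator grid
#'
#' @param g an `rt_compensator`.
#' @param xy k x 2 matrix of planar probe positions in mm; must lie inside
#'   the grid footprint.
#' @param include_base add the uniform base thickness (default `TRUE`).
#' @return numeric vector of interpolated design heights in mm.
#' @export
grid_height_at <- function(g, xy, include_base = TRUE) {
  xy <- matrix(as.numeric(xy), ncol = 2L)
  sx <- g$pixel_spacing_mm[2L]; sy <- g$pixel_spacing_mm[1L]
  u <- (xy[, 1L] - g$origin_mm[1L]) / sx   # column coordinate, 0-based
  v <- (xy[, 2L] - g$origin_mm[2L]) / sy   # row coordinate, 0-based
  if (any(u < -1e-9 | u > g$n_cols - 1 + 1e-9 |
          v < -1e-9 | v > g$n_rows - 1 + 1e-9))
    stop("probe point outside compensator footprint")
  u <- pmin(pmax(u, 0), g$n_cols - 1)
  v <- pmin(pmax(v, 0), g$n_rows - 1)
  c0 <- pmin(floor(u), g$n_cols - 2); r0 <- pmin(floor(v), g$n_rows - 2)
  fu <- u - c0; fv <- v - r0
  t <- g$thickness_mm
  h <- t[cbind(r0 + 1, c0 + 1)] * (1 - fu) * (1 - fv) +
       t[cbind(r0 + 2, c0 + 1)] * (1 - fu) * fv +
       t[cbind(r0 + 1, c0 + 2)] * fu * (1 - fv) +
       t[cbind(r0 + 2, c0 + 2)] * fu * fv
  if (include_base) h + g$base_thickness_mm else h
}
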