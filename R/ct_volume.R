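# CT volumes: 3-D Hounsfield-unit arrays with geometry.

#' Construct a CT volume
#'
#' @param hu 3-D numeric array of Hounsfield units indexed `[x, y, z]`
#'   (rescale slope/intercept already applied).
#' @param spacing_mm length-3 voxel spacing (x, y, z) in mm, > 0.
#' @param origin_mm length-3 position of the centre of voxel (1, 1, 1) in
#'   mm (LPS patient frame).
#' @param frame coordinate-frame label (default `"LPS"`).
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(hu, spacing_mm, origin_mm = c(0, 0, 0), frame = "LPS") {
  if (length(dim(hu)) != 3L) stop("hu must be a 3-D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive values")
  structure(list(hu = hu, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm)[1:3], frame = frame),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf("<ct_volume> %d x %d x %d voxels at (%g, %g, %g) mm, HU range [%.0f, %.0f]\n",
              d[1L], d[2L], d[3L], x$spacing_mm[1L], x$spacing_mm[2L], x$spacing_mm[3L],
              min(x$hu), max(x$hu)))
  invisible(x)
}

#' Voxel-centre coordinates along one axis of a CT volume
#' @param v a `ct_volume`.
#' @param ax axis index: 1 = x, 2 = y, 3 = z.
#' @return numeric vector of voxel-centre positions in mm.
#' @export
ct_axis <- function(v, ax) v$origin_mm[ax] + (seq_len(dim(v$hu)[ax]) - 1L) * v$spacing_mm[ax]

# slice index nearest to z_mm; errors if outside the volume by > half a slice
ct_slice_index <- function(v, z_mm) {
  z <- ct_axis(v, 3L)
  k <- which.min(abs(z - z_mm))
  if (abs(z[k] - z_mm) > v$spacing_mm[3L] / 2 + 1e-9)
    stop(sprintf("z = %g mm is outside the CT volume [%g, %g]", z_mm, min(z), max(z)))
  k
}
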