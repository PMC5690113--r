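# Planar contours and axial contour stacks.
#
# All coordinates are millimetres in the DICOM LPS patient frame
# (x: right->left, y: anterior->posterior, z: inferior->superior).
# Contours are closed polygons stored WITHOUT a duplicated closing vertex.

#' Construct a planar closed contour
#'
#' A contour is an ordered closed polygon on an axial plane, the in-memory
#' form of one slice of a bolus design or of a CT-extracted surface profile.
#' The closing point is not duplicated: the edge from the last point back to
#' the first is implicit.
#'
#' @param points numeric n x 2 matrix of (x, y) vertex coordinates in mm,
#'   ordered along the polygon; the closing vertex must not be repeated.
#' @param z_mm axial position of the plane in mm.
#' @param validate if `TRUE` (default), check the polygon invariants
#'   (>= 3 points, finite, no repeated consecutive points).
#' @return an object of class `rt_contour` with fields `points`, `z_mm`.
#' @export
contour <- function(points, z_mm, validate = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("contour points must be an n x 2 matrix of (x, y) in mm")
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  z_mm <- as.numeric(z_mm)
  if (validate) {
    if (nrow(points) >= 2L &&
        all(points[1L, ] == points[nrow(points), ]))
      points <- points[-nrow(points), , drop = FALSE]
    if (nrow(points) < 3L)
      stop("degenerate contour: fewer than 3 distinct points")
    if (!all(is.finite(points)) || !is.finite(z_mm))
      stop("contour coordinates must be finite")
    d <- points - points[c(2:nrow(points), 1L), , drop = FALSE]
    if (any(rowSums(d * d) == 0))
      stop("contour has two identical consecutive points")
  }
  structure(list(points = points, z_mm = z_mm), class = "rt_contour")
}

#' @export
print.rt_contour <- function(x, ...) {
  cat(sprintf("<rt_contour> z = %.3f mm, %d points, perimeter %.2f mm, area %.2f mm^2\n",
              x$z_mm, nrow(x$points), contour_perimeter(x), abs(contour_area(x))))
  invisible(x)
}

edge_lengths <- function(points) {
  d <- points[c(2:nrow(points), 1L), , drop = FALSE] - points
  sqrt(rowSums(d * d))
}

#' Perimeter of a closed contour
#' @param c an `rt_contour`.
#' @return perimeter in mm.
#' @export
contour_perimeter <- function(c) sum(edge_lengths(c$points))

#' Signed area of a closed contour
#'
#' Shoelace formula; positive for counter-clockwise orientation when viewed
#' from +z (superior).
#' @param c an `rt_contour`.
#' @return signed area in mm^2.
#' @export
contour_area <- function(c) {
  p <- c$points
  q <- p[c(2:nrow(p), 1L), , drop = FALSE]
  sum(p[, 1L] * q[, 2L] - q[, 1L] * p[, 2L]) / 2
}

# Orient a contour counter-clockwise (positive area).
orient_ccw <- function(c) {
  if (contour_area(c) < 0)
    c$points <- c$points[nrow(c$points):1L, , drop = FALSE]
  c
}

#' Test whether a polygon is simple (non-self-intersecting)
#'
#' All non-adjacent edge pairs are tested for proper or improper crossing.
#' Design contours are required to be simple before meshing.
#'
#' @param c an `rt_contour`.
#' @return `TRUE` if no two non-adjacent edges intersect.
#' @export
is_simple_contour <- function(c) {
  p <- c$points
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    # skip edges adjacent to edge i (shared endpoint cannot count as crossing)
    j <- setdiff((i + 2L):n, if (i == 1L) n else integer(0))
    if (!length(j)) next
    if (any(segments_intersect(a[i, ], b[i, ], a[j, , drop = FALSE], b[j, , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

# Vectorised proper/collinear-overlap segment intersection test:
# segment (p1,p2) against rows of (q1, q2).
segments_intersect <- function(p1, p2, q1, q2) {
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- cross2(q1[, 1L], q1[, 2L], q2[, 1L], q2[, 2L], p1[1L], p1[2L])
  d2 <- cross2(q1[, 1L], q1[, 2L], q2[, 1L], q2[, 2L], p2[1L], p2[2L])
  d3 <- cross2(p1[1L], p1[2L], p2[1L], p2[2L], q1[, 1L], q1[, 2L])
  d4 <- cross2(p1[1L], p1[2L], p2[1L], p2[2L], q2[, 1L], q2[, 2L])
  proper <- (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
             ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
  if (any(proper)) return(proper)
  # touching/collinear contacts count as non-simple only if interiors overlap;
  # endpoint grazing is tolerated (resampled contours touch at vertices).
  rep(FALSE, nrow(q1))
}

#' Construct a stack of axial contours
#'
#' The in-memory form of a bolus design: one closed contour per axial slice,
#' strictly ascending in z. Single-component objects only.
#'
#' @param contours list of [contour()] objects.
#' @param frame coordinate-frame label recorded on the stack
#'   (default `"LPS"`).
#' @return an object of class `rt_contour_stack`.
#' @export
contour_stack <- function(contours, frame = "LPS") {
  if (!length(contours) || !all(vapply(contours, inherits, TRUE, "rt_contour")))
    stop("contours must be a non-empty list of rt_contour objects")
  z <- vapply(contours, function(c) c$z_mm, 0)
  o <- order(z)
  contours <- contours[o]
  z <- z[o]
  if (any(diff(z) <= 0))
    stop("contour stack must have strictly increasing z (one contour per slice)")
  structure(list(contours = contours, frame = frame),
            class = "rt_contour_stack")
}

#' @export
print.rt_contour_stack <- function(x, ...) {
  z <- stack_z(x)
  cat(sprintf("<rt_contour_stack> %d slices, z in [%.2f, %.2f] mm (frame %s)\n",
              length(z), min(z), max(z), x$frame))
  invisible(x)
}

#' Axial positions of a contour stack
#' @param s an `rt_contour_stack`.
#' @return numeric vector of slice z positions in mm, ascending.
#' @export
stack_z <- function(s) vapply(s$contours, function(c) c$z_mm, 0)

#' Subdivide contour edges to a maximum spacing
#'
#' Before meshing, design profiles are refined so that every polygon edge is
#' no longer than `max_spacing_mm` (sub-millimetre sampling ahead of surface
#' reconstruction). Each edge of length L is split into `ceiling(L /
#' max_spacing_mm)` equal parts; existing vertices are never moved or
#' removed, so the polygon as a curve is unchanged and the perimeter is
#' preserved exactly.
#'
#' @param c an `rt_contour`.
#' @param max_spacing_mm maximum allowed edge length in mm (> 0).
#' @return an `rt_contour` with every edge <= `max_spacing_mm`.
#' @export
resample_contour <- function(c, max_spacing_mm) {
  stopifnot(inherits(c, "rt_contour"))
  if (!is.numeric(max_spacing_mm) || max_spacing_mm <= 0)
    stop("max_spacing_mm must be > 0")
  p <- c$points
  n <- nrow(p)
  if (n < 3L) stop("degenerate contour: fewer than 3 points")
  len <- edge_lengths(p)
  k <- pmax(1L, as.integer(ceiling(len / max_spacing_mm - 1e-12)))
  if (all(k == 1L)) return(c)
  nxt <- p[c(2:n, 1L), , drop = FALSE]
  idx <- rep.int(seq_len(n), k)
  frac <- unlist(lapply(seq_len(n), function(i) (seq_len(k[i]) - 1L) / k[i]),
                 use.names = FALSE)
  out <- p[idx, , drop = FALSE] * (1 - frac) + nxt[idx, , drop = FALSE] * frac
  contour(out, c$z_mm, validate = FALSE)
}

# Resample a closed contour to exactly n points, uniformly in arc length,
# starting at the first vertex. New points lie exactly on the input polygon.
resample_contour_n <- function(c, n) {
  p <- c$points
  m <- nrow(p)
  if (m == n) {
    len <- edge_lengths(p)
    if (max(len) - min(len) < 1e-9 * mean(len)) return(c)  # already uniform
  }
  len <- edge_lengths(p)
  cum <- c(0, cumsum(len))
  total <- cum[m + 1L]
  t <- (seq_len(n) - 1L) / n * total
  seg <- findInterval(t, cum, rightmost.closed = TRUE)
  seg[seg > m] <- m
  frac <- (t - cum[seg]) / len[seg]
  nxt <- p[c(2:m, 1L), , drop = FALSE]
  out <- p[seg, , drop = FALSE] * (1 - frac) + nxt[seg, , drop = FALSE] * frac
  contour(out, c$z_mm, validate = FALSE)
}

# Cyclic shift of contour B minimising the sum of squared distances to
# contour A (both n x 2, same n). Returns the shifted point matrix.
align_cyclic <- function(a, b) {
  n <- nrow(a)
  # ssd(k) = const - 2 * sum_i a_i . b_{i+k}; maximise the cross term
  best_k <- 0L
  best <- -Inf
  bx <- b[, 1L]; by <- b[, 2L]
  for (k in 0L:(n - 1L)) {
    idx <- ((seq_len(n) - 1L + k) %% n) + 1L
    s <- sum(a[, 1L] * bx[idx] + a[, 2L] * by[idx])
    if (s > best) { best <- s; best_k <- k }
  }
  idx <- ((seq_len(n) - 1L + best_k) %% n) + 1L
  b[idx, , drop = FALSE]
}

# Establish vertex correspondence across a stack: orient all contours CCW,
# resample each to the maximum point count, then cyclically align each
# contour to its predecessor. Returns a stack whose contours all have the
# same number of corresponding vertices.
correspond_stack <- function(s, max_spacing_mm = NULL) {
  cs <- lapply(s$contours, orient_ccw)
  if (!is.null(max_spacing_mm))
    cs <- lapply(cs, resample_contour, max_spacing_mm = max_spacing_mm)
  n <- max(vapply(cs, function(c) nrow(c$points), 0L))
  cs <- lapply(cs, resample_contour_n, n = n)
  for (i in seq_along(cs)[-1L])
    cs[[i]]$points <- align_cyclic(cs[[i - 1L]]$points, cs[[i]]$points)
  contour_stack(cs, frame = s$frame)
}

#' Interpolate a contour stack to a finer slice spacing
#'
#' Bolus designs live on CT slices a few millimetres apart; before surface
#' reconstruction the stack is refined so adjacent slices are at most
#' `target_spacing_mm` apart. Each z-gap of width dz is subdivided into
#' `ceiling(dz / target_spacing_mm)` equal sub-gaps and intermediate
#' contours are vertex-wise linear blends of the bounding slices (after the
#' stack has been put into vertex correspondence: common point count,
#' counter-clockwise orientation, cyclic alignment by least squared
#' distance). If every existing gap is already within the target the stack
#' is returned unchanged.
#'
#' @param s an `rt_contour_stack` with at least 2 contours.
#' @param target_spacing_mm maximum output slice gap in mm (default 1).
#' @return an `rt_contour_stack` with gaps <= `target_spacing_mm`; original
#'   slice positions are retained.
#' @export
interpolate_stack <- function(s, target_spacing_mm = 1.0) {
  stopifnot(inherits(s, "rt_contour_stack"))
  if (length(s$contours) < 2L)
    stop("interpolate_stack needs at least 2 contours")
  if (target_spacing_mm <= 0) stop("target_spacing_mm must be > 0")
  z <- stack_z(s)
  gaps <- diff(z)
  nsub <- pmax(1L, as.integer(ceiling(gaps / target_spacing_mm - 1e-12)))
  if (all(nsub == 1L)) return(s)
  sc <- correspond_stack(s)
  out <- list(sc$contours[[1L]])
  for (i in seq_along(gaps)) {
    a <- sc$contours[[i]]; b <- sc$contours[[i + 1L]]
    for (j in seq_len(nsub[i])) {
      f <- j / nsub[i]
      if (j < nsub[i]) {
        pts <- a$points * (1 - f) + b$points * f
        out[[length(out) + 1L]] <- contour(pts, a$z_mm * (1 - f) + b$z_mm * f,
                                           validate = FALSE)
      } else {
        out[[length(out) + 1L]] <- b
      }
    }
  }
  contour_stack(out, frame = s$frame)
}
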