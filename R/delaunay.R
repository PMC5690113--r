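# 2-D Delaunay triangulation (Bowyer-Watson) and constrained polygon caps.
#
# Surface reconstruction closes the end slices of a contour stack with a
# triangulation of the end polygons satisfying the empty-circumcircle
# property; non-convex contours additionally require their boundary edges to
# be present (constrained Delaunay) with exterior triangles culled.

# > 0 iff point d lies strictly inside the circumcircle of CCW triangle abc.
incircle_det <- function(a, b, c, d) {
  adx <- a[1L] - d[1L]; ady <- a[2L] - d[2L]
  bdx <- b[1L] - d[1L]; bdy <- b[2L] - d[2L]
  cdx <- c[1L] - d[1L]; cdy <- c[2L] - d[2L]
  (adx * adx + ady * ady) * (bdx * cdy - cdx * bdy) +
  (bdx * bdx + bdy * bdy) * (cdx * ady - adx * cdy) +
  (cdx * cdx + cdy * cdy) * (adx * bdy - bdx * ady)
}

orient2d <- function(a, b, c)
  (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])

# Bowyer-Watson incremental Delaunay triangulation of a 2-D point set.
# Deterministic: points are inserted in input order; cocircular
# configurations are resolved by the strict inside test, so the diagonal
# chosen depends only on insertion order (a fixed lexicographic-style
# perturbation). Returns an m x 3 matrix of 1-based CCW triangles.
delaunay2d <- function(points) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points")
  # super-triangle comfortably containing all points
  cmin <- apply(pts, 2L, min); cmax <- apply(pts, 2L, max)
  d <- max(cmax - cmin, 1)
  mid <- (cmin + cmax) / 2
  sup <- rbind(mid + c(-20 * d, -10 * d),
               mid + c( 20 * d, -10 * d),
               mid + c( 0,       20 * d))
  P <- rbind(pts, sup)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L
  tris <- matrix(c(s1, s2, s3), 1L, 3L)
  # circumcircle cache: centre x, y, radius^2
  cc <- matrix(0, 1L, 3L)
  circ <- function(t) {
    a <- P[t[1L], ]; b <- P[t[2L], ]; c <- P[t[3L], ]
    d2 <- 2 * (a[1L] * (b[2L] - c[2L]) + b[1L] * (c[2L] - a[2L]) + c[1L] * (a[2L] - b[2L]))
    ux <- ((a[1L]^2 + a[2L]^2) * (b[2L] - c[2L]) + (b[1L]^2 + b[2L]^2) * (c[2L] - a[2L]) +
           (c[1L]^2 + c[2L]^2) * (a[2L] - b[2L])) / d2
    uy <- ((a[1L]^2 + a[2L]^2) * (c[1L] - b[1L]) + (b[1L]^2 + b[2L]^2) * (a[1L] - c[1L]) +
           (c[1L]^2 + c[2L]^2) * (b[1L] - a[1L])) / d2
    c(ux, uy, (a[1L] - ux)^2 + (a[2L] - uy)^2)
  }
  cc[1L, ] <- circ(tris[1L, ])
  for (ip in seq_len(n)) {
    p <- P[ip, ]
    dx <- cc[, 1L] - p[1L]; dy <- cc[, 2L] - p[2L]
    bad <- which(dx * dx + dy * dy < cc[, 3L] * (1 + 1e-12))
    if (!length(bad)) {
      # numerical safety: fall back to exact incircle test
      bad <- which(vapply(seq_len(nrow(tris)), function(i)
        incircle_det(P[tris[i, 1L], ], P[tris[i, 2L], ], P[tris[i, 3L], ], p) > 0, TRUE))
      if (!length(bad)) next
    }
    bt <- tris[bad, , drop = FALSE]
    ea <- c(bt[, 1L], bt[, 2L], bt[, 3L])
    eb <- c(bt[, 2L], bt[, 3L], bt[, 1L])
    key <- paste(pmin(ea, eb), pmax(ea, eb))
    once <- !(key %in% key[duplicated(key)])
    ba <- ea[once]; bb <- eb[once]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    newt <- cbind(ba, bb, ip)
    newcc <- t(vapply(seq_len(nrow(newt)), function(i) circ(newt[i, ]), numeric(3)))
    tris <- rbind(tris, newt)
    cc <- rbind(cc, newcc)
  }
  keep <- tris[, 1L] <= n & tris[, 2L] <= n & tris[, 3L] <= n
  tris <- tris[keep, , drop = FALSE]
  # normalise to CCW
  for (i in seq_len(nrow(tris))) {
    t <- tris[i, ]
    if (orient2d(P[t[1L], ], P[t[2L], ], P[t[3L], ]) < 0)
      tris[i, ] <- t[c(1L, 3L, 2L)]
  }
  dimnames(tris) <- NULL
  tris
}

# Recursive Delaunay triangulation of a pseudo-polygon against base edge
# (a, b): choose the vertex whose circumcircle with (a, b) is empty.
# `verts` are the interior chain vertices in order from a to b.
triangulate_pseudo <- function(P, a, b, verts) {
  if (!length(verts)) return(matrix(integer(0), 0L, 3L))
  if (length(verts) == 1L) return(matrix(c(a, verts, b), 1L, 3L))
  ci <- 1L
  for (k in seq_along(verts)[-1L]) {
    if (incircle_det(P[a, ], P[b, ], P[verts[ci], ], P[verts[k], ]) > 0)
      ci <- k
  }
  c_ <- verts[ci]
  rbind(matrix(c(a, c_, b), 1L, 3L),
        triangulate_pseudo(P, a, c_, verts[seq_len(ci - 1L)]),
        triangulate_pseudo(P, c_, b, verts[seq_along(verts) > ci]))
}

# Insert a constrained edge (a, b) into triangulation `tris` over points P:
# remove the triangles the open segment crosses and retriangulate the two
# pseudo-polygons on either side.
insert_constraint <- function(P, tris, a, b) {
  ea <- c(tris[, 1L], tris[, 2L], tris[, 3L])
  eb <- c(tris[, 2L], tris[, 3L], tris[, 1L])
  has <- any((ea == a & eb == b) | (ea == b & eb == a))
  if (has) return(tris)
  pa <- P[a, ]; pb <- P[b, ]
  crossed <- logical(nrow(tris))
  for (i in seq_len(nrow(tris))) {
    t <- tris[i, ]
    if (a %in% t || b %in% t) {
      # triangle incident to an endpoint is crossed if the opposite edge
      # properly crosses segment ab
      opp <- setdiff(t, c(a, b))
      if (length(opp) == 2L) {
        d1 <- orient2d(pa, pb, P[opp[1L], ])
        d2 <- orient2d(pa, pb, P[opp[2L], ])
        d3 <- orient2d(P[opp[1L], ], P[opp[2L], ], pa)
        d4 <- orient2d(P[opp[1L], ], P[opp[2L], ], pb)
        crossed[i] <- (d1 * d2 < 0) && (d3 * d4 < 0)
      }
    } else {
      for (e in list(t[c(1L, 2L)], t[c(2L, 3L)], t[c(3L, 1L)])) {
        d1 <- orient2d(pa, pb, P[e[1L], ])
        d2 <- orient2d(pa, pb, P[e[2L], ])
        d3 <- orient2d(P[e[1L], ], P[e[2L], ], pa)
        d4 <- orient2d(P[e[1L], ], P[e[2L], ], pb)
        if ((d1 * d2 < 0) && (d3 * d4 < 0)) { crossed[i] <- TRUE; break }
      }
    }
  }
  if (!any(crossed))
    stop("constrained edge recovery failed: no crossed triangles found")
  cav <- tris[crossed, , drop = FALSE]
  vs <- setdiff(unique(as.vector(cav)), c(a, b))
  side <- vapply(vs, function(v) orient2d(pa, pb, P[v, ]), 0)
  dir <- pb - pa
  proj <- vapply(vs, function(v) sum((P[v, ] - pa) * dir), 0)
  up <- vs[side > 0][order(proj[side > 0])]
  dn <- vs[side < 0][order(proj[side < 0])]
  tris <- tris[!crossed, , drop = FALSE]
  newt <- rbind(triangulate_pseudo(P, a, b, up),
                triangulate_pseudo(P, a, b, dn))
  for (i in seq_len(nrow(newt))) {
    t <- newt[i, ]
    if (orient2d(P[t[1L], ], P[t[2L], ], P[t[3L], ]) < 0)
      newt[i, ] <- t[c(1L, 3L, 2L)]
  }
  rbind(tris, newt)
}

# Point-in-polygon (crossing number), vectorised over query rows.
points_in_polygon <- function(q, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(q))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    cond <- ((yi > q[, 2L]) != (yj > q[, 2L])) &
      (q[, 1L] < (xj - xi) * (q[, 2L] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cond)
    j <- i
  }
  inside
}

#' Constrained Delaunay triangulation of a simple polygon
#'
#' Triangulates the interior of a closed polygon: a Bowyer-Watson Delaunay
#' triangulation of the vertices, followed by recovery of any missing
#' boundary edges (cavity retriangulation, so the result is a constrained
#' Delaunay triangulation) and culling of triangles whose centroid falls
#' outside the polygon. Used to cap the end slices of a reconstructed
#' surface.
#'
#' @param points n x 2 matrix of polygon vertices in order, closing edge
#'   implicit, no duplicated closing vertex.
#' @return m x 3 matrix of CCW triangles (1-based indices into `points`);
#'   every polygon boundary edge is an edge of the triangulation.
#' @export
triangulate_polygon <- function(points) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < 3L) stop("polygon needs at least 3 vertices")
  if (n == 3L) {
    t <- matrix(1:3, 1L, 3L)
    if (orient2d(pts[1L, ], pts[2L, ], pts[3L, ]) < 0) t <- t[, c(1L, 3L, 2L), drop = FALSE]
    return(t)
  }
  tris <- delaunay2d(pts)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    tris <- insert_constraint(pts, tris, i, j)
  }
  cent <- (pts[tris[, 1L], , drop = FALSE] +
           pts[tris[, 2L], , drop = FALSE] +
           pts[tris[, 3L], , drop = FALSE]) / 3
  tris[points_in_polygon(cent, pts), , drop = FALSE]
}
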