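# Shared fixtures and independent brute-force oracles.

square_contour <- function(side = 10, z = 0, origin = c(0, 0)) {
  contour(rbind(origin,
                origin + c(side, 0),
                origin + c(side, side),
                origin + c(0, side)), z)
}

circle_contour <- function(radius, z, n = 64, centre = c(0, 0), angle0 = 0) {
  th <- angle0 + 2 * pi * (0:(n - 1)) / n
  contour(cbind(centre[1] + radius * cos(th), centre[2] + radius * sin(th)), z)
}

cube_mesh <- function(side = 10) {
  stack_to_mesh(contour_stack(list(square_contour(side, 0),
                                   square_contour(side, side))),
                target_spacing_mm = 2 * side)
}

# O(n^2) double-loop Hausdorff oracle on sampled points (no vectorisation
# shared with the implementation)
hausdorff_oracle <- function(a, b) {
  dmin_ab <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
      if (d < best) best <- d
    }
    dmin_ab[i] <- best
  }
  dmin_ba <- numeric(nrow(b))
  for (j in seq_len(nrow(b))) {
    best <- Inf
    for (i in seq_len(nrow(a))) {
      d <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
      if (d < best) best <- d
    }
    dmin_ba[j] <- best
  }
  max(max(dmin_ab), max(dmin_ba))
}

# brute-force convex hull volume: every point triple whose plane has all
# other points on one side is a hull face; volume = sum of signed
# tetrahedra against the centroid
convex_hull_volume_oracle <- function(pts) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  vol <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
    nrm <- c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
             (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
             (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    s <- as.vector((pts - matrix(a, n, 3, byrow = TRUE)) %*% nrm)
    s[c(i, j, k)] <- 0
    if (all(s <= 1e-9) || all(s >= -1e-9)) {
      # orient the face outward from the centroid
      if (sum((a - ctr) * nrm) < 0) { tmp <- b; b <- c; c <- tmp }
      vol <- vol + (sum((a - ctr) * c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
                                      (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
                                      (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])))) / 6
    }
  }
  vol
}

# hull faces (index triples, outward CCW) for building a mesh on a convex
# vertex set
convex_hull_faces <- function(pts) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  faces <- list()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; c <- pts[k, ]
    nrm <- c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
             (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
             (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    s <- as.vector((pts - matrix(a, n, 3, byrow = TRUE)) %*% nrm)
    s[c(i, j, k)] <- 0
    if (all(s <= 1e-9) || all(s >= -1e-9)) {
      f <- if (sum((a - ctr) * nrm) >= 0) c(i, j, k) else c(i, k, j)
      faces[[length(faces) + 1]] <- f
    }
  }
  unique(do.call(rbind, faces))
}

icosahedron_vertices <- function(radius = 10) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v / sqrt(1 + phi^2) * radius
}

# empty-circumcircle oracle for a (constrained) polygon cap: no polygon
# vertex visible from a triangle's centroid may lie strictly inside its
# circumcircle; visibility is blocked by polygon boundary edges.
cap_circumcircle_ok <- function(pts, tris, tol = 1e-7) {
  n <- nrow(pts)
  seg_cross <- function(p1, p2, q1, q2) {
    o <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- o(p1, p2, q1); d2 <- o(p1, p2, q2)
    d3 <- o(q1, q2, p1); d4 <- o(q1, q2, p2)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (r in seq_len(nrow(tris))) {
    a <- pts[tris[r, 1], ]; b <- pts[tris[r, 2], ]; c <- pts[tris[r, 3], ]
    d2 <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    ux <- ((sum(a^2)) * (b[2] - c[2]) + (sum(b^2)) * (c[2] - a[2]) + (sum(c^2)) * (a[2] - b[2])) / d2
    uy <- ((sum(a^2)) * (c[1] - b[1]) + (sum(b^2)) * (a[1] - c[1]) + (sum(c^2)) * (b[1] - a[1])) / d2
    r2 <- (a[1] - ux)^2 + (a[2] - uy)^2
    ctr <- (a + b + c) / 3
    for (v in setdiff(seq_len(n), tris[r, ])) {
      p <- pts[v, ]
      if ((p[1] - ux)^2 + (p[2] - uy)^2 < r2 * (1 - tol)) {
        visible <- TRUE
        for (e in seq_len(n)) {
          e2 <- if (e == n) 1 else e + 1
          if (v %in% c(e, e2)) next
          if (seg_cross(ctr, p, pts[e, ], pts[e2, ])) { visible <- FALSE; break }
        }
        if (visible) return(FALSE)
      }
    }
  }
  TRUE
}

# deterministic random star-shaped simple contour
random_contour <- function(seed, n = 40, z = 0, r_base = 20) {
  set.seed(seed)
  th <- sort(runif(n, 0, 2 * pi))
  r <- r_base * (0.6 + 0.4 * runif(n))
  contour(cbind(r * cos(th), r * sin(th)), z)
}
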