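# Indexed triangle meshes: the printable surface representation.

#' Construct an indexed triangle mesh
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates in mm.
#' @param facets integer m x 3 matrix of 1-based vertex indices; the facet
#'   normal follows the right-hand rule over the vertex order, and a closed
#'   mesh is oriented outward when its signed volume is positive.
#' @return an object of class `rt_mesh` with fields `vertices`, `facets`,
#'   and unit `normals` (m x 3, recomputed from the geometry).
#' @export
triangle_mesh <- function(vertices, facets) {
  vertices <- as.matrix(vertices)
  facets <- as.matrix(facets)
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(facets) != 3L) stop("facets must be an m x 3 index matrix")
  storage.mode(vertices) <- "double"
  storage.mode(facets) <- "integer"
  dimnames(vertices) <- dimnames(facets) <- NULL
  if (nrow(facets) && (min(facets) < 1L || max(facets) > nrow(vertices)))
    stop("facet indices out of range")
  m <- structure(list(vertices = vertices, facets = facets, normals = NULL),
                 class = "rt_mesh")
  m$normals <- facet_normals(m)
  m
}

#' @export
print.rt_mesh <- function(x, ...) {
  cat(sprintf("<rt_mesh> %d vertices, %d facets", nrow(x$vertices), nrow(x$facets)))
  v <- tryCatch(signed_volume(x), error = function(e) NA_real_)
  if (is.finite(v)) cat(sprintf(", signed volume %.2f mm^3", v))
  cat("\n")
  invisible(x)
}

# Unit facet normals by the right-hand rule; zero-area facets get zero rows.
facet_normals <- function(m) {
  a <- m$vertices[m$facets[, 1L], , drop = FALSE]
  b <- m$vertices[m$facets[, 2L], , drop = FALSE]
  c <- m$vertices[m$facets[, 3L], , drop = FALSE]
  u <- b - a; v <- c - a
  n <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
             u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
             u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  len <- sqrt(rowSums(n * n))
  ok <- len > 0
  n[ok, ] <- n[ok, , drop = FALSE] / len[ok]
  n
}

# Signed enclosed volume via the divergence theorem (sum of signed
# tetrahedra against the origin). Positive for outward orientation.
signed_volume <- function(m) {
  a <- m$vertices[m$facets[, 1L], , drop = FALSE]
  b <- m$vertices[m$facets[, 2L], , drop = FALSE]
  c <- m$vertices[m$facets[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * c[, 3L] - b[, 3L] * c[, 2L]) +
      a[, 2L] * (b[, 3L] * c[, 1L] - b[, 1L] * c[, 3L]) +
      a[, 3L] * (b[, 1L] * c[, 2L] - b[, 2L] * c[, 1L])) / 6
}

#' Validate a triangle mesh for printability
#'
#' Report-only integrity checks of the kind a CAD pre-print inspection
#' performs: watertightness (every undirected edge shared by exactly two
#' facets), consistent orientation (each shared edge traversed once in each
#' direction), Euler characteristic per connected component, degenerate and
#' duplicate facets, and the signed enclosed volume (positive when normals
#' point outward).
#'
#' @param m an `rt_mesh`.
#' @return an object of class `mesh_validation`: list with `watertight`,
#'   `consistent_orientation`, `boundary_edges` (k x 2 index matrix),
#'   `nonmanifold_edges`, `n_components`, `euler_per_component`,
#'   `n_degenerate_facets`, `n_duplicate_facets`, `signed_volume_mm3`,
#'   `outward`, and `ok` (watertight, consistent, outward, no degenerates).
#' @export
validate_mesh <- function(m) {
  stopifnot(inherits(m, "rt_mesh"))
  f <- m$facets
  nf <- nrow(f)
  # directed edges
  ea <- c(f[, 1L], f[, 2L], f[, 3L])
  eb <- c(f[, 2L], f[, 3L], f[, 1L])
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  key <- paste(lo, hi)
  cnt <- table(key)
  boundary_keys <- names(cnt)[cnt == 1L]
  nonmanifold_keys <- names(cnt)[cnt > 2L]
  watertight <- !length(boundary_keys) && !length(nonmanifold_keys)
  # orientation: for shared edges, the two traversals must be opposite
  dir_key <- paste(ea, eb)
  dup_dir <- any(duplicated(dir_key))
  consistent <- watertight && !dup_dir
  key_to_edge <- function(keys) {
    if (!length(keys)) return(matrix(integer(0), 0L, 2L))
    t(vapply(strsplit(keys, " "), function(s) as.integer(s), integer(2)))
  }
  degen <- f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]
  areas <- {
    a <- m$vertices[f[, 1L], , drop = FALSE]
    b <- m$vertices[f[, 2L], , drop = FALSE]
    c <- m$vertices[f[, 3L], , drop = FALSE]
    u <- b - a; v <- c - a
    n <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
               u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
               u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
    sqrt(rowSums(n * n)) / 2
  }
  degen <- degen | areas == 0
  dupf <- duplicated(apply(f, 1L, function(r) paste(sort(r), collapse = " ")))
  # connected components over vertices used by facets (union-find)
  used <- sort(unique(as.vector(f)))
  parent <- seq_len(nrow(m$vertices))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_along(ea)) {
    ra <- find(ea[i]); rb <- find(eb[i])
    if (ra != rb) parent[ra] <- rb
  }
  comp <- vapply(used, find, 0L)
  comp_id <- match(comp, unique(comp))
  n_comp <- length(unique(comp_id))
  # per-component Euler characteristic V - E + F
  und_first <- !duplicated(key)
  edge_comp <- comp_id[match(lo[und_first], used)]
  face_comp <- comp_id[match(f[, 1L], used)]
  vert_comp <- comp_id
  euler <- vapply(seq_len(n_comp), function(k)
    sum(vert_comp == k) - sum(edge_comp == k) + sum(face_comp == k), 0)
  vol <- signed_volume(m)
  res <- structure(list(
    watertight = watertight,
    consistent_orientation = consistent,
    boundary_edges = key_to_edge(boundary_keys),
    nonmanifold_edges = key_to_edge(nonmanifold_keys),
    n_components = n_comp,
    euler_per_component = euler,
    n_degenerate_facets = sum(degen),
    n_duplicate_facets = sum(dupf),
    signed_volume_mm3 = vol,
    outward = watertight && vol > 0,
    ok = watertight && consistent && vol > 0 && sum(degen) == 0L
  ), class = "mesh_validation")
  res
}

#' @export
print.mesh_validation <- function(x, ...) {
  cat("<mesh_validation>\n")
  cat(sprintf("  watertight: %s (%d boundary, %d non-manifold edges)\n",
              x$watertight, nrow(x$boundary_edges), nrow(x$nonmanifold_edges)))
  cat(sprintf("  orientation consistent: %s, outward: %s\n",
              x$consistent_orientation, x$outward))
  cat(sprintf("  components: %d, Euler characteristic: %s\n",
              x$n_components, paste(x$euler_per_component, collapse = ", ")))
  cat(sprintf("  degenerate facets: %d, duplicate facets: %d\n",
              x$n_degenerate_facets, x$n_duplicate_facets))
  cat(sprintf("  signed volume: %.3f mm^3\n", x$signed_volume_mm3))
  cat(sprintf("  ok: %s\n", x$ok))
  invisible(x)
}

#' Enclosed volume of a watertight mesh
#'
#' Signed volume by the divergence theorem summed over facets; used for
#' design volumes in density estimation. Errors on non-watertight meshes,
#' naming the open edges; a negative value indicates inward orientation and
#' is reported as an error so orientation faults are not silently absorbed.
#'
#' @param m an `rt_mesh`, watertight and consistently oriented.
#' @param check validate first (default `TRUE`).
#' @return enclosed volume in mm^3 (positive).
#' @export
mesh_volume <- function(m, check = TRUE) {
  if (check) {
    v <- validate_mesh(m)
    if (!v$watertight) {
      be <- v$boundary_edges
      shown <- utils::head(apply(be, 1L, paste, collapse = "-"), 10L)
      stop(sprintf("mesh is not watertight: %d open edge(s): %s",
                   nrow(be), paste(shown, collapse = ", ")))
    }
    if (v$signed_volume_mm3 < 0)
      stop(sprintf("mesh orientation error: normals point inward (signed volume %.3f mm^3)",
                   v$signed_volume_mm3))
    return(v$signed_volume_mm3)
  }
  signed_volume(m)
}

#' Scale a mesh about a fixed point
#'
#' Anisotropic scaling used to shrink a print (the compensator in the study
#' workflow is printed at half scale in each direction). The default fixed
#' point is the minimum corner of the bounding box so the part's base stays
#' put; normals are rederived from the scaled geometry.
#'
#' @param m an `rt_mesh`.
#' @param factors numeric length-3 (fx, fy, fz), all > 0 (a scalar is
#'   recycled).
#' @param fixed_point length-3 point held fixed; default the bounding-box
#'   minimum corner.
#' @return the scaled `rt_mesh`; volume scales by `prod(factors)`.
#' @export
scale_mesh <- function(m, factors, fixed_point = NULL) {
  stopifnot(inherits(m, "rt_mesh"))
  factors <- rep_len(as.numeric(factors), 3L)
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("scale factors must be positive")
  if (is.null(fixed_point)) fixed_point <- apply(m$vertices, 2L, min)
  v <- sweep(m$vertices, 2L, fixed_point)
  v <- sweep(v, 2L, factors, `*`)
  v <- sweep(v, 2L, fixed_point, `+`)
  triangle_mesh(v, m$facets)
}

# Flip all facet orientations.
flip_mesh <- function(m) triangle_mesh(m$vertices, m$facets[, c(1L, 3L, 2L)])

#' Axis-aligned bounding box of a mesh
#' @param m an `rt_mesh`.
#' @return 2 x 3 matrix: rows `min`, `max`.
#' @export
mesh_bbox <- function(m) {
  b <- rbind(apply(m$vertices, 2L, min), apply(m$vertices, 2L, max))
  rownames(b) <- c("min", "max")
  colnames(b) <- c("x", "y", "z")
  b
}
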