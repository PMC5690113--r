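# Characterisation of fabricated parts: CT profile extraction, geometric
# conformity, HU uniformity, mass density, height-gauge checks.

#' Extract a sub-pixel surface profile from one CT slice
#'
#' Marching-squares iso-contouring (with linear interpolation between voxel
#' centres, via `grDevices::contourLines`) of the axial slice nearest
#' `z_mm` at the given HU threshold. The default threshold is the midpoint
#' between the background and material mean HU, estimated by a 2-class
#' split of the slice intensities, which places the iso-line at the
#' half-maximum of the partial-volume ramp.
#'
#' @param v a `ct_volume`.
#' @param z_mm axial position of the slice (must lie inside the volume).
#' @param threshold_hu iso-level; `NULL` (default) for the estimated
#'   background/material midpoint.
#' @return an `rt_contour` in patient mm at the slice z. If several closed
#'   iso-contours exist, the largest-area component is returned with a
#'   warning.
#' @export
extract_slice_profile <- function(v, z_mm, threshold_hu = NULL) {
  stopifnot(inherits(v, "ct_volume"))
  k <- ct_slice_index(v, z_mm)
  sl <- v$hu[, , k]
  if (is.null(threshold_hu)) threshold_hu <- hu_midpoint_threshold(sl)
  x <- ct_axis(v, 1L); y <- ct_axis(v, 2L)
  cl <- grDevices::contourLines(x, y, sl, levels = threshold_hu)
  closed <- Filter(function(c) {
    n <- length(c$x)
    n >= 4L && c$x[1L] == c$x[n] && c$y[1L] == c$y[n]
  }, cl)
  if (!length(closed))
    stop(sprintf("no closed iso-contour at %g HU on slice z = %g mm",
                 threshold_hu, z_mm))
  areas <- vapply(closed, function(c) {
    n <- length(c$x)
    abs(sum(c$x[-n] * c$y[-1L] - c$x[-1L] * c$y[-n]) / 2)
  }, 0)
  if (length(closed) > 1L)
    warning(sprintf("%d closed components on slice z = %g mm; returning the largest",
                    length(closed), z_mm))
  best <- closed[[which.max(areas)]]
  n <- length(best$x)
  contour(cbind(best$x[-n], best$y[-n]), ct_axis(v, 3L)[k])
}

# midpoint between the two intensity classes of a slice/volume
hu_midpoint_threshold <- function(hu) {
  v <- as.vector(hu)
  q <- stats::quantile(v, c(0.05, 0.95), names = FALSE)
  if (q[1L] == q[2L]) return(q[1L])
  km <- stats::kmeans(v, centers = matrix(q, 2L, 1L))
  mean(km$centers)
}

#' Largest Euclidean distance between two slice profiles
#'
#' The per-slice conformity index: both contours are resampled to at most
#' `max_spacing_mm` point spacing and the symmetric largest nearest-point
#' distance (Hausdorff distance on the sampled point sets) is returned.
#' Point-to-point distances at <= 0.5 mm resampling bound the
#' discretisation error at 0.25 mm.
#'
#' @param design,measured `rt_contour` objects.
#' @param max_spacing_mm resampling spacing before comparison (default
#'   0.5 mm).
#' @return largest Euclidean distance in mm (symmetric, >= 0).
#' @export
slice_conformity <- function(design, measured, max_spacing_mm = 0.5) {
  stopifnot(inherits(design, "rt_contour"), inherits(measured, "rt_contour"))
  a <- resample_contour(design, max_spacing_mm)$points
  b <- resample_contour(measured, max_spacing_mm)$points
  d2 <- outer(a[, 1L], b[, 1L], `-`)^2 + outer(a[, 2L], b[, 2L], `-`)^2
  max(sqrt(apply(d2, 1L, min)), sqrt(apply(d2, 2L, min)))
}

#' Geometric conformity of a fabricated part against its design
#'
#' For every measured slice whose z lies inside the design's z range, the
#' design contour is interpolated to that z (vertex-wise blend of the
#' bounding design slices after correspondence) and the per-slice largest
#' Euclidean distance is computed; the report carries the per-slice values
#' and their mean and population (N) standard deviation. Optionally a rigid
#' in-plane pre-registration (centroid translation followed by 2-D
#' point-to-point ICP) is applied to the measured stack first and recorded;
#' by default comparison is in the shared patient frame with no
#' registration.
#'
#' @param design an `rt_contour_stack` (the design).
#' @param measured an `rt_contour_stack` (profiles extracted from CT).
#' @param register apply rigid 2-D pre-registration (default `FALSE`).
#' @param max_spacing_mm resampling spacing for the distance computation.
#' @return an object of class `conformity_report`: list with `per_slice`
#'   (data.frame `z_mm`, `largest_distance_mm`), `mean_mm`, `sd_mm`
#'   (population), `registered`, `transform`.
#' @export
conformity_report <- function(design, measured, register = FALSE,
                              max_spacing_mm = 0.5) {
  stopifnot(inherits(design, "rt_contour_stack"),
            inherits(measured, "rt_contour_stack"))
  dz <- stack_z(design)
  mz <- stack_z(measured)
  use <- which(mz >= min(dz) - 1e-9 & mz <= max(dz) + 1e-9)
  if (!length(use))
    stop("no measured slices overlap the design z range")
  transform <- NULL
  if (register) {
    transform <- register_stacks(design, measured)
    measured$contours <- lapply(measured$contours, function(c) {
      c$points <- sweep(c$points %*% transform$rotation, 2L,
                        transform$translation, `+`)
      c
    })
  }
  sc <- correspond_stack(design, max_spacing_mm = max_spacing_mm)
  dzz <- stack_z(sc)
  dist <- vapply(use, function(i) {
    z <- mz[i]
    hit <- which(abs(dz - z) < 1e-9)
    if (length(hit)) {
      # measured slice coincides with a design slice: compare to the
      # original design contour, no correspondence resampling involved
      design_c <- design$contours[[hit[1L]]]
    } else {
      j <- findInterval(z, dzz, rightmost.closed = TRUE)
      j <- min(max(j, 1L), length(dzz) - 1L)
      f <- (z - dzz[j]) / (dzz[j + 1L] - dzz[j])
      f <- min(max(f, 0), 1)
      pts <- sc$contours[[j]]$points * (1 - f) + sc$contours[[j + 1L]]$points * f
      design_c <- contour(pts, z, validate = FALSE)
    }
    slice_conformity(design_c, measured$contours[[i]], max_spacing_mm)
  }, 0)
  per_slice <- data.frame(z_mm = mz[use], largest_distance_mm = dist)
  structure(list(per_slice = per_slice,
                 mean_mm = mean(dist),
                 sd_mm = stats::sd(dist) * sqrt((length(dist) - 1) / length(dist)),
                 n_slices = length(dist),
                 registered = register,
                 transform = transform,
                 sd_definition = "population"),
            class = "conformity_report")
}

#' @export
print.conformity_report <- function(x, ...) {
  cat(sprintf("<conformity_report> %d slices: largest per-slice distance %.2f +/- %.2f mm (mean +/- population sd)\n",
              x$n_slices, x$mean_mm, x$sd_mm))
  if (x$registered) cat("  (rigid 2-D pre-registration applied)\n")
  invisible(x)
}

# centroid + 2-D ICP rigid registration of measured onto design
register_stacks <- function(design, measured, iters = 20L) {
  dp <- do.call(rbind, lapply(design$contours, function(c)
    resample_contour(c, 1)$points))
  mp <- do.call(rbind, lapply(measured$contours, function(c)
    resample_contour(c, 1)$points))
  R <- diag(2)
  t_ <- colMeans(dp) - colMeans(mp)
  for (it in seq_len(iters)) {
    cur <- sweep(mp %*% R, 2L, t_, `+`)
    d2 <- outer(rowSums(cur^2), rowSums(dp^2), `+`) - 2 * tcrossprod(cur, dp)
    nn <- dp[max.col(-d2, ties.method = "first"), , drop = FALSE]
    mu_m <- colMeans(mp); mu_n <- colMeans(nn)
    H <- crossprod(sweep(mp, 2L, mu_m), sweep(nn, 2L, mu_n))
    sv <- svd(H)
    Rn <- sv$v %*% t(sv$u)
    if (det(Rn) < 0) { sv$v[, 2L] <- -sv$v[, 2L]; Rn <- sv$v %*% t(sv$u) }
    tn <- mu_n - as.vector(mu_m %*% Rn)
    if (max(abs(Rn - R)) < 1e-10 && max(abs(tn - t_)) < 1e-8) { R <- Rn; t_ <- tn; break }
    R <- Rn; t_ <- tn
  }
  list(rotation = R, translation = t_)
}

#' HU mean and uniformity inside an interface-eroded core
#'
#' The object mask is morphologically eroded by a ball of radius
#' `erosion_margin_mm` (converted to voxel radii per axis, rounded up) so
#' partial-volume voxels at the air/object interface do not bias the
#' statistics; the mean and standard deviation of the remaining voxels are
#' returned. The study protocol uses a 1.25 mm margin.
#'
#' @param v a `ct_volume`.
#' @param object_mask logical array of the object voxels (same dim as the
#'   volume), or `NULL` to threshold at the background/material midpoint.
#' @param erosion_margin_mm erosion radius in mm (default 1.25).
#' @return list with `mean_hu`, `sd_hu`, `n_voxels`, `erosion_margin_mm`.
#' @export
hu_stats <- function(v, object_mask = NULL, erosion_margin_mm = 1.25) {
  stopifnot(inherits(v, "ct_volume"))
  if (is.null(object_mask))
    object_mask <- v$hu > hu_midpoint_threshold(v$hu)
  stopifnot(identical(dim(object_mask), dim(v$hu)))
  core <- erode_mask(object_mask, erosion_margin_mm, v$spacing_mm)
  if (!any(core))
    stop(sprintf("object mask vanished after %.2f mm erosion; use a smaller margin",
                 erosion_margin_mm))
  vals <- v$hu[core]
  list(mean_hu = mean(vals), sd_hu = stats::sd(vals),
       n_voxels = length(vals), erosion_margin_mm = erosion_margin_mm)
}

# binary erosion by an ellipsoidal ball: radius in voxels = ceil(margin /
# spacing) per axis; voxels outside the array count as background.
erode_mask <- function(mask, margin_mm, spacing_mm) {
  if (margin_mm <= 0) return(mask)
  r <- ceiling(margin_mm / spacing_mm - 1e-9)
  offs <- expand.grid(dx = -r[1L]:r[1L], dy = -r[2L]:r[2L], dz = -r[3L]:r[3L])
  keep <- (offs$dx / max(r[1L], 1))^2 + (offs$dy / max(r[2L], 1))^2 +
          (offs$dz / max(r[3L], 1))^2 <= 1 + 1e-12
  offs <- offs[keep, ]
  d <- dim(mask)
  out <- mask
  for (i in seq_len(nrow(offs))) {
    sh <- shift_mask(mask, c(offs$dx[i], offs$dy[i], offs$dz[i]), d)
    out <- out & sh
    if (!any(out)) break
  }
  out
}

shift_mask <- function(mask, by, d) {
  src <- lapply(1:3, function(a) {
    i <- seq_len(d[a]) + by[a]
    i
  })
  ok <- lapply(1:3, function(a) src[[a]] >= 1L & src[[a]] <= d[a])
  out <- array(FALSE, d)
  out[ok[[1L]], ok[[2L]], ok[[3L]]] <-
    mask[src[[1L]][ok[[1L]]], src[[2L]][ok[[2L]]], src[[3L]][ok[[3L]]], drop = FALSE]
  out
}

#' Mass density from weight and design volume
#'
#' @param mass_g measured mass in grams (> 0).
#' @param design_mesh watertight design `rt_mesh` (volume in mm^3), or a
#'   numeric volume in mm^3.
#' @return density in g/cm^3.
#' @export
estimate_density <- function(mass_g, design_mesh) {
  if (!is.numeric(mass_g) || length(mass_g) != 1L || mass_g <= 0)
    stop("mass_g must be a single positive number")
  vol_mm3 <- if (inherits(design_mesh, "rt_mesh")) mesh_volume(design_mesh)
             else as.numeric(design_mesh)
  if (vol_mm3 <= 0) stop("design volume must be positive")
  mass_g / (vol_mm3 / 1000)
}

#' Height-gauge point checks against a compensator design
#'
#' Mirrors the bench QA of probing known flat regions with a height gauge:
#' the design height is bilinearly interpolated at each planar probe
#' position and compared with the measured height (both from the part's
#' base).
#'
#' @param design an `rt_compensator` (or an `rt_mesh` height field, probed
#'   by its top surface z extent).
#' @param probes k x 2 matrix of planar probe positions in mm (inside the
#'   footprint).
#' @param measured_mm measured heights in mm, length k.
#' @param tolerance_mm pass tolerance on |deviation| (default 1 mm).
#' @return an object of class `height_check`: data.frame with `x_mm`,
#'   `y_mm`, `design_mm`, `measured_mm`, `deviation_mm`, plus attributes
#'   `pass` and `tolerance_mm`.
#' @export
height_check <- function(design, probes, measured_mm, tolerance_mm = 1.0) {
  probes <- matrix(as.numeric(probes), ncol = 2L)
  if (nrow(probes) != length(measured_mm))
    stop("one measured height per probe point required")
  if (inherits(design, "rt_compensator")) {
    h <- grid_height_at(design, probes)
  } else if (inherits(design, "rt_mesh")) {
    h <- mesh_height_at(design, probes)
  } else stop("design must be an rt_compensator or rt_mesh")
  dev <- measured_mm - h
  out <- data.frame(x_mm = probes[, 1L], y_mm = probes[, 2L],
                    design_mm = h, measured_mm = measured_mm,
                    deviation_mm = dev)
  attr(out, "tolerance_mm") <- tolerance_mm
  attr(out, "pass") <- all(abs(dev) < tolerance_mm)
  class(out) <- c("height_check", "data.frame")
  out
}

#' @export
print.height_check <- function(x, ...) {
  print.data.frame(x, ...)
  cat(sprintf("%s: all |deviation| < %.2f mm: %s\n",
              if (attr(x, "pass")) "PASS" else "FAIL",
              attr(x, "tolerance_mm"), attr(x, "pass")))
  if (!attr(x, "pass")) {
    bad <- which(abs(x$deviation_mm) >= attr(x, "tolerance_mm"))
    cat("  out of tolerance at probe(s):", paste(bad, collapse = ", "), "\n")
  }
  invisible(x)
}

# total height (max z minus min z) of the mesh surface above planar probes:
# column ray through each probe, span of facet intersections
mesh_height_at <- function(m, probes) {
  vapply(seq_len(nrow(probes)), function(i) {
    z <- column_intersections(m, probes[i, 1L], probes[i, 2L])
    if (length(z) < 2L) stop("probe point outside mesh footprint")
    max(z) - min(z)
  }, 0)
}

#' Map HU to relative electron density with a user calibration
#'
#' Piecewise-linear interpolation of a scanner-specific (HU, RED)
#' calibration table. HU outside the table range is clamped to the end
#' values with a warning. No default table is shipped: the HU-to-RED
#' relation is a property of the scanner calibration, not of this package.
#'
#' @param calibration_table data.frame or 2-column matrix with ascending
#'   `hu` and corresponding `red` (>= 2 rows).
#' @param hu Hounsfield units to convert.
#' @return relative electron density values.
#' @export
hu_to_red <- function(calibration_table, hu) {
  tab <- as.matrix(calibration_table)
  if (ncol(tab) != 2L || nrow(tab) < 2L)
    stop("calibration table must have >= 2 rows of (hu, red)")
  if (any(diff(tab[, 1L]) <= 0)) stop("calibration HU values must be ascending")
  if (any(hu < tab[1L, 1L] | hu > tab[nrow(tab), 1L]))
    warning("HU outside calibration range; clamped to table end values")
  stats::approx(tab[, 1L], tab[, 2L], xout = hu, rule = 2)$y
}

#' Assemble a material characterisation report
#'
#' Bundles the CT, weighing and beam measurements of one printed material
#' into a single record (HU mean/sd, mass density, relative electron
#' density, relative stopping power), each entry optional with a
#' provenance note.
#'
#' @param hu_mean,hu_sd Hounsfield statistics (e.g. from [hu_stats()]).
#' @param mass_density_g_cm3 from [estimate_density()].
#' @param relative_electron_density from [hu_to_red()].
#' @param relative_stopping_power from [estimate_rsp()].
#' @param provenance named character notes on where each entry came from.
#' @return an object of class `material_report`.
#' @export
material_report <- function(hu_mean = NULL, hu_sd = NULL,
                            mass_density_g_cm3 = NULL,
                            relative_electron_density = NULL,
                            relative_stopping_power = NULL,
                            provenance = character()) {
  if (!is.null(mass_density_g_cm3) && mass_density_g_cm3 <= 0)
    stop("mass density must be positive")
  structure(list(hu_mean = hu_mean, hu_sd = hu_sd,
                 mass_density_g_cm3 = mass_density_g_cm3,
                 relative_electron_density = relative_electron_density,
                 relative_stopping_power = relative_stopping_power,
                 provenance = provenance),
            class = "material_report")
}

#' @export
print.material_report <- function(x, ...) {
  cat("<material_report>\n")
  fmt <- function(lbl, v, unit = "")
    if (!is.null(v)) cat(sprintf("  %s: %.4g%s\n", lbl, v, unit))
  fmt("HU mean", x$hu_mean); fmt("HU sd", x$hu_sd)
  fmt("mass density", x$mass_density_g_cm3, " g/cm^3")
  fmt("relative electron density", x$relative_electron_density)
  fmt("relative stopping power", x$relative_stopping_power)
  invisible(x)
}
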