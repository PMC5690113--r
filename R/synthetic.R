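# Synthetic fixtures: parametric designs, simulated CT scans of "printed"
# objects, and DICOM fixture files. Everything the pipeline consumes can be
# generated here, deterministically under an explicit seed.

#' Generate a scalp-like electron bolus design
#'
#' A crescent-shaped shell (outer ellipse minus an inward-offset ellipse,
#' joined by flat ends) over a stack of axial slices, emulating a bolus
#' draped over a curved scalp: the ellipse axes shrink quadratically away
#' from the central slice and a smooth low-frequency radial perturbation
#' (three seeded cosine modes, modulated along z) breaks the symmetry.
#' All contours are simple; with `perturb_amp_mm = 0` the contours are the
#' analytic elliptical band.
#'
#' @param outer_semiaxes_mm outer ellipse semi-axes (a, b) at the central
#'   slice, mm.
#' @param thickness_mm shell thickness (default 8 mm).
#' @param z_range_mm axial extent, mm.
#' @param slice_spacing_mm design slice spacing (default 2.5 mm, a typical
#'   planning-CT spacing).
#' @param angle_range_deg angular extent of the crescent.
#' @param perturb_amp_mm amplitude of the smooth perturbation (default
#'   1.5 mm).
#' @param points_per_arc samples per arc before resampling (default 60).
#' @param seed integer seed (required when `perturb_amp_mm > 0`).
#' @return an `rt_contour_stack`.
#' @export
make_scalp_bolus <- function(outer_semiaxes_mm = c(35, 25), thickness_mm = 8,
                             z_range_mm = c(0, 25), slice_spacing_mm = 2.5,
                             angle_range_deg = c(-115, 115),
                             perturb_amp_mm = 1.5, points_per_arc = 60,
                             seed = NULL) {
  if (perturb_amp_mm > 0 && is.null(seed))
    stop("an explicit seed is required for a perturbed bolus")
  a <- outer_semiaxes_mm[1L]; b <- outer_semiaxes_mm[2L]
  if (thickness_mm <= 0 || thickness_mm >= min(a, b))
    stop("thickness must be positive and smaller than the semi-axes")
  zs <- seq(z_range_mm[1L], z_range_mm[2L], by = slice_spacing_mm)
  if (length(zs) < 2L) stop("z range must span at least two slices")
  modes <- if (perturb_amp_mm > 0) {
    with_seed(seed, list(amp = stats::runif(3L, 0.3, 1) * perturb_amp_mm,
                         phase = stats::runif(3L, 0, 2 * pi),
                         zphase = stats::runif(1L, 0, 2 * pi)))
  } else list(amp = numeric(3L), phase = numeric(3L), zphase = 0)
  th <- seq(angle_range_deg[1L], angle_range_deg[2L],
            length.out = points_per_arc) * pi / 180
  zc <- mean(z_range_mm); zh <- diff(z_range_mm) / 2
  contours <- lapply(zs, function(z) {
    s <- 1 - 0.15 * ((z - zc) / zh)^2
    zt <- (z - z_range_mm[1L]) / diff(z_range_mm)
    mod <- 1 + 0.3 * sin(pi * zt + modes$zphase)
    pert <- mod * (modes$amp[1L] * cos(th + modes$phase[1L]) +
                   modes$amp[2L] * cos(2 * th + modes$phase[2L]) +
                   modes$amp[3L] * cos(3 * th + modes$phase[3L]))
    ro_a <- a * s; ro_b <- b * s
    outer <- cbind((ro_a + pert) * cos(th), (ro_b + pert) * sin(th))
    inner <- cbind((ro_a - thickness_mm + pert) * cos(rev(th)),
                   (ro_b - thickness_mm + pert) * sin(rev(th)))
    cn <- contour(rbind(outer, inner), z)
    if (!is_simple_contour(cn))
      stop("generated bolus contour self-intersects; reduce perturb_amp_mm")
    cn
  })
  contour_stack(contours)
}

#' Generate a concave proton compensator design
#'
#' A smooth height field on a regular grid: uniform edge thickness minus a
#' radial concave bowl (thinner at the centre, as a compensator shaped to
#' the distal edge of a deep central target), plus seeded band-limited
#' cosine noise. Thickness is quantised to 0.01 mm, the decimal-string
#' precision at which grids are exported to the plan file, so the DICOM
#' round trip is exact.
#'
#' @param n_rows,n_cols grid size (default 100 x 100).
#' @param spacing_mm grid resolution (default 1 mm, the planning-system
#'   export resolution).
#' @param edge_thickness_mm thickness at the rim (default 45 mm).
#' @param bowl_depth_mm centre-to-rim thickness difference (default 25 mm).
#' @param noise_amp_mm amplitude of the band-limited surface noise
#'   (default 0.5 mm).
#' @param seed integer seed (required when `noise_amp_mm > 0`).
#' @return an `rt_compensator` (origin centred on the grid).
#' @export
make_compensator <- function(n_rows = 100L, n_cols = 100L, spacing_mm = 1,
                             edge_thickness_mm = 45, bowl_depth_mm = 25,
                             noise_amp_mm = 0.5, seed = NULL) {
  if (noise_amp_mm > 0 && is.null(seed))
    stop("an explicit seed is required for a noisy compensator")
  x <- (seq_len(n_cols) - (n_cols + 1) / 2) * spacing_mm
  y <- (seq_len(n_rows) - (n_rows + 1) / 2) * spacing_mm
  X <- matrix(x, n_rows, n_cols, byrow = TRUE)
  Y <- matrix(y, n_rows, n_cols)
  r <- sqrt(X^2 + Y^2)
  r0 <- max(abs(x), abs(y))
  bowl <- bowl_depth_mm * (cos(pmin(r / r0, 1) * pi) + 1) / 2
  t <- edge_thickness_mm - bowl
  if (noise_amp_mm > 0) {
    modes <- with_seed(seed, list(kx = stats::runif(4L, 0.5, 2.5),
                                  ky = stats::runif(4L, 0.5, 2.5),
                                  ph = stats::runif(4L, 0, 2 * pi),
                                  am = stats::runif(4L, 0.3, 1)))
    for (m in 1:4)
      t <- t + noise_amp_mm * modes$am[m] *
        cos(2 * pi * (modes$kx[m] * X / (n_cols * spacing_mm) +
                      modes$ky[m] * Y / (n_rows * spacing_mm)) + modes$ph[m])
  }
  t <- round(pmax(t, 0), 2)
  compensator_grid(t, pixel_spacing_mm = c(spacing_mm, spacing_mm),
                   origin_mm = c(x[1L], y[1L]))
}

#' Simulate a CT scan of a meshed object
#'
#' Voxelises a watertight mesh into a Hounsfield-unit volume the way a CT
#' of the printed part would look: inside/outside classification of voxel
#' centres by vertical ray parity, optional partial-volume fractions via
#' supersampling (`supersample^3` subvoxels), optional Gaussian PSF blur,
#' and additive Gaussian HU noise under an explicit seed. The voxel grid
#' is offset by a small fraction of the spacing so rays never graze mesh
#' edges exactly.
#'
#' @param m a watertight `rt_mesh`.
#' @param spacing_mm voxel spacing (x, y, z); default `c(0.5, 0.5, 0.625)`
#'   (0.625 mm is the study's scanner slice spacing).
#' @param material_hu,background_hu HU assigned inside/outside (defaults
#'   130.1 and -1000: printed PLA in air).
#' @param noise_sd_hu additive Gaussian noise sd (default 0).
#' @param psf_sigma_mm isotropic Gaussian blur sd (default 0).
#' @param supersample integer subvoxel factor per axis for partial-volume
#'   fractions (default 1 = binary voxels).
#' @param margin_mm padding of air around the mesh bounding box (default
#'   5 mm).
#' @param seed integer seed, required when `noise_sd_hu > 0`.
#' @return a `ct_volume`.
#' @export
voxelize_ct <- function(m, spacing_mm = c(0.5, 0.5, 0.625),
                        material_hu = 130.1, background_hu = -1000,
                        noise_sd_hu = 0, psf_sigma_mm = 0,
                        supersample = 1L, margin_mm = 5, seed = NULL) {
  stopifnot(inherits(m, "rt_mesh"))
  if (noise_sd_hu > 0 && is.null(seed))
    stop("an explicit seed is required for a noisy CT simulation")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  f <- as.integer(supersample)
  if (f < 1L) stop("supersample must be >= 1")
  bb <- mesh_bbox(m)
  # grid offset: jitter by an irrational-ish fraction of a voxel so voxel
  # centres never coincide with mesh vertices/edges
  jit <- spacing_mm * 2.4e-4
  lo <- bb[1L, ] - margin_mm + jit
  n <- pmax(2L, as.integer(ceiling((bb[2L, ] - lo + margin_mm) / spacing_mm)))
  fine <- spacing_mm / f
  xs <- lo[1L] + fine[1L] / 2 + (seq_len(n[1L] * f) - 1L) * fine[1L]
  ys <- lo[2L] + fine[2L] / 2 + (seq_len(n[2L] * f) - 1L) * fine[2L]
  zs <- lo[3L] + fine[3L] / 2 + (seq_len(n[3L] * f) - 1L) * fine[3L]
  mask <- classify_columns(m, xs, ys, zs)
  occ <- if (f == 1L) mask * 1 else block_mean3(mask * 1, f)
  hu <- background_hu + occ * (material_hu - background_hu)
  if (psf_sigma_mm > 0) hu <- gaussian_blur3(hu, psf_sigma_mm / spacing_mm)
  if (noise_sd_hu > 0)
    hu <- hu + with_seed(seed, array(stats::rnorm(length(hu), 0, noise_sd_hu), dim(hu)))
  ct_volume(hu, spacing_mm,
            origin_mm = c(lo[1L], lo[2L], lo[3L]) + spacing_mm / 2)
}

# vertical-ray parity classification of grid points against a mesh
classify_columns <- function(m, xs, ys, zs) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  v <- m$vertices; fct <- m$facets
  A <- v[fct[, 1L], , drop = FALSE]
  B <- v[fct[, 2L], , drop = FALSE]
  C <- v[fct[, 3L], , drop = FALSE]
  det <- (B[, 1L] - A[, 1L]) * (C[, 2L] - A[, 2L]) -
         (B[, 2L] - A[, 2L]) * (C[, 1L] - A[, 1L])
  ids <- vector("list", nrow(fct))
  zhit <- vector("list", nrow(fct))
  dx <- xs[2L] - xs[1L]; dy <- ys[2L] - ys[1L]
  for (t in seq_len(nrow(fct))) {
    if (abs(det[t]) < 1e-12) next                   # vertical facet: no projected area
    xr <- range(A[t, 1L], B[t, 1L], C[t, 1L])
    yr <- range(A[t, 2L], B[t, 2L], C[t, 2L])
    i0 <- max(1L, ceiling((xr[1L] - xs[1L]) / dx) + 1L)
    i1 <- min(nx, floor((xr[2L] - xs[1L]) / dx) + 1L)
    j0 <- max(1L, ceiling((yr[1L] - ys[1L]) / dy) + 1L)
    j1 <- min(ny, floor((yr[2L] - ys[1L]) / dy) + 1L)
    if (i0 > i1 || j0 > j1) next
    px <- rep(xs[i0:i1], times = j1 - j0 + 1L)
    py <- rep(ys[j0:j1], each = i1 - i0 + 1L)
    w1 <- ((B[t, 1L] - A[t, 1L]) * (py - A[t, 2L]) -
           (B[t, 2L] - A[t, 2L]) * (px - A[t, 1L])) / det[t]
    w2 <- ((A[t, 1L] - C[t, 1L]) * (py - C[t, 2L]) -
           (A[t, 2L] - C[t, 2L]) * (px - C[t, 1L])) / det[t]
    inside <- w1 >= 0 & w2 >= 0 & (w1 + w2) <= 1
    if (!any(inside)) next
    w1 <- w1[inside]; w2 <- w2[inside]
    zt <- C[t, 3L] * w1 + B[t, 3L] * w2 + A[t, 3L] * (1 - w1 - w2)
    ii <- rep(i0:i1, times = j1 - j0 + 1L)[inside]
    jj <- rep(j0:j1, each = i1 - i0 + 1L)[inside]
    ids[[t]] <- (jj - 1L) * nx + ii
    zhit[[t]] <- zt
  }
  colid <- unlist(ids, use.names = FALSE)
  zval <- unlist(zhit, use.names = FALSE)
  mask <- array(FALSE, c(nx, ny, nz))
  if (!length(colid)) return(mask)
  byc <- split(zval, colid)
  for (nm in names(byc)) {
    z <- sort(byc[[nm]])
    if (length(z) %% 2L == 1L) z <- z[-length(z)]   # grazing artefact: drop
    if (!length(z)) next
    cid <- as.integer(nm)
    i <- (cid - 1L) %% nx + 1L
    j <- (cid - 1L) %/% nx + 1L
    for (p in seq(1L, length(z), by = 2L)) {
      k <- findInterval(c(z[p], z[p + 1L]), zs)
      if (k[2L] > k[1L]) mask[i, j, (k[1L] + 1L):k[2L]] <- TRUE
    }
  }
  mask
}

# z values where the vertical line through (x, y) crosses mesh facets
column_intersections <- function(m, x, y) {
  v <- m$vertices; fct <- m$facets
  A <- v[fct[, 1L], , drop = FALSE]
  B <- v[fct[, 2L], , drop = FALSE]
  C <- v[fct[, 3L], , drop = FALSE]
  det <- (B[, 1L] - A[, 1L]) * (C[, 2L] - A[, 2L]) -
         (B[, 2L] - A[, 2L]) * (C[, 1L] - A[, 1L])
  ok <- abs(det) > 1e-12
  w1 <- ((B[, 1L] - A[, 1L]) * (y - A[, 2L]) - (B[, 2L] - A[, 2L]) * (x - A[, 1L])) / det
  w2 <- ((A[, 1L] - C[, 1L]) * (y - C[, 2L]) - (A[, 2L] - C[, 2L]) * (x - C[, 1L])) / det
  hit <- ok & w1 >= 0 & w2 >= 0 & (w1 + w2) <= 1
  sort((C[, 3L] * w1 + B[, 3L] * w2 + A[, 3L] * (1 - w1 - w2))[hit])
}

# mean over f x f x f blocks
block_mean3 <- function(a, f) {
  d <- dim(a) / f
  a <- array(a, c(f, d[1L], f * d[2L] * f * d[3L]))
  a <- colSums(a)                                   # -> (d1, f*d2*f*d3)
  a <- array(a, c(d[1L], f, d[2L] * f * d[3L]))
  a <- aperm(a, c(2L, 1L, 3L))
  a <- colSums(array(a, c(f, d[1L] * d[2L] * f * d[3L])))
  a <- array(a, c(d[1L], d[2L], f, d[3L]))
  a <- aperm(a, c(3L, 1L, 2L, 4L))
  a <- colSums(array(a, c(f, d[1L] * d[2L] * d[3L])))
  array(a / f^3, d)
}

# separable Gaussian blur; sigma in voxels per axis; border-renormalised
gaussian_blur3 <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2)); k <- k / sum(k)
    n <- d[ax]
    Kb <- Matrix::bandSparse(n, n, k = -r:r,
                             diagonals = lapply(seq_along(k), function(i)
                               rep(k[i], n - abs(i - r - 1L))))
    Kb <- Kb / Matrix::rowSums(Kb)                  # renormalise at borders
    perm <- switch(ax, `1` = 1:3, `2` = c(2L, 1L, 3L), `3` = c(3L, 2L, 1L))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    ap <- array(as.numeric(Kb %*% matrix(ap, dp[1L])), dp)
    a <- aperm(ap, order(perm))
  }
  a
}

#' Write a set of fixtures as DICOM files and curve CSVs
#'
#' Dispatches on object class: contour stacks into one RT Structure Set
#' (`rtstruct.dcm`, ROI per name), compensators into one RT Ion Plan
#' (`ionplan.dcm`, beam per name), each CT volume into a slice-series
#' subdirectory, and depth-dose curves into CSV files. A `manifest.json`
#' records what was written.
#'
#' @param objects named list of `rt_contour_stack`, `rt_compensator`,
#'   `ct_volume` and/or `depth_dose` objects.
#' @param dir output directory (created).
#' @param uid_seed integer mixed into generated DICOM UIDs.
#' @return invisibly, the manifest as a list.
#' @export
write_fixture_dicoms <- function(objects, dir, uid_seed = 1L) {
  stopifnot(is.list(objects), !is.null(names(objects)), all(nzchar(names(objects))))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cls <- vapply(objects, function(o) class(o)[1L], "")
  manifest <- list(uid_seed = uid_seed, files = list())
  stacks <- objects[cls == "rt_contour_stack"]
  if (length(stacks)) {
    p <- file.path(dir, "rtstruct.dcm")
    write_rtstruct(stacks, p, uid_seed = uid_seed)
    manifest$files$rtstruct <- list(path = "rtstruct.dcm", rois = names(stacks))
  }
  comps <- objects[cls == "rt_compensator"]
  if (length(comps)) {
    p <- file.path(dir, "ionplan.dcm")
    beams <- lapply(names(comps), function(nm)
      list(name = nm, compensator = comps[[nm]]))
    write_ion_plan(beams, p, uid_seed = uid_seed)
    manifest$files$ionplan <- list(path = "ionplan.dcm", beams = names(comps))
  }
  for (nm in names(objects)[cls == "ct_volume"]) {
    sub <- file.path(dir, paste0("ct_", nm))
    write_ct_series(objects[[nm]], sub, uid_seed = uid_seed)
    manifest$files[[paste0("ct_", nm)]] <- list(path = paste0("ct_", nm),
                                                slices = dim(objects[[nm]]$hu)[3L])
  }
  for (nm in names(objects)[cls == "depth_dose"]) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write_depth_dose(objects[[nm]], p)
    manifest$files[[nm]] <- list(path = paste0(nm, ".csv"))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
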