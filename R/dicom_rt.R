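# DICOM-RT readers (structure set, ion plan, CT series) and the
# corresponding fixture writers used by the synthetic module.

SOP_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
SOP_ION_PLAN <- "1.2.840.10008.5.1.4.1.1.481.8"
SOP_CT_IMAGE <- "1.2.840.10008.5.1.4.1.1.2"

#' Read a bolus contour stack from a DICOM RT Structure Set
#'
#' Extracts the closed planar contours of the named ROI and returns them as
#' a contour stack in patient mm coordinates, sorted by z. A closing point
#' duplicated in the file is dropped on read.
#'
#' @param path RT Structure Set file.
#' @param roi_name name of the ROI holding the bolus design.
#' @return an `rt_contour_stack`.
#' @export
read_rtstruct <- function(path, roi_name) {
  el <- read_dicom_file(path)
  if (!identical(el[["0008,0016"]], SOP_RTSTRUCT))
    stop("not an RT Structure Set: ", path)
  rois <- el[["3006,0020"]]
  names_av <- vapply(rois, function(r) r[["3006,0026"]][1L], "")
  numbers <- vapply(rois, function(r) r[["3006,0022"]][1L], 0L)
  hit <- which(names_av == roi_name)
  if (!length(hit))
    stop(sprintf("ROI '%s' not found; available ROIs: %s", roi_name,
                 paste(sprintf("'%s'", names_av), collapse = ", ")))
  want <- numbers[hit[1L]]
  rcs <- el[["3006,0039"]]
  item <- Filter(function(r) identical(r[["3006,0084"]][1L], want), rcs)
  if (!length(item)) stop("ROI has no contour data: ", roi_name)
  contours <- lapply(item[[1L]][["3006,0040"]], function(ci) {
    gt <- ci[["3006,0042"]]
    if (!is.null(gt) && !identical(gt[1L], "CLOSED_PLANAR"))
      stop("unsupported contour geometric type: ", gt[1L])
    xyz <- matrix(ci[["3006,0050"]], ncol = 3L, byrow = TRUE)
    if (diff(range(xyz[, 3L])) > 1e-6)
      stop(sprintf("non-planar contour data (z spans %g mm)", diff(range(xyz[, 3L]))))
    contour(xyz[, 1:2, drop = FALSE], xyz[1L, 3L])
  })
  contour_stack(contours)
}

#' Read a compensator grid from a DICOM RT Ion Plan
#'
#' Pulls the range-compensator thickness matrix of one beam from the
#' standard ion range compensator sequence (row-major thickness data,
#' pixel spacing and position attributes).
#'
#' @param path RT Ion Plan file.
#' @param beam_index 1-based index into the ion beam sequence.
#' @return an `rt_compensator`.
#' @export
read_ion_plan_compensator <- function(path, beam_index = 1L) {
  el <- read_dicom_file(path)
  if (!identical(el[["0008,0016"]], SOP_ION_PLAN))
    stop("not an RT Ion Plan: ", path)
  beams <- el[["300A,03A2"]]
  if (beam_index < 1L || beam_index > length(beams))
    stop(sprintf("beam_index %d out of range (plan has %d beam(s))",
                 beam_index, length(beams)))
  beam <- beams[[beam_index]]
  comp <- beam[["300A,02EA"]]
  if (is.null(comp) || !length(comp))
    stop(sprintf("beam %d has no range compensator", beam_index))
  c1 <- comp[[1L]]
  nr <- c1[["300A,00E7"]][1L]
  nc <- c1[["300A,00E8"]][1L]
  spacing <- c1[["300A,00E9"]]
  pos <- c1[["300A,00EA"]]
  th <- c1[["300A,00EC"]]
  if (length(th) != nr * nc)
    stop("compensator thickness data length does not match rows x columns")
  thickness <- matrix(th, nrow = nr, ncol = nc, byrow = TRUE)
  compensator_grid(thickness, pixel_spacing_mm = spacing, origin_mm = pos)
}

#' Read a CT series from a directory of slice files
#'
#' Reads every DICOM file in the directory, verifies a single series,
#' applies the rescale slope/intercept, sorts slices by patient z and
#' verifies uniform slice spacing. The result does not depend on file
#' listing order.
#'
#' @param dir directory containing one CT series.
#' @param spacing_tol_mm allowed deviation from uniform z spacing
#'   (default 1e-3 mm).
#' @return a `ct_volume`.
#' @export
read_ct_series <- function(dir, spacing_tol_mm = 1e-3) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) stop("no .dcm files in ", dir)
  slices <- lapply(files, read_dicom_file)
  series <- vapply(slices, function(s) s[["0020,000E"]][1L], "")
  if (length(unique(series)) != 1L)
    stop(sprintf("mixed series UIDs in %s: %s", dir,
                 paste(unique(series), collapse = ", ")))
  z <- vapply(slices, function(s) s[["0020,0032"]][3L], 0)
  o <- order(z)
  slices <- slices[o]; z <- z[o]
  if (length(z) < 2L) stop("CT series needs at least 2 slices")
  dz <- diff(z)
  if (diff(range(dz)) > spacing_tol_mm)
    stop(sprintf("non-uniform slice spacing: gaps range %.4f-%.4f mm",
                 min(dz), max(dz)))
  s1 <- slices[[1L]]
  nrow_px <- s1[["0028,0010"]][1L]
  ncol_px <- s1[["0028,0011"]][1L]
  ps <- s1[["0028,0030"]]                            # (row, col) = (dy, dx)
  hu <- array(0, dim = c(ncol_px, nrow_px, length(z)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    slope <- if (is.null(s[["0028,1053"]])) 1 else s[["0028,1053"]][1L]
    inter <- if (is.null(s[["0028,1052"]])) 0 else s[["0028,1052"]][1L]
    px <- s[["7FE0,0010"]]
    if (length(px) != nrow_px * ncol_px)
      stop("pixel data length mismatch in slice ", k)
    hu[, , k] <- matrix(px, nrow = ncol_px) * slope + inter
  }
  ct_volume(hu, spacing_mm = c(ps[2L], ps[1L], dz[1L]),
            origin_mm = s1[["0020,0032"]])
}

# fixture writers -----------------------------------------------------------

#' Write a contour stack as a DICOM RT Structure Set fixture
#'
#' Emits a minimal, standard-conformant structure set readable by
#' [read_rtstruct()] (and by pydicom); used by the synthetic module.
#'
#' @param stacks named list of `rt_contour_stack` objects; names become ROI
#'   names.
#' @param path output file.
#' @param uid_seed integer mixed into the generated instance UIDs so reruns
#'   are byte-identical.
#' @param duplicate_closing_point if `TRUE`, repeat the first point at the
#'   end of each contour (a dialect some planning systems emit; the reader
#'   normalises it away).
#' @return invisibly, `path`.
#' @export
write_rtstruct <- function(stacks, path, uid_seed = 1L,
                           duplicate_closing_point = FALSE) {
  stopifnot(is.list(stacks), !is.null(names(stacks)), all(nzchar(names(stacks))))
  sop_uid <- rtprint_uid(3, uid_seed, 1)
  ssroi <- lapply(seq_along(stacks), function(i)
    dcm_item(c(dcm_el(0x3006, 0x0022, "IS", i),
               dcm_el(0x3006, 0x0026, "LO", names(stacks)[i]))))
  rcs <- lapply(seq_along(stacks), function(i) {
    cs <- lapply(stacks[[i]]$contours, function(cn) {
      p <- cn$points
      if (duplicate_closing_point) p <- rbind(p, p[1L, ])
      xyz <- cbind(p, cn$z_mm)
      dcm_item(c(dcm_el(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
                 dcm_el(0x3006, 0x0046, "IS", nrow(p)),
                 dcm_el(0x3006, 0x0050, "DS", as.vector(t(xyz)))))
    })
    dcm_item(c(dcm_sq(0x3006, 0x0040, cs),
               dcm_el(0x3006, 0x0084, "IS", i)))
  })
  ds <- c(
    dcm_el(0x0008, 0x0016, "UI", SOP_RTSTRUCT),
    dcm_el(0x0008, 0x0018, "UI", sop_uid),
    dcm_el(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_el(0x0010, 0x0010, "PN", "rtprint^fixture"),
    dcm_el(0x0010, 0x0020, "LO", "RTPRINT"),
    dcm_el(0x0020, 0x000D, "UI", rtprint_uid(1, uid_seed)),
    dcm_el(0x0020, 0x000E, "UI", rtprint_uid(2, uid_seed, 1)),
    dcm_el(0x3006, 0x0002, "SH", "rtprint"),
    dcm_sq(0x3006, 0x0020, ssroi),
    dcm_sq(0x3006, 0x0039, rcs)
  )
  write_dicom_file(path, SOP_RTSTRUCT, sop_uid, ds)
}

#' Write compensator grids as a DICOM RT Ion Plan fixture
#'
#' @param beams list of beams; each beam is a list with `name` and an
#'   optional `compensator` (`rt_compensator`, or `NULL` for a beam without
#'   one).
#' @param path output file.
#' @param uid_seed integer mixed into the generated instance UIDs.
#' @return invisibly, `path`.
#' @export
write_ion_plan <- function(beams, path, uid_seed = 1L) {
  sop_uid <- rtprint_uid(8, uid_seed, 1)
  ibs <- lapply(seq_along(beams), function(i) {
    b <- beams[[i]]
    body <- c(dcm_el(0x300A, 0x00C0, "IS", i),
              dcm_el(0x300A, 0x00C2, "LO", b$name %||% sprintf("beam%d", i)))
    if (!is.null(b$compensator)) {
      g <- b$compensator
      comp <- dcm_item(c(
        dcm_el(0x300A, 0x00E7, "IS", g$n_rows),
        dcm_el(0x300A, 0x00E8, "IS", g$n_cols),
        dcm_el(0x300A, 0x00E9, "DS", g$pixel_spacing_mm),
        dcm_el(0x300A, 0x00EA, "DS", g$origin_mm),
        dcm_el(0x300A, 0x00EC, "DS", as.vector(t(g$thickness_mm)))
      ))
      body <- c(body, dcm_sq(0x300A, 0x02EA, list(comp)))
    }
    dcm_item(body)
  })
  ds <- c(
    dcm_el(0x0008, 0x0016, "UI", SOP_ION_PLAN),
    dcm_el(0x0008, 0x0018, "UI", sop_uid),
    dcm_el(0x0008, 0x0060, "CS", "RTPLAN"),
    dcm_el(0x0010, 0x0010, "PN", "rtprint^fixture"),
    dcm_el(0x0010, 0x0020, "LO", "RTPRINT"),
    dcm_el(0x0020, 0x000D, "UI", rtprint_uid(1, uid_seed)),
    dcm_el(0x0020, 0x000E, "UI", rtprint_uid(2, uid_seed, 8)),
    dcm_el(0x300A, 0x0002, "SH", "rtprint"),
    dcm_sq(0x300A, 0x03A2, ibs)
  )
  write_dicom_file(path, SOP_ION_PLAN, sop_uid, ds)
}

#' Write a CT volume as a DICOM slice series fixture
#'
#' HU values are stored as signed 16-bit pixels with rescale slope 1 and
#' intercept 0, i.e. quantised to whole HU (scanner exports are integral
#' HU; sub-HU structure in a simulated volume is rounded).
#'
#' @param v a `ct_volume`.
#' @param dir output directory (created if needed); one `.dcm` file per
#'   slice.
#' @param uid_seed integer mixed into the generated UIDs.
#' @return invisibly, the vector of file paths.
#' @export
write_ct_series <- function(v, dir, uid_seed = 1L) {
  stopifnot(inherits(v, "ct_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(v$hu)
  series_uid <- rtprint_uid(2, uid_seed, 2)
  paths <- character(d[3L])
  for (k in seq_len(d[3L])) {
    sop_uid <- rtprint_uid(4, uid_seed, k)
    px <- as.integer(round(pmin(pmax(v$hu[, , k], -32768), 32767)))
    ds <- c(
      dcm_el(0x0008, 0x0016, "UI", SOP_CT_IMAGE),
      dcm_el(0x0008, 0x0018, "UI", sop_uid),
      dcm_el(0x0008, 0x0060, "CS", "CT"),
      dcm_el(0x0010, 0x0010, "PN", "rtprint^fixture"),
      dcm_el(0x0010, 0x0020, "LO", "RTPRINT"),
      dcm_el(0x0020, 0x000D, "UI", rtprint_uid(1, uid_seed)),
      dcm_el(0x0020, 0x000E, "UI", series_uid),
      dcm_el(0x0020, 0x0013, "IS", k),
      dcm_el(0x0020, 0x0032, "DS", c(v$origin_mm[1:2],
                                     v$origin_mm[3L] + (k - 1L) * v$spacing_mm[3L])),
      dcm_el(0x0020, 0x0037, "DS", c(1, 0, 0, 0, 1, 0)),
      dcm_el(0x0028, 0x0002, "US", 1L),
      dcm_el(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_el(0x0028, 0x0010, "US", d[2L]),          # rows = y
      dcm_el(0x0028, 0x0011, "US", d[1L]),          # columns = x
      dcm_el(0x0028, 0x0030, "DS", c(v$spacing_mm[2L], v$spacing_mm[1L])),
      dcm_el(0x0028, 0x0100, "US", 16L),
      dcm_el(0x0028, 0x0101, "US", 16L),
      dcm_el(0x0028, 0x0102, "US", 15L),
      dcm_el(0x0028, 0x0103, "US", 1L),             # signed pixels
      dcm_el(0x0028, 0x1052, "DS", 0),
      dcm_el(0x0028, 0x1053, "DS", 1),
      dcm_el(0x7FE0, 0x0010, "OW", px)              # column-major == row-major over (x fast)
    )
    paths[k] <- file.path(dir, sprintf("ct_%04d.dcm", k))
    write_dicom_file(paths[k], SOP_CT_IMAGE, sop_uid, ds)
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
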