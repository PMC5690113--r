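# Minimal DICOM (explicit VR little endian) encoder/decoder.
#
# Scoped to the elements the pipeline touches: RT Structure Set contours,
# RT Ion Plan range-compensator grids, and CT image slices. No installed R
# package reads DICOM, so the byte layer is implemented here: tag (2 x
# uint16), 2-char VR, 16-bit length (or 2 reserved bytes + 32-bit length
# for OB/OW/OF/SQ/UT/UN), little endian throughout, values padded to even
# length. Sequences use defined lengths on write; defined and undefined
# lengths are accepted on read.

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

pad_even <- function(r, pad = as.raw(0L)) if (length(r) %% 2L) c(r, pad) else r

dcm_raw_element <- function(group, element, vr, payload) {
  if (length(payload) > 65534L && !(vr %in% LONG_VRS))
    stop(sprintf("DICOM element (%04X,%04X) %s value of %d bytes exceeds the 16-bit length field",
                 group, element, vr, length(payload)))
  head <- c(u16(group), u16(element), charToRaw(vr))
  if (vr %in% LONG_VRS) c(head, raw(2L), u32(length(payload)), payload)
  else c(head, u16(length(payload)), payload)
}

# value encoders -----------------------------------------------------------

enc_str <- function(group, element, vr, s, pad = as.raw(0x20))
  dcm_raw_element(group, element, vr, pad_even(charToRaw(s), pad))

dcm_el <- function(group, element, vr, value) {
  switch(vr,
    UI = enc_str(group, element, vr, as.character(value)[1L], as.raw(0L)),
    DS = enc_str(group, element, vr,
                 paste(vapply(as.numeric(value), format_ds, ""), collapse = "\\")),
    IS = enc_str(group, element, vr, paste(as.integer(value), collapse = "\\")),
    LO = ,
    SH = ,
    CS = ,
    PN = ,
    DA = ,
    TM = enc_str(group, element, vr, paste(as.character(value), collapse = "\\")),
    US = dcm_raw_element(group, element, vr, u16(value)),
    UL = dcm_raw_element(group, element, vr, u32(value)),
    OB = dcm_raw_element(group, element, vr, pad_even(as.raw(value))),
    OW = dcm_raw_element(group, element, vr,
                         writeBin(as.integer(value), raw(), size = 2L, endian = "little")),
    SQ = dcm_raw_element(group, element, vr, value),  # pre-encoded items
    stop("unsupported VR: ", vr)
  )
}

# decimal-string formatter: <= 16 bytes per DICOM, shortest faithful form
format_ds <- function(x) {
  s <- sprintf("%.9g", x)
  if (nchar(s) > 16L) s <- sprintf("%.8g", x)
  if (nchar(s) > 16L) s <- sprintf("%.6g", x)
  s
}

dcm_item <- function(dataset_raw)
  c(u16(0xFFFE), u16(0xE000), u32(length(dataset_raw)), dataset_raw)

dcm_sq <- function(group, element, items_raw)
  dcm_el(group, element, "SQ", do.call(c, c(items_raw, list(raw(0)))))

# file writer ---------------------------------------------------------------

TRANSFER_SYNTAX_ELE <- "1.2.840.10008.1.2.1"
RTPRINT_UID_ROOT <- "1.2.826.0.1.3680043.10.1157"  # synthetic fixture UID root

rtprint_uid <- function(...) paste(RTPRINT_UID_ROOT, ..., sep = ".")

write_dicom_file <- function(path, sop_class_uid, sop_instance_uid, dataset_raw) {
  meta <- c(
    dcm_el(0x0002, 0x0001, "OB", c(0L, 1L)),
    dcm_el(0x0002, 0x0002, "UI", sop_class_uid),
    dcm_el(0x0002, 0x0003, "UI", sop_instance_uid),
    dcm_el(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_ELE),
    dcm_el(0x0002, 0x0012, "UI", rtprint_uid("0"))
  )
  meta <- c(dcm_el(0x0002, 0x0000, "UL", length(meta)), meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta, con)
  writeBin(dataset_raw, con)
  invisible(path)
}

# file reader ---------------------------------------------------------------

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file: ", path)
  meta <- parse_dataset(raw, 133L, length(raw), stop_after_group2 = TRUE)
  ts <- meta$elements[["0002,0010"]]
  if (is.null(ts) || ts != TRANSFER_SYNTAX_ELE)
    stop("unsupported DICOM transfer syntax (only explicit VR little endian is read)")
  ds <- parse_dataset(raw, meta$pos, length(raw))
  ds$elements
}

rd_u16 <- function(raw, pos)
  readBin(raw[pos:(pos + 1L)], "integer", 1L, size = 2L, signed = FALSE, endian = "little")
rd_u32 <- function(raw, pos) {
  v <- readBin(raw[pos:(pos + 3L)], "integer", 1L, size = 4L, endian = "little")
  if (v < 0) v + 2^32 else as.numeric(v)
}

parse_dataset <- function(raw, pos, end, stop_after_group2 = FALSE) {
  out <- list()
  while (pos <= end - 7L) {
    group <- rd_u16(raw, pos)
    element <- rd_u16(raw, pos + 2L)
    if (stop_after_group2 && group != 0x0002) break
    if (group == 0xFFFE) break  # item/sequence delimiter at this level
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit VR or corrupt element encountered; only explicit VR little endian is read")
    if (vr %in% LONG_VRS) {
      len <- rd_u32(raw, pos + 8L)
      vpos <- pos + 12L
    } else {
      len <- rd_u16(raw, pos + 6L)
      vpos <- pos + 8L
    }
    key <- sprintf("%04X,%04X", group, element)
    if (vr == "SQ") {
      sq <- parse_sequence(raw, vpos, len)
      out[[key]] <- sq$items
      pos <- sq$pos
    } else {
      if (len == 4294967295) stop("undefined length on non-SQ element")
      val_raw <- if (len > 0) raw[vpos:(vpos + len - 1L)] else raw(0L)
      out[[key]] <- decode_value(vr, val_raw)
      pos <- vpos + len
    }
  }
  list(elements = out, pos = pos)
}

parse_sequence <- function(raw, pos, len) {
  undefined <- len == 4294967295
  end <- if (undefined) length(raw) else pos + len - 1L
  items <- list()
  while (pos <= end - 7L) {
    g <- rd_u16(raw, pos); e <- rd_u16(raw, pos + 2L)
    ilen <- rd_u32(raw, pos + 4L)
    pos <- pos + 8L
    if (g == 0xFFFE && e == 0xE0DD) break           # sequence delimiter
    if (!(g == 0xFFFE && e == 0xE000))
      stop("malformed sequence: expected item tag")
    if (ilen == 4294967295) {                        # undefined-length item
      ds <- parse_dataset(raw, pos, end)
      items[[length(items) + 1L]] <- ds$elements
      pos <- ds$pos
      g2 <- rd_u16(raw, pos); e2 <- rd_u16(raw, pos + 2L)
      if (g2 == 0xFFFE && e2 == 0xE00D) pos <- pos + 8L
    } else {
      ds <- parse_dataset(raw, pos, pos + ilen - 1L)
      items[[length(items) + 1L]] <- ds$elements
      pos <- pos + ilen
    }
  }
  list(items = items, pos = pos)
}

decode_value <- function(vr, val_raw) {
  switch(vr,
    UI = rawToChar(val_raw[val_raw != as.raw(0L)]),
    DS = as.numeric(strsplit(trimws(rawToChar(val_raw)), "\\\\")[[1L]]),
    IS = as.integer(strsplit(trimws(rawToChar(val_raw)), "\\\\")[[1L]]),
    LO = ,
    SH = ,
    CS = ,
    PN = ,
    DA = ,
    TM = strsplit(trimws(rawToChar(val_raw)), "\\\\")[[1L]],
    US = readBin(val_raw, "integer", length(val_raw) / 2L, size = 2L,
                 signed = FALSE, endian = "little"),
    UL = readBin(val_raw, "integer", length(val_raw) / 4L, size = 4L,
                 endian = "little"),
    OW = readBin(val_raw, "integer", length(val_raw) / 2L, size = 2L,
                 signed = TRUE, endian = "little"),
    OB = val_raw,
    val_raw
  )
}
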