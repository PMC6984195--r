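# Minimal DICOM writer used only to build read-oracle fixtures at test time
# (the package itself never writes DICOM). Explicit VR little endian with a
# standard 128-byte preamble and file meta group.

dcm_raw_u16 <- function(x) writeBin(as.integer(x), raw(), 2, endian = "little")
dcm_raw_u32 <- function(x) writeBin(as.integer(x), raw(), 4, endian = "little")

dcm_el <- function(group, elem, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    if (length(value) %% 2 == 1) value <- c(value, charToRaw(" "))
  }
  hdr <- c(dcm_raw_u16(group), dcm_raw_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(hdr, raw(2), dcm_raw_u32(length(value)), value)
  else
    c(hdr, dcm_raw_u16(length(value)), value)
}

# slice: numeric matrix indexed [x, y]; position: ImagePositionPatient (mm);
# spacing_xy: (x, y) spacing in mm.
write_dicom_slice <- function(path, slice, position, spacing_xy,
                              slope = 1, intercept = 0) {
  cols <- nrow(slice)   # x
  rows <- ncol(slice)   # y
  # DICOM pixel order is row 0 first, x fastest -- i.e. index x + cols*y,
  # which is exactly column-major order of the [x, y] matrix.
  pix <- as.integer(round((slice - intercept) / slope))
  stopifnot(all(pix >= -32768 & pix <= 32767))
  body <- c(
    dcm_el(0x0008, 0x0060, "CS", "CT"),
    dcm_el(0x0020, 0x0032, "DS", sprintf("%g\\%g\\%g", position[1],
                                         position[2], position[3])),
    dcm_el(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
    dcm_el(0x0028, 0x0002, "US", dcm_raw_u16(1)),
    dcm_el(0x0028, 0x0010, "US", dcm_raw_u16(rows)),
    dcm_el(0x0028, 0x0011, "US", dcm_raw_u16(cols)),
    dcm_el(0x0028, 0x0030, "DS", sprintf("%g\\%g", spacing_xy[2], spacing_xy[1])),
    dcm_el(0x0028, 0x0100, "US", dcm_raw_u16(16)),
    dcm_el(0x0028, 0x0101, "US", dcm_raw_u16(16)),
    dcm_el(0x0028, 0x0102, "US", dcm_raw_u16(15)),
    dcm_el(0x0028, 0x0103, "US", dcm_raw_u16(1)),
    dcm_el(0x0028, 0x1052, "DS", sprintf("%g", intercept)),
    dcm_el(0x0028, 0x1053, "DS", sprintf("%g", slope)),
    dcm_el(0x7fe0, 0x0010, "OW", writeBin(pix, raw(), 2, endian = "little"))
  )
  ts <- dcm_el(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  meta <- c(dcm_el(0x0002, 0x0000, "UL", dcm_raw_u32(length(ts))), ts)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# Write a volume as a DICOM series, one file per slice, optionally with
# file names deliberately out of z order.
write_dicom_series <- function(vol, dir, scramble_names = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- vol$dims[3]
  ord <- if (scramble_names) rev(seq_len(nz)) else seq_len(nz)
  for (idx in seq_len(nz)) {
    k <- ord[idx]
    pos <- vol$origin + c(0, 0, (k - 1) * vol$spacing[3])
    write_dicom_slice(file.path(dir, sprintf("slice%03d.dcm", idx)),
                      vol$data[, , k], pos, vol$spacing[1:2])
  }
  invisible(dir)
}
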