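# Minimal DICOM series reader: uncompressed little-endian transfer syntaxes
# (implicit and explicit VR), axial axis-aligned slices only. Covers the tags
# a resampled/zero-padded CT or CBCT export needs: geometry, pixel layout,
# rescale, pixel data. Sequences with undefined length are not supported.

dcm_u16 <- function(r, off) readBin(r[off + 1:2], "integer", 1, 2,
                                    signed = FALSE, endian = "little")
dcm_u32 <- function(r, off) {
  b <- as.numeric(as.integer(r[off + 1:4]))
  b[1] + 256 * (b[2] + 256 * (b[3] + 256 * b[4]))
}

DCM_EXPLICIT_LONG_VR <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse one element at offset `off` (0-based); returns list(tag, value raw,
# next offset). `explicit` selects VR encoding.
dcm_element <- function(r, off, explicit) {
  if (off + 8 > length(r)) return(NULL)
  group <- dcm_u16(r, off)
  elem <- dcm_u16(r, off + 2)
  if (explicit) {
    vr <- rawToChar(r[off + 5:6])
    if (vr %in% DCM_EXPLICIT_LONG_VR) {
      len <- dcm_u32(r, off + 8)
      hdr <- 12
    } else {
      len <- dcm_u16(r, off + 6)
      hdr <- 8
    }
  } else {
    vr <- NA_character_
    len <- dcm_u32(r, off + 4)
    hdr <- 8
  }
  if (len == 4294967295)
    stop("DICOM: undefined-length element not supported")
  if (off + hdr + len > length(r))
    stop(sprintf("DICOM: element (%04x,%04x) overruns file", group, elem))
  list(group = group, elem = elem, vr = vr,
       value = r[off + hdr + seq_len(len)], nxt = off + hdr + len)
}

dcm_str <- function(v) trimws(rawToChar(v[v != as.raw(0)]))
dcm_ds <- function(v) as.numeric(strsplit(dcm_str(v), "\\\\")[[1]])

read_dicom_file <- function(path) {
  r <- readBin(path, "raw", file.size(path))
  off <- 0
  explicit <- TRUE
  ts <- "1.2.840.10008.1.2.1"
  if (length(r) > 132 && rawToChar(r[129:132]) == "DICM") {
    off <- 132
    # File meta group (0002,xxxx) is always explicit little-endian.
    repeat {
      el <- dcm_element(r, off, TRUE)
      if (is.null(el) || el$group != 2L) break
      if (el$elem == 16L) ts <- dcm_str(el$value)
      off <- el$nxt
    }
  }
  explicit <- switch(ts,
    "1.2.840.10008.1.2" = FALSE,
    "1.2.840.10008.1.2.1" = TRUE,
    stop(sprintf("DICOM '%s': unsupported transfer syntax '%s'", path, ts)))
  tags <- list()
  repeat {
    el <- dcm_element(r, off, explicit)
    if (is.null(el)) break
    key <- sprintf("%04x,%04x", el$group, el$elem)
    tags[[key]] <- el
    off <- el$nxt
    if (el$group == 0x7fe0 && el$elem == 0x0010) break
  }
  need <- function(key, what) {
    if (is.null(tags[[key]]))
      stop(sprintf("DICOM '%s': missing required tag (%s) [%s]", path, key, what))
    tags[[key]]
  }
  rows <- dcm_u16(need("0028,0010", "Rows")$value, 0)
  cols <- dcm_u16(need("0028,0011", "Columns")$value, 0)
  ps <- dcm_ds(need("0028,0030", "PixelSpacing")$value)   # row spacing, col spacing
  ipp <- dcm_ds(need("0020,0032", "ImagePositionPatient")$value)
  if (!is.null(tags[["0020,0037"]])) {
    iop <- dcm_ds(tags[["0020,0037"]]$value)
    if (max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-4)
      stop(sprintf("DICOM '%s': oblique ImageOrientationPatient not supported", path))
  }
  bits <- dcm_u16(need("0028,0100", "BitsAllocated")$value, 0)
  if (bits != 16L)
    stop(sprintf("DICOM '%s': BitsAllocated = %d, only 16 supported", path, bits))
  pixrep <- if (!is.null(tags[["0028,0103"]]))
    dcm_u16(tags[["0028,0103"]]$value, 0) else 0L
  slope <- if (!is.null(tags[["0028,1053"]])) dcm_ds(tags[["0028,1053"]]$value) else 1
  inter <- if (!is.null(tags[["0028,1052"]])) dcm_ds(tags[["0028,1052"]]$value) else 0
  pd <- need("7fe0,0010", "PixelData")$value
  n <- as.integer(rows) * as.integer(cols)
  if (length(pd) < 2L * n)
    stop(sprintf("DICOM '%s': PixelData too short", path))
  pix <- readBin(pd, "integer", n, 2, signed = pixrep == 1L, endian = "little")
  # Pixel order: row 0 (all columns) first, so index = x + cols*y.
  slice <- matrix(as.numeric(pix) * slope + inter, nrow = cols, ncol = rows)
  list(slice = slice, position = ipp,
       spacing_xy = c(ps[2], ps[1]), rows = rows, cols = cols)
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    stop(sprintf("DICOM series '%s': no files found", dir))
  slices <- lapply(files, read_dicom_file)
  dims_xy <- vapply(slices, function(s) c(s$cols, s$rows), integer(2))
  if (any(dims_xy[1, ] != dims_xy[1, 1]) || any(dims_xy[2, ] != dims_xy[2, 1]))
    stop(sprintf("DICOM series '%s': inconsistent slice dimensions", dir))
  sp_xy <- vapply(slices, function(s) s$spacing_xy, numeric(2))
  if (max(abs(sp_xy - sp_xy[, 1])) > 1e-6)
    stop(sprintf("DICOM series '%s': mixed in-plane PixelSpacing", dir))
  z <- vapply(slices, function(s) s$position[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  dz <- if (length(z) > 1L) diff(z) else 1
  if (length(z) > 1L) {
    if (any(dz <= 0))
      stop(sprintf("DICOM series '%s': duplicate slice positions", dir))
    if (max(dz) - min(dz) > 1e-3)
      stop(sprintf("DICOM series '%s': mixed slice spacing (%.4f..%.4f mm)",
                   dir, min(dz), max(dz)))
  }
  nx <- slices[[1]]$cols
  ny <- slices[[1]]$rows
  nz <- length(slices)
  data <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) data[, , k] <- slices[[k]]$slice
  vs_volume(data,
            spacing = c(slices[[1]]$spacing_xy, if (nz > 1L) mean(dz) else 1),
            origin = slices[[1]]$position)
}
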