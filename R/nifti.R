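# Minimal NIfTI-1 reader/writer (.nii, .nii.gz), single-file, little-endian
# preferred, byte-swapped files detected via sizeof_hdr. Axis-aligned sform
# only; oblique orientation matrices are rejected rather than silently
# mishandled. Scalar volumes use dim[0] = 3; 3-vector deformation fields use
# dim[0] = 5, dim[5] = 3, intent code 1007 (NIFTI_INTENT_VECTOR).

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
                 float64 = 64L, uint16 = 512L)
NIFTI_BITPIX <- c(uint8 = 8L, int16 = 16L, int32 = 32L, float32 = 32L,
                  float64 = 64L, uint16 = 16L)

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1, 4, endian = endian)
  if (length(sizeof_hdr) != 1L)
    stop(sprintf("NIfTI '%s': truncated header", path))
  if (sizeof_hdr != 348L) {
    endian <- "big"
    swapped <- readBin(writeBin(sizeof_hdr, raw(), 4, endian = "little"),
                       "integer", 1, 4, endian = "big")
    if (!identical(swapped, 348L))
      stop(sprintf("NIfTI '%s': bad sizeof_hdr (expected 348)", path))
  }
  hdr <- readBin(con, "raw", 344)
  rd_i16 <- function(off, n) readBin(hdr[(off - 3):(off - 4 + 2 * n)],
                                     "integer", n, 2, endian = endian)
  rd_i32 <- function(off, n) readBin(hdr[(off - 3):(off - 4 + 4 * n)],
                                     "integer", n, 4, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr[(off - 3):(off - 4 + 4 * n)],
                                     "double", n, 4, endian = endian)
  dim_field <- rd_i16(40, 8)
  datatype <- rd_i16(70, 1)
  pixdim <- rd_f32(76, 8)
  vox_offset <- rd_f32(108, 1)
  scl_slope <- rd_f32(112, 1)
  scl_inter <- rd_f32(116, 1)
  sform_code <- rd_i16(254, 1)
  qform_code <- rd_i16(252, 1)
  srow <- matrix(rd_f32(280, 12), nrow = 3, byrow = TRUE)
  magic <- rawToChar(hdr[(345 - 4):(347 - 4)])
  if (!magic %in% c("n+1", "ni1"))
    stop(sprintf("NIfTI '%s': bad magic '%s'", path, magic))
  ndim <- dim_field[1]
  if (!ndim %in% c(3L, 5L))
    stop(sprintf("NIfTI '%s': unsupported dim[0] = %d (want 3 or 5)", path, ndim))
  dims <- dim_field[2:4]
  ncomp <- if (ndim == 5L) dim_field[6] else 1L
  if (ndim == 5L && dim_field[5] != 1L)
    stop(sprintf("NIfTI '%s': time dimension not supported (dim[4] = %d)",
                 path, dim_field[5]))
  if (any(dims < 1L))
    stop(sprintf("NIfTI '%s': non-positive dim field", path))
  dtname <- names(NIFTI_DT)[match(datatype, unlist(NIFTI_DT))]
  if (is.na(dtname))
    stop(sprintf("NIfTI '%s': unsupported datatype code %d", path, datatype))
  spacing <- abs(pixdim[2:4])
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop(sprintf("NIfTI '%s': non-positive pixdim", path))
  origin <- c(0, 0, 0)
  if (sform_code > 0L) {
    diag_s <- diag(srow[, 1:3])
    offdiag <- srow[, 1:3]; diag(offdiag) <- 0
    if (max(abs(offdiag)) > 1e-4 * max(abs(diag_s)))
      stop(sprintf("NIfTI '%s': oblique srow orientation not supported", path))
    if (any(diag_s <= 0))
      stop(sprintf("NIfTI '%s': flipped/degenerate srow axes not supported", path))
    spacing <- diag_s
    origin <- srow[, 4]
  } else if (qform_code > 0L) {
    quat <- rd_f32(256, 3)
    if (max(abs(quat)) > 1e-6)
      stop(sprintf("NIfTI '%s': oblique qform orientation not supported", path))
    origin <- rd_f32(268, 3)
  }
  seek(con, where = max(vox_offset, 352))
  n <- prod(dims) * ncomp
  what <- if (dtname %in% c("float32", "float64")) "double" else "integer"
  size <- NIFTI_BITPIX[[dtname]] / 8L
  signed <- !(dtname %in% c("uint8", "uint16"))
  vals <- readBin(con, what, n, size, signed = signed, endian = endian)
  if (length(vals) != n)
    stop(sprintf("NIfTI '%s': expected %d values, got %d", path, n, length(vals)))
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  if (ncomp == 1L)
    vs_volume(array(vals, dims), spacing, origin)
  else
    list(data = array(vals, c(dims, ncomp)), spacing = spacing,
         origin = origin, dims = dims, ncomp = ncomp)
}

# data: 3D array (scalar) or 4D array with last dim = 3 (vector field).
write_nifti <- function(data, spacing, origin, path, datatype = NULL) {
  nd <- length(dim(data))
  dims <- dim(data)[1:3]
  ncomp <- if (nd == 4L) dim(data)[4] else 1L
  vals <- as.numeric(data)
  if (is.null(datatype)) {
    intlike <- all(vals == round(vals)) && all(is.finite(vals))
    datatype <- if (intlike && min(vals) >= -32768 && max(vals) <= 32767) "int16"
                else if (intlike && min(vals) >= -2^31 && max(vals) < 2^31) "int32"
                else "float64"
  }
  if (!datatype %in% names(NIFTI_DT))
    stop(sprintf("unsupported NIfTI datatype '%s'", datatype))
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wr_i16 <- function(x) writeBin(as.integer(x), con, 2, endian = "little")
  wr_i32 <- function(x) writeBin(as.integer(x), con, 4, endian = "little")
  wr_f32 <- function(x) writeBin(as.numeric(x), con, 4, endian = "little")
  wr_pad <- function(n) writeBin(raw(n), con)
  wr_i32(348)                          # sizeof_hdr
  wr_pad(36)                           # data_type..regular, dim_info
  dim_field <- integer(8)
  dim_field[1] <- if (ncomp == 1L) 3L else 5L
  dim_field[2:4] <- dims
  dim_field[5:8] <- 1L
  if (ncomp > 1L) dim_field[6] <- ncomp
  wr_i16(dim_field)
  wr_f32(c(0, 0, 0))                   # intent_p1..p3
  wr_i16(if (ncomp > 1L) 1007L else 0L)  # intent_code (vector for fields)
  wr_i16(NIFTI_DT[[datatype]])
  wr_i16(NIFTI_BITPIX[[datatype]])
  wr_i16(0)                            # slice_start
  wr_f32(c(0, spacing, 1, 1, 1, 1))    # pixdim
  wr_f32(352)                          # vox_offset
  wr_f32(c(1, 0))                      # scl_slope, scl_inter
  wr_i16(0); wr_pad(2)                 # slice_end, slice_code, xyzt_units
  wr_f32(c(0, 0, 0, 0))                # cal_max..toffset
  wr_i32(c(0, 0))                      # glmax, glmin
  wr_pad(104)                          # descrip, aux_file
  wr_i16(c(0, 1))                      # qform_code = 0, sform_code = 1
  wr_f32(rep(0, 6))                    # quatern_b..qoffset_z
  wr_f32(c(spacing[1], 0, 0, origin[1]))
  wr_f32(c(0, spacing[2], 0, origin[2]))
  wr_f32(c(0, 0, spacing[3], origin[3]))
  wr_pad(16)                           # intent_name
  writeBin(charToRaw("n+1"), con); wr_pad(1)
  wr_pad(4)                            # extension flag
  what <- if (datatype %in% c("float32", "float64")) vals else as.integer(round(vals))
  writeBin(what, con, NIFTI_BITPIX[[datatype]] / 8L, endian = "little")
  invisible(NULL)
}
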