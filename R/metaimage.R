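# MetaImage (.mhd header + .raw data) reader/writer. Local-data form only
# (ElementDataFile names a companion .raw); axis-aligned identity
# TransformMatrix required.

MET_TYPES <- c(MET_UCHAR = "uint8", MET_SHORT = "int16", MET_USHORT = "uint16",
               MET_INT = "int32", MET_FLOAT = "float32", MET_DOUBLE = "float64")

read_metaimage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- m[3]
  }
  need <- function(key) {
    if (is.null(kv[[key]]))
      stop(sprintf("MetaImage '%s': missing required field '%s'", path, key))
    kv[[key]]
  }
  ndims <- as.integer(need("NDims"))
  if (ndims != 3L)
    stop(sprintf("MetaImage '%s': NDims = %d, only 3 supported", path, ndims))
  dims <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  spacing <- if (!is.null(kv$ElementSpacing))
    as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(kv$Offset))
    as.numeric(strsplit(kv$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  if (!is.null(kv$TransformMatrix)) {
    tm <- as.numeric(strsplit(kv$TransformMatrix, "\\s+")[[1]])
    if (max(abs(tm - c(1, 0, 0, 0, 1, 0, 0, 0, 1))) > 1e-6)
      stop(sprintf("MetaImage '%s': oblique TransformMatrix not supported", path))
  }
  et <- need("ElementType")
  dtname <- MET_TYPES[[et]]
  if (is.null(dtname))
    stop(sprintf("MetaImage '%s': unsupported ElementType '%s'", path, et))
  big <- identical(kv$BinaryDataByteOrderMSB, "True") ||
         identical(kv$ElementByteOrderMSB, "True")
  datafile <- need("ElementDataFile")
  if (identical(datafile, "LIST"))
    stop(sprintf("MetaImage '%s': multi-file LIST form not supported", path))
  rawpath <- file.path(dirname(path), datafile)
  size <- NIFTI_BITPIX[[dtname]] / 8L
  what <- if (dtname %in% c("float32", "float64")) "double" else "integer"
  con <- file(rawpath, "rb")
  on.exit(close(con))
  n <- prod(dims)
  vals <- readBin(con, what, n, size, signed = !(dtname %in% c("uint8", "uint16")),
                  endian = if (big) "big" else "little")
  if (length(vals) != n)
    stop(sprintf("MetaImage '%s': raw file holds %d values, header says %d",
                 path, length(vals), n))
  vs_volume(array(as.numeric(vals), dims), spacing, origin)
}

write_metaimage <- function(data, spacing, origin, path, datatype = NULL) {
  vals <- as.numeric(data)
  if (is.null(datatype)) {
    intlike <- all(vals == round(vals)) && all(is.finite(vals))
    datatype <- if (intlike && min(vals) >= -32768 && max(vals) <= 32767) "int16"
                else if (intlike && min(vals) >= -2^31 && max(vals) < 2^31) "int32"
                else "float64"
  }
  et <- names(MET_TYPES)[match(datatype, MET_TYPES)]
  if (is.na(et)) stop(sprintf("unsupported MetaImage datatype '%s'", datatype))
  rawname <- sub("\\.mhd$", ".raw", basename(path))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(origin, trim = TRUE), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    paste("ElementSpacing =", paste(format(spacing, trim = TRUE), collapse = " ")),
    paste("DimSize =", paste(dim(data)[1:3], collapse = " ")),
    paste("ElementType =", et),
    paste("ElementDataFile =", rawname)
  )
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), rawname), "wb")
  on.exit(close(con))
  what <- if (datatype %in% c("float32", "float64")) vals else as.integer(round(vals))
  writeBin(what, con, NIFTI_BITPIX[[datatype]] / 8L, endian = "little")
  invisible(NULL)
}
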