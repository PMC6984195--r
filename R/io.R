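#' Read a 3D volume from a standard format
#'
#' Supported formats: NIfTI-1 (`.nii` / `.nii.gz`), MetaImage (`.mhd` with a
#' companion `.raw`), and a DICOM series directory (read-only). Integer
#' intensities are preserved losslessly; geometry (dims, spacing in mm,
#' origin in mm) is taken from the file header. Oblique orientation matrices
#' and mixed-spacing DICOM series are rejected with an error naming the
#' offending field.
#'
#' @param path file path (NIfTI/MetaImage) or directory (DICOM series).
#' @param format one of `"nifti"`, `"metaimage"`, `"dicom_series"`, or
#'   `"auto"` to infer from the path.
#' @param verbose log dims/spacing of everything read (default off).
#' @return A [vs_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "metaimage", "dicom_series"),
                        verbose = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_series"
    else if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
    else if (grepl("\\.mhd$", path)) "metaimage"
    else stop(sprintf("cannot infer format of '%s'; pass `format`", path))
  }
  if (format != "dicom_series" && !file.exists(path))
    stop(sprintf("file '%s' does not exist", path))
  vol <- switch(format,
    nifti = read_nifti(path),
    metaimage = read_metaimage(path),
    dicom_series = read_dicom_series(path))
  if (verbose)
    message(sprintf("read %s '%s': %s voxels, spacing (%s) mm", format, path,
                    paste(vol$dims, collapse = "x"),
                    paste(format(vol$spacing), collapse = ", ")))
  vol
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' Integer-valued data round-trips bit-exactly (stored as int16/int32);
#' non-integer data is stored as float64. A failed write leaves no partial
#' file behind (write-to-temporary then rename).
#'
#' @param vol a [vs_volume()].
#' @param path output path (`.nii`, `.nii.gz`, or `.mhd`).
#' @param format `"nifti"`, `"metaimage"`, or `"auto"` (from the extension).
#' @param verbose log what was written.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path, format = c("auto", "nifti", "metaimage"),
                         verbose = FALSE) {
  stopifnot_volume(vol)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
    else if (grepl("\\.mhd$", path)) "metaimage"
    else stop(sprintf("cannot infer format of '%s'; pass `format`", path))
  }
  write_atomic(path, format, vol$data, vol$spacing, vol$origin)
  if (verbose)
    message(sprintf("wrote %s '%s': %s voxels", format, path,
                    paste(vol$dims, collapse = "x")))
  invisible(path)
}

# Write via a temporary sibling then rename, so failures leave no partial file.
# MetaImage needs its .raw companion to carry the final name, so it is written
# into a scratch subdirectory first.
write_atomic <- function(path, format, data, spacing, origin) {
  dir <- dirname(path)
  if (format == "nifti") {
    tmp <- tempfile(tmpdir = dir, fileext = ".nii.part")
    ok <- FALSE
    on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
    # Force the gz/plain choice of the *final* name on the temporary.
    if (grepl("\\.gz$", path)) tmp <- paste0(tmp, ".gz")
    write_nifti(data, spacing, origin, tmp)
    if (!file.rename(tmp, path))
      stop(sprintf("cannot write '%s'", path))
    ok <- TRUE
  } else {
    tmpdir <- tempfile("mhd", tmpdir = dir)
    ok <- dir.create(tmpdir)
    if (!ok) stop(sprintf("cannot create staging directory under '%s'", dir))
    ok <- FALSE
    on.exit(if (!ok) unlink(tmpdir, recursive = TRUE))
    tmp <- file.path(tmpdir, basename(path))
    write_metaimage(data, spacing, origin, tmp)
    rawname <- sub("\\.mhd$", ".raw", basename(path))
    file.rename(file.path(tmpdir, rawname), file.path(dir, rawname))
    file.rename(tmp, path)
    unlink(tmpdir, recursive = TRUE)
    ok <- TRUE
  }
  invisible(NULL)
}

#' Read or write a deformation field as a 3-vector NIfTI volume
#'
#' Fields are stored as 5-dimensional NIfTI (dim\[5\] = 3, intent code
#' NIFTI_INTENT_VECTOR), displacement components in mm on the reference grid.
#'
#' @param field a [deformation_field()].
#' @param path a `.nii` / `.nii.gz` path.
#' @return `read_field` returns a [deformation_field()].
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "vs_field"))
  write_nifti(field$u, field$spacing, field$origin, path, datatype = "float64")
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  x <- read_nifti(path)
  if (is_vs_volume(x) || x$ncomp != 3L)
    stop(sprintf("'%s' is not a 3-vector field", path))
  deformation_field(x$data, x$spacing, x$origin)
}
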