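#' 3D scalar volume with physical geometry
#'
#' The image currency of every registration stage: a 3D intensity grid with
#' per-axis voxel spacing and a physical origin, both in millimetres, in an
#' axis-aligned patient frame. Voxel indices are 0-based in physical maps;
#' `physical(v) = origin + v * spacing`. Oblique orientations are not
#' represented (see [read_volume()]).
#'
#' @param data numeric 3D array of intensities, indexed (i, j, k).
#' @param spacing numeric(3), voxel size per axis in mm; strictly positive.
#' @param origin numeric(3), physical position (mm) of voxel (0, 0, 0).
#' @return A `vs_volume` object with fields `data`, `spacing`, `origin`, `dims`.
#' @examples
#' v <- vs_volume(array(0, c(8, 8, 8)), spacing = c(1, 1, 2))
#' v$dims
#' @export
vs_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin,
                 dims = dim(data)),
            class = "vs_volume")
}

#' @export
print.vs_volume <- function(x, ...) {
  cat(sprintf("<vs_volume> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.vs_volume <- function(x) x$dims

is_vs_volume <- function(x) inherits(x, "vs_volume")

stopifnot_volume <- function(x, arg = deparse(substitute(x))) {
  if (!is_vs_volume(x)) stop(sprintf("`%s` must be a vs_volume", arg))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  all(a$dims == b$dims) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Convert between physical (mm) and continuous voxel coordinates
#'
#' Mutually inverse maps between the physical patient frame and 0-based
#' continuous voxel indices: voxel (0, 0, 0) maps to the volume origin.
#' Out-of-grid indices are allowed; callers decide how to treat them.
#'
#' @param vol a [vs_volume()].
#' @param p numeric(3) physical point in mm, or an n x 3 matrix of points.
#' @param v numeric(3) continuous voxel index, or an n x 3 matrix.
#' @return The mapped coordinates, same shape as the input.
#' @examples
#' v <- vs_volume(array(0, c(4, 4, 4)), spacing = c(2, 2, 2), origin = c(10, 0, 0))
#' physical_to_voxel(v, c(10, 0, 0))   # (0, 0, 0)
#' voxel_to_physical(v, c(1, 1, 1))    # origin + spacing
#' @export
physical_to_voxel <- function(vol, p) {
  stopifnot_volume(vol)
  if (is.matrix(p)) sweep(sweep(p, 2, vol$origin), 2, vol$spacing, "/")
  else (as.numeric(p) - vol$origin) / vol$spacing
}

#' @rdname physical_to_voxel
#' @export
voxel_to_physical <- function(vol, v) {
  stopifnot_volume(vol)
  if (is.matrix(v)) sweep(sweep(v, 2, vol$spacing, "*"), 2, vol$origin, "+")
  else vol$origin + as.numeric(v) * vol$spacing
}

#' Resample a volume onto another volume's grid
#'
#' Trilinearly interpolates `moving` at the physical location of every voxel
#' of `target`; locations outside `moving`'s physical extent receive `fill`.
#' Used to harmonize CBCT grids onto the planning-CT grid (resample +
#' zero-pad). Exact (no interpolation error) when the two grids coincide.
#'
#' @param moving the [vs_volume()] supplying intensities.
#' @param target the [vs_volume()] supplying the output geometry.
#' @param fill scalar used outside `moving`'s extent (default 0, zero-padding).
#' @return A `vs_volume` on `target`'s grid.
#' @export
resample_to_grid <- function(moving, target, fill = 0) {
  stopifnot_volume(moving); stopifnot_volume(target)
  out <- cpp_resample(as.numeric(moving$data), as.integer(moving$dims),
                      moving$spacing, moving$origin,
                      as.integer(target$dims), target$spacing, target$origin,
                      as.numeric(fill))
  vs_volume(array(out, target$dims), target$spacing, target$origin)
}

#' Sample a volume at arbitrary physical points
#'
#' @param vol a [vs_volume()].
#' @param pts n x 3 matrix of physical points (mm).
#' @param fill value for points outside the volume extent.
#' @return numeric vector of trilinearly interpolated intensities.
#' @keywords internal
sample_at <- function(vol, pts, fill = NA_real_) {
  stopifnot_volume(vol)
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3)
  idx <- physical_to_voxel(vol, pts)
  cpp_trilinear_sample(as.numeric(vol$data), as.integer(vol$dims), idx,
                       as.numeric(fill))
}
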