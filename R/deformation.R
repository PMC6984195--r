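#' Dense deformation field on the reference grid
#'
#' Per-voxel displacement vectors in mm: the field maps a reference physical
#' point `p` to the floating-space point `p + u(p)` (backward map), so
#' warping the floating image onto the reference grid needs no inversion.
#'
#' @param u numeric 4D array `dims x 3` of displacements (mm).
#' @param spacing,origin reference grid geometry (mm).
#' @return A `vs_field` object.
#' @export
deformation_field <- function(u, spacing, origin) {
  if (length(dim(u)) != 4L || dim(u)[4] != 3L)
    stop("`u` must be a dims x 3 displacement array")
  if (any(!is.finite(u))) stop("deformation field must be finite everywhere")
  structure(list(u = u, dims = dim(u)[1:3], spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "vs_field")
}

#' @export
print.vs_field <- function(x, ...) {
  mag <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat(sprintf("<vs_field> %s voxels, |u| max %.3f mm, mean %.3f mm\n",
              paste(x$dims, collapse = "x"), max(mag), mean(mag)))
  invisible(x)
}

#' Dense field from the finest-level transform grid
#'
#' Realizes "quaternion-based cubic interpolation of individual rigid
#' transformations": each control transform is put in the common displace-x
#' form `y = R x + b`; rotations are blended as sign-aligned unit
#' quaternions and `b` vectors with separable Catmull-Rom cubic weights over
#' the 4 x 4 x 4 control neighborhood (border-replicated), the blended
#' quaternion is renormalized, and `u(x) = R_hat x + b_hat - x`. Cubic
#' weights sum to 1, so a constant control grid -- identity, a pure
#' translation, or one shared rigid motion -- is reproduced exactly, and the
#' field is C1 away from control points.
#'
#' @param leaf_grid the `leaf_grid` component of a [hierarchical_register()]
#'   result (regular, complete grid of cell centers + transforms), or a
#'   `vs_hierarchy`.
#' @param ref_geometry `list(dims, spacing, origin)` of the reference grid
#'   (defaults to the hierarchy's own).
#' @return A [deformation_field()].
#' @export
interpolate_field <- function(leaf_grid, ref_geometry = NULL) {
  if (inherits(leaf_grid, "vs_hierarchy")) {
    if (is.null(ref_geometry)) ref_geometry <- leaf_grid$ref_geometry
    leaf_grid <- leaf_grid$leaf_grid
  }
  if (is.null(ref_geometry))
    stop("`ref_geometry` is required when passing a bare leaf grid")
  g <- leaf_grid
  if (is.null(g$dims) || nrow(g$centers) != prod(g$dims))
    stop("incomplete leaf grid: need one transform per finest-level cell")
  gdims <- as.integer(g$dims)
  first <- g$centers[1, ]
  last <- g$centers[nrow(g$centers), ]
  gstep <- ifelse(gdims > 1L, (last - first) / pmax(gdims - 1L, 1L),
                  ref_geometry$dims * ref_geometry$spacing)
  u <- cpp_interpolate_field(g$quats, g$bvecs, gdims, first, gstep,
                             as.integer(ref_geometry$dims),
                             ref_geometry$spacing, ref_geometry$origin)
  deformation_field(array(u, c(ref_geometry$dims, 3)),
                    ref_geometry$spacing, ref_geometry$origin)
}

#' Field from a single rigid transform
#'
#' Utility: the dense field of one global rigid motion on a reference grid.
#'
#' @param T a [rigid_transform()].
#' @param geometry `list(dims, spacing, origin)` or a [vs_volume()].
#' @return A [deformation_field()].
#' @export
rigid_field <- function(T, geometry) {
  if (is_vs_volume(geometry))
    geometry <- list(dims = geometry$dims, spacing = geometry$spacing,
                     origin = geometry$origin)
  Rb <- rigid_to_Rb(T)
  grid <- list(dims = c(1L, 1L, 1L),
               centers = matrix(geometry$origin, 1),
               quats = matrix(Rb$q, 1), bvecs = matrix(as.numeric(Rb$b), 1))
  interpolate_field(grid, geometry)
}

#' Warp a floating image through a deformation field
#'
#' Backward warping onto the reference grid: the output intensity at voxel
#' `x` is the trilinear sample of `flt` at `x + u(x)`; samples outside the
#' floating volume receive `fill`.
#'
#' @param flt floating [vs_volume()].
#' @param field a [deformation_field()] on the reference grid.
#' @param fill out-of-volume fill value.
#' @return A `vs_volume` on the reference grid (the "registered CT").
#' @export
warp <- function(flt, field, fill = 0) {
  stopifnot_volume(flt)
  stopifnot(inherits(field, "vs_field"))
  out <- cpp_warp(as.numeric(flt$data), as.integer(flt$dims), flt$spacing,
                  flt$origin, as.numeric(field$u), as.integer(field$dims),
                  field$spacing, field$origin, as.numeric(fill))
  vs_volume(array(out, field$dims), field$spacing, field$origin)
}

#' Minimum Jacobian determinant of a deformation field
#'
#' Minimum over interior voxels of `det(I + grad(u))`, with the displacement
#' gradient taken by central differences in physical units. A strictly
#' positive value certifies that the field preserves topology (no image
#' folding) -- the invariant the per-level displacement caps are designed to
#' guarantee.
#'
#' @param field a [deformation_field()].
#' @return Scalar minimum determinant (1 for a zero or constant field).
#' @export
jacobian_min <- function(field) {
  stopifnot(inherits(field, "vs_field"))
  cpp_jacobian_min(as.numeric(field$u), as.integer(field$dims), field$spacing)
}

#' Map a physical point through a deformation field
#'
#' `p + u(p)` with `u` trilinearly interpolated at `p`; exact at voxel
#' centers. Errors if `p` lies outside the field's physical extent.
#'
#' @param field a [deformation_field()].
#' @param p numeric(3) physical point (mm) or n x 3 matrix of points.
#' @return Mapped point(s), same shape as `p`.
#' @export
transform_point <- function(field, p) {
  stopifnot(inherits(field, "vs_field"))
  pts <- if (is.matrix(p)) p else matrix(as.numeric(p), ncol = 3)
  idx <- sweep(sweep(pts, 2, field$origin), 2, field$spacing, "/")
  bad <- which(apply(idx, 1, function(v)
    any(v < 0 | v > field$dims - 1)))
  if (length(bad) > 0L)
    stop(sprintf("point (%s) mm is outside the field extent",
                 paste(format(pts[bad[1], ]), collapse = ", ")))
  n <- nrow(pts)
  dims <- as.integer(field$dims)
  out <- pts
  for (c in 1:3)
    out[, c] <- pts[, c] + cpp_trilinear_sample(as.numeric(field$u[, , , c]),
                                                dims, idx, NA_real_)
  if (is.matrix(p)) out else as.numeric(out)
}
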