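#' Intensity window/level
#'
#' The window `[wmin, wmax]` selects the intensity subset that takes part in
#' the mutual-information calculation: values are clamped to the window and
#' mapped affinely so that `wmin` becomes 0 and `wmax` becomes 255.
#'
#' @param wmin,wmax window bounds in the image's native intensity units
#'   (Hounsfield-like for CT); `wmax > wmin`.
#' @return A `vs_window` object.
#' @export
window_level <- function(wmin, wmax) {
  if (!is.finite(wmin) || !is.finite(wmax) || wmax <= wmin)
    stop("degenerate window: `wmax` must exceed `wmin`")
  structure(list(wmin = as.numeric(wmin), wmax = as.numeric(wmax)),
            class = "vs_window")
}

#' Rescale intensities into \[0, 255\] by a preset window/level
#'
#' `clamp(v, wmin, wmax)` mapped affinely to `[0, 255]`; monotone
#' non-decreasing in the input intensity.
#'
#' @param vol a [vs_volume()].
#' @param wl a [window_level()].
#' @return A `vs_volume` with intensities in `[0, 255]`.
#' @examples
#' v <- vs_volume(array(c(-1000, 0, 1000), c(3, 1, 1)))
#' window_level_rescale(v, window_level(-1000, 1000))$data[, 1, 1]
#' @export
window_level_rescale <- function(vol, wl) {
  stopifnot_volume(vol)
  if (!inherits(wl, "vs_window")) stop("`wl` must be a vs_window")
  if (!is.finite(wl$wmin) || !is.finite(wl$wmax) || wl$wmax <= wl$wmin)
    stop("degenerate window: `wmax` must exceed `wmin`")
  d <- pmin(pmax(vol$data, wl$wmin), wl$wmax)
  d <- (d - wl$wmin) * (255 / (wl$wmax - wl$wmin))
  vs_volume(array(d, vol$dims), vol$spacing, vol$origin)
}

gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Gaussian smoothing at the voxel-size scale
#'
#' Separable discrete Gaussian filtering applied per axis before
#' registration, with per-axis standard deviation equal to one voxel spacing
#' (`sigma_i = spacing_i` mm, i.e. one voxel). The kernel is truncated at 3
#' sigma and renormalized; boundaries are handled by edge replication, which
#' avoids darkening at the field-of-view border that would bias MI. Constant
#' volumes are preserved exactly.
#'
#' @param vol a [vs_volume()].
#' @param sigma_mm optional numeric(3) override of the per-axis sigma in mm.
#' @return The smoothed `vs_volume`.
#' @export
gaussian_smooth <- function(vol, sigma_mm = NULL) {
  stopifnot_volume(vol)
  if (is.null(sigma_mm)) sigma_mm <- vol$spacing
  sigma_vox <- sigma_mm / vol$spacing
  d <- as.numeric(vol$data)
  for (axis in 0:2) {
    if (sigma_vox[axis + 1] <= 0) next
    k <- gaussian_kernel_1d(sigma_vox[axis + 1])
    d <- cpp_conv_axis(d, as.integer(vol$dims), k, axis)
  }
  vs_volume(array(d, vol$dims), vol$spacing, vol$origin)
}

#' Preprocess an image pair for registration
#'
#' Pipeline head applied to both reference and floating images: each image is
#' rescaled by its own preset window/level into \[0, 255\], then Gaussian
#' smoothing at voxel-size scale is applied (optional).
#'
#' @param vol a [vs_volume()].
#' @param wl its [window_level()].
#' @param smooth apply [gaussian_smooth()] after windowing (default `TRUE`).
#' @return The preprocessed `vs_volume`, intensities in `[0, 255]`.
#' @export
preprocess_volume <- function(vol, wl, smooth = TRUE) {
  out <- window_level_rescale(vol, wl)
  if (smooth) out <- gaussian_smooth(out)
  out
}
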