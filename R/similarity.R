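#' Build a joint intensity histogram
#'
#' Co-occurrence counts of paired reference/floating intensity samples
#' already windowed into \[0, 255\]. Bin index is `floor(v * n_bins / 256)`,
#' clamped to the top bin at `v = 255`; counts sum to the number of samples.
#' This is the "mutual histogram" at the heart of the MI estimator.
#'
#' @param ref_samples,flt_samples equal-length numeric vectors in `[0, 255]`.
#' @param n_bins bins per image (same for both axes here).
#' @return A `vs_jhist`: `counts` (n_bins x n_bins matrix, ref rows, flt
#'   columns), `n_bins_ref`, `n_bins_flt`, `total`.
#' @export
build_joint_histogram <- function(ref_samples, flt_samples, n_bins = 64L) {
  n <- length(ref_samples)
  if (n == 0L || length(flt_samples) == 0L)
    stop("empty sample lists: MI undefined")
  if (length(flt_samples) != n)
    stop("ref and flt sample lists must have equal length")
  bin <- function(v) pmin(pmax(floor(v * n_bins / 256), 0L), n_bins - 1L)
  counts <- matrix(0, n_bins, n_bins)
  tab <- table(factor(bin(ref_samples), levels = 0:(n_bins - 1L)),
               factor(bin(flt_samples), levels = 0:(n_bins - 1L)))
  counts[] <- as.numeric(tab)
  joint_histogram(counts)
}

#' @rdname build_joint_histogram
#' @param counts a nonnegative count matrix (ref bins x flt bins).
#' @export
joint_histogram <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("joint histogram counts must be nonnegative")
  structure(list(counts = counts, n_bins_ref = nrow(counts),
                 n_bins_flt = ncol(counts), total = sum(counts)),
            class = "vs_jhist")
}

#' Mutual information of a joint histogram, in bits
#'
#' `MI = sum_ij p_ij log2(p_ij / (p_i. p_.j))` over nonzero cells, with
#' `p = counts / total`. Always nonnegative; symmetric under transposition.
#' The registration cost at every subdivision level maximizes this quantity.
#'
#' @param h a [joint_histogram()] (or a raw count matrix).
#' @return MI in bits.
#' @examples
#' mutual_information(joint_histogram(diag(5, 2)))   # 1 bit
#' mutual_information(joint_histogram(matrix(25, 2, 2)))  # 0 bits
#' @export
mutual_information <- function(h) {
  if (is.matrix(h)) h <- joint_histogram(h)
  if (!inherits(h, "vs_jhist")) stop("`h` must be a joint histogram")
  if (h$total <= 0) stop("joint histogram is empty (total = 0)")
  p <- h$counts / h$total
  pr <- rowSums(p)
  pc <- colSums(p)
  nz <- which(p > 0, arr.ind = TRUE)
  pij <- p[nz]
  sum(pij * log2(pij / (pr[nz[, 1]] * pc[nz[, 2]])))
}

#' Mean 3D structural similarity (SSIM) index
#'
#' Local luminance, contrast and structure terms combined per voxel within a
#' 3D sliding Gaussian window and averaged over a mask. Used as a
#' modality-tolerant evaluation metric between the (warped) planning CT and
#' the reference CBCT, complementing the point-based TRE. Defaults follow
#' the standard SSIM constants on the post-windowing 8-bit range:
#' `L = 255`, `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, `C3 = C2 / 2`, cubic
#' window of radius 5 with Gaussian weights of sigma 1.5 voxels.
#'
#' @param a,b [vs_volume()]s on the same grid.
#' @param mask logical array on the same grid, or `NULL` for all voxels. The
#'   usual choice is the CBCT field of view (`b$data > 0` after padding).
#' @param params list overriding `L`, `C1`, `C2`, `C3`, `window_radius`,
#'   `window_sigma`.
#' @return Mean SSIM over the mask, in `[-1, 1]`; exactly 1 iff `a` and `b`
#'   agree on (a neighborhood of) the mask.
#' @export
ssim3d <- function(a, b, mask = NULL, params = list()) {
  stopifnot_volume(a); stopifnot_volume(b)
  if (!all(a$dims == b$dims))
    stop("ssim3d: volumes must share a grid")
  p <- utils::modifyList(list(L = 255, window_radius = 5L, window_sigma = 1.5),
                         params)
  if (is.null(p$C1)) p$C1 <- (0.01 * p$L)^2
  if (is.null(p$C2)) p$C2 <- (0.03 * p$L)^2
  if (is.null(p$C3)) p$C3 <- p$C2 / 2
  if (p$C1 <= 0 || p$C2 <= 0 || p$C3 <= 0) stop("SSIM stabilizers must be > 0")
  r <- p$window_radius
  x <- (-r):r
  k <- exp(-x^2 / (2 * p$window_sigma^2))
  k <- k / sum(k)
  dims <- as.integer(a$dims)
  smooth3 <- function(v) {
    for (axis in 0:2) v <- cpp_conv_axis(v, dims, k, axis)
    v
  }
  av <- as.numeric(a$data); bv <- as.numeric(b$data)
  mu_a <- smooth3(av); mu_b <- smooth3(bv)
  va <- pmax(smooth3(av * av) - mu_a^2, 0)
  vb <- pmax(smooth3(bv * bv) - mu_b^2, 0)
  cab <- smooth3(av * bv) - mu_a * mu_b
  lum <- (2 * mu_a * mu_b + p$C1) / (mu_a^2 + mu_b^2 + p$C1)
  if (isTRUE(all.equal(p$C3, p$C2 / 2))) {
    # contrast * structure collapses to one ratio, which is exactly 1 for
    # identical inputs (no sqrt rounding).
    s <- lum * (2 * cab + p$C2) / (va + vb + p$C2)
  } else {
    sa <- sqrt(va); sb <- sqrt(vb)
    con <- (2 * sa * sb + p$C2) / (va + vb + p$C2)
    str <- (cab + p$C3) / (sa * sb + p$C3)
    s <- lum * con * str
  }
  if (is.null(mask)) mean(s) else {
    m <- as.logical(mask)
    if (!any(m)) stop("ssim3d: empty mask")
    mean(s[m])
  }
}

#' Field-of-view mask of a zero-padded volume
#'
#' @param vol a [vs_volume()].
#' @param threshold voxels strictly above this count as inside (default 0).
#' @return logical array on the volume grid.
#' @export
fov_mask <- function(vol, threshold = 0) {
  stopifnot_volume(vol)
  vol$data > threshold
}
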