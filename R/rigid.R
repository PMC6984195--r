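# Quaternion convention: q = (w, x, y, z), unit norm, acting as the rotation
# matrix R(q). Euler angles use the R = Rz(rz) Ry(ry) Rx(rx) composition in
# radians internally; user-facing steps/bounds are in degrees.

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_multiply <- function(q2, q1) {
  w1 <- q1[1]; v1 <- q1[2:4]
  w2 <- q2[1]; v2 <- q2[2:4]
  c(w2 * w1 - sum(v2 * v1),
    w2 * v1 + w1 * v2 + c(v2[2] * v1[3] - v2[3] * v1[2],
                          v2[3] * v1[1] - v2[1] * v1[3],
                          v2[1] * v1[2] - v2[2] * v1[1]))
}

quat_conjugate <- function(q) c(q[1], -q[2:4])

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  quat_normalize(q)
}

euler_to_quat <- function(rx, ry, rz) {
  half <- c(rx, ry, rz) / 2
  cx <- cos(half[1]); sx <- sin(half[1])
  cy <- cos(half[2]); sy <- sin(half[2])
  cz <- cos(half[3]); sz <- sin(half[3])
  # q = qz * qy * qx
  quat_multiply(c(cz, 0, 0, sz), quat_multiply(c(cy, 0, sy, 0), c(cx, sx, 0, 0)))
}

quat_to_euler <- function(q) {
  R <- quat_to_matrix(q)
  ry <- asin(max(-1, min(1, -R[3, 1])))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  c(rx, ry, rz)
}

#' Rigid transform: unit-quaternion rotation + translation about a center
#'
#' The per-subvolume unknown of the volume-subdivision hierarchy. Applied as
#' `T(p) = center + R (p - center) + translation`, all in physical mm.
#'
#' @param rotation unit quaternion `(w, x, y, z)` (normalized on input).
#' @param translation numeric(3), mm.
#' @param center numeric(3), rotation center in mm.
#' @return A `vs_rigid` object.
#' @export
rigid_transform <- function(rotation = c(1, 0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- as.numeric(rotation)
  if (length(rotation) != 4L || abs(sqrt(sum(rotation^2)) - 1) > 1e-6)
    stop("`rotation` must be a (near-)unit quaternion (w, x, y, z)")
  structure(list(rotation = quat_normalize(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "vs_rigid")
}

#' @rdname rigid_transform
#' @export
identity_transform <- function(center = c(0, 0, 0))
  rigid_transform(center = center)

#' @export
print.vs_rigid <- function(x, ...) {
  ang <- quat_to_euler(x$rotation) * 180 / pi
  cat(sprintf("<vs_rigid> rot (%.3f, %.3f, %.3f) deg, trans (%.3f, %.3f, %.3f) mm, center (%.1f, %.1f, %.1f) mm\n",
              ang[1], ang[2], ang[3], x$translation[1], x$translation[2],
              x$translation[3], x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

# "Displace x" form: T(p) = R p + b.
rigid_to_Rb <- function(T) {
  R <- quat_to_matrix(T$rotation)
  list(R = R, b = T$center - R %*% T$center + T$translation, q = T$rotation)
}

rigid_from_Rb <- function(q, b, center = c(0, 0, 0)) {
  R <- quat_to_matrix(q)
  rigid_transform(q, as.numeric(b) - center + as.numeric(R %*% center), center)
}

#' Apply, compose, invert and re-center rigid transforms
#'
#' `apply_transform` maps points; `compose(T2, T1)` is "apply `T1`, then
#' `T2`"; `invert` satisfies `compose(T, invert(T)) = identity`;
#' `recenter` re-expresses the same rigid motion about a new rotation center.
#'
#' @param T,T1,T2 [rigid_transform()]s.
#' @param p numeric(3) point (mm) or an n x 3 matrix of points.
#' @param center new rotation center, numeric(3) mm.
#' @return `apply_transform`: mapped point(s); the others: a `vs_rigid`.
#' @export
apply_transform <- function(T, p) {
  Rb <- rigid_to_Rb(T)
  if (is.matrix(p)) t(Rb$R %*% t(p) + as.numeric(Rb$b))
  else as.numeric(Rb$R %*% p + Rb$b)
}

#' @rdname apply_transform
#' @export
compose <- function(T2, T1) {
  a <- rigid_to_Rb(T2); b <- rigid_to_Rb(T1)
  q <- quat_normalize(quat_multiply(a$q, b$q))
  rigid_from_Rb(q, a$R %*% b$b + a$b, T1$center)
}

#' @rdname apply_transform
#' @export
invert <- function(T) {
  Rb <- rigid_to_Rb(T)
  q <- quat_conjugate(T$rotation)
  rigid_from_Rb(q, -t(Rb$R) %*% Rb$b, T$center)
}

#' @rdname apply_transform
#' @export
recenter <- function(T, center) {
  Rb <- rigid_to_Rb(T)
  rigid_from_Rb(T$rotation, Rb$b, as.numeric(center))
}

#' MI-driven rigid registration of a region
#'
#' Maximizes histogram mutual information between the reference intensities
#' inside `region` and the floating intensities at rigidly transformed
#' positions, over 6 parameters (3 Euler rotations, 3 translations), by
#' bound-constrained downhill simplex starting from `init`. The search is a
#' *refinement*: candidate transforms are `delta o init`, with the delta
#' rotation centered at the init-mapped region center, so the translation
#' parameters are exactly the displacement of the region center relative to
#' `init` and are projected onto the ball of radius `max_disp`.
#'
#' Reference voxels whose transformed position falls outside the floating
#' volume are discarded from the histogram; if fewer than `min_valid_frac`
#' of the region's samples are valid at `init`, the region is left
#' unrefined (`refined = FALSE`) and `init` is returned.
#'
#' @param ref,flt preprocessed [vs_volume()]s with intensities in `[0, 255]`.
#' @param region `list(lo =, hi =)` of 0-based half-open voxel bounds on the
#'   reference grid, or `NULL` for the whole volume.
#' @param init starting [rigid_transform()] (default identity).
#' @param max_disp maximum allowed displacement (mm) of the region center
#'   relative to `init`.
#' @param settings [simplex_settings()]; steps in mm and degrees.
#' @param n_bins histogram bins per image.
#' @param stride sample every `stride`-th voxel per axis (speed knob).
#' @param rot_bound_deg rotation bound per Euler angle, degrees.
#' @param min_valid_frac minimum valid-sample fraction to attempt refinement.
#' @param min_ref_sd minimum standard deviation of the reference intensities
#'   in the region (0-255 scale) for refinement to be attempted: a
#'   near-constant region (air outside the patient) carries no registrable
#'   structure, and MI on its residual noise would be a random walk.
#' @param reg_weight weight (bits) of the quadratic movement-regularization
#'   term `reg_weight * (|dt| / max_disp)^2` added to the cost; 0 disables.
#'   In the hierarchy this carries the flexibility parameter: the weight is
#'   inversely proportional to it.
#' @param detrend_z locally stationarize the reference samples before
#'   binning by removing their within-region linear trend along z
#'   (counteracts the axial shading of cone-beam reconstructions, which
#'   otherwise couples intensity to position inside every region).
#' @param equalize use rank (equalized) binning: histogram bins are the
#'   region's own intensity quantiles (ties share a bin). MI is invariant
#'   under monotone remaps, so this changes only the estimator -- the
#'   locally informative intensity band fills all bins instead of being
#'   quantized into a few.
#' @param jitter sample at deterministically jittered sub-voxel positions,
#'   suppressing the MI interpolation artifact that otherwise inflates the
#'   estimate at exactly grid-aligned transforms (default `TRUE`).
#' @return A `vs_rigid` with rotation center at the region's physical
#'   center, plus attributes `refined`, `mi_init`, `mi_final`, `valid_frac`.
#' @export
rigid_register <- function(ref, flt, region = NULL, init = NULL,
                           max_disp = 50, settings = simplex_settings(),
                           n_bins = 64L, stride = 1L, rot_bound_deg = 20,
                           min_valid_frac = 0.25, min_ref_sd = 2,
                           reg_weight = 0, detrend_z = FALSE,
                           equalize = FALSE, jitter = TRUE) {
  stopifnot_volume(ref); stopifnot_volume(flt)
  if (is.null(region)) region <- list(lo = c(0L, 0L, 0L), hi = ref$dims)
  lo <- as.integer(region$lo); hi <- as.integer(region$hi)
  if (any(hi <= lo)) stop("rigid_register: empty region")
  if (is.null(init)) init <- identity_transform()
  center <- voxel_to_physical(ref, (lo + hi - 1) / 2)
  cprime <- apply_transform(init, center)
  init_Rb <- rigid_to_Rb(init)

  mi_of <- function(Rb) {
    cpp_mi_region(as.numeric(ref$data), as.integer(ref$dims), ref$spacing,
                  ref$origin, as.numeric(flt$data), as.integer(flt$dims),
                  flt$spacing, flt$origin, lo, hi, Rb$R, as.numeric(Rb$b),
                  c(0, 0, 0), as.integer(n_bins), as.integer(stride),
                  as.integer(isTRUE(detrend_z)), as.integer(isTRUE(equalize)),
                  as.integer(isTRUE(jitter)))
  }
  compose_Rb <- function(aR, ab, aq) {
    list(R = aR %*% init_Rb$R, b = aR %*% init_Rb$b + ab,
         q = quat_normalize(quat_multiply(aq, init_Rb$q)))
  }
  delta_Rb <- function(par) {
    q <- euler_to_quat(par[1] * pi / 180, par[2] * pi / 180, par[3] * pi / 180)
    R <- quat_to_matrix(q)
    b <- cprime - R %*% cprime + par[4:6]
    compose_Rb(R, b, q)
  }

  ref_region <- ref$data[seq(lo[1] + 1L, hi[1], by = stride),
                         seq(lo[2] + 1L, hi[2], by = stride),
                         seq(lo[3] + 1L, hi[3], by = stride)]
  at_init <- mi_of(init_Rb)
  if (at_init[2] < min_valid_frac || stats::sd(ref_region) < min_ref_sd) {
    out <- recenter(init, center)
    attr(out, "refined") <- FALSE
    attr(out, "mi_init") <- at_init[1]
    attr(out, "mi_final") <- at_init[1]
    attr(out, "valid_frac") <- at_init[2]
    return(out)
  }

  # MI rises spuriously as overlap shrinks (fewer samples, sharper
  # histogram), so the cost is overlap-weighted: -MI * valid_fraction.
  # Full-overlap candidates are unaffected. The quadratic movement term is
  # the regularization that restricts excessive subvolume movement: small
  # against any real MI gradient, decisive against same-magnitude
  # estimator-noise optima far from the initialization.
  cost <- function(par) {
    v <- mi_of(delta_Rb(par))
    if (v[2] < min_valid_frac) return(1e6)  # vanishing overlap: large penalty
    -v[1] * v[2] + reg_weight * sum(par[4:6]^2) / max_disp^2
  }
  project <- function(par) {
    par[1:3] <- pmin(pmax(par[1:3], -rot_bound_deg), rot_bound_deg)
    nrm <- sqrt(sum(par[4:6]^2))
    if (nrm > max_disp) par[4:6] <- par[4:6] * (max_disp / nrm)
    par
  }
  fit <- downhill_simplex(cost, x0 = numeric(6),
                          step = c(rep(settings$rot_step, 3),
                                   rep(settings$trans_step, 3)),
                          settings = settings, project = project)
  Rb <- delta_Rb(fit$par)
  out <- recenter(rigid_from_Rb(Rb$q, Rb$b), center)
  attr(out, "refined") <- TRUE
  attr(out, "mi_init") <- at_init[1] * at_init[2]   # overlap-weighted, like the cost
  attr(out, "mi_final") <- -fit$value
  attr(out, "valid_frac") <- at_init[2]
  out
}
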