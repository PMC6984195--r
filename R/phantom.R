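# Deterministic synthetic CT-like / CBCT-like pair generator with known
# ground-truth deformation and landmarks: the desk-scale stand-in for a
# clinical head-and-neck planning CT + daily CBCT dataset. The default
# geometry (96 x 96 x 48 voxels at 1.5 x 1.5 x 3.0 mm) echoes the
# anisotropic slice-thickness-limited acquisitions that motivate the
# z-subdivision-rate parameter.

#' Phantom specification
#'
#' @param dims grid size per axis.
#' @param spacing voxel size, mm.
#' @param seed integer seed; output is bit-reproducible for a fixed seed.
#' @param n_structures number of randomized inclusions (bone-like + soft).
#' @param deform_amplitude peak bump displacement magnitude, mm.
#' @param rigid_translation global translation component of the ground
#'   truth, mm.
#' @param rigid_rotation_deg global rotation (about z through the volume
#'   center), degrees.
#' @return A `vs_phantom_spec` list.
#' @export
phantom_spec <- function(dims = c(96L, 96L, 48L), spacing = c(1.5, 1.5, 3.0),
                         seed = 1L, n_structures = 10L, deform_amplitude = 6,
                         rigid_translation = c(3, 0, 0),
                         rigid_rotation_deg = 0) {
  if (deform_amplitude < 0) stop("`deform_amplitude` must be >= 0")
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 seed = as.integer(seed), n_structures = as.integer(n_structures),
                 deform_amplitude = as.numeric(deform_amplitude),
                 rigid_translation = as.numeric(rigid_translation),
                 rigid_rotation_deg = as.numeric(rigid_rotation_deg)),
            class = "vs_phantom_spec")
}

phantom_coords <- function(spec) {
  d <- spec$dims; s <- spec$spacing
  list(x = (0:(d[1] - 1)) * s[1], y = (0:(d[2] - 1)) * s[2],
       z = (0:(d[3] - 1)) * s[3],
       extent = (d - 1) * s, center = (d - 1) * s / 2)
}

#' Synthetic CT phantom with landmarks
#'
#' Air background (-1000 HU-like), a soft-tissue body ellipsoid (~0 HU)
#' with a slow internal gradient, and `n_structures` randomized inclusions
#' alternating bone-like (~700 HU) ellipsoids and soft-structure (~60 HU)
#' blobs, each with a smooth edge. Landmarks sit at structure centroids.
#'
#' @param spec a [phantom_spec()].
#' @return `list(volume, landmarks)`: the [vs_volume()] and an
#'   `n_structures x 3` matrix of landmark physical coordinates (mm).
#' @export
make_ct_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "vs_phantom_spec"))
  with_seed(spec$seed, {
    co <- phantom_coords(spec)
    d <- spec$dims
    X <- array(rep(co$x, times = d[2] * d[3]), d)
    Y <- array(rep(rep(co$y, each = d[1]), times = d[3]), d)
    Z <- array(rep(co$z, each = d[1] * d[2]), d)
    vol <- array(-1000, d)
    # Body: a 3D ellipsoid (head-like), so every axis -- including
    # superior-inferior -- carries boundary structure. A z-invariant body
    # would leave MI blind to z motion, which no real anatomy is.
    ax <- 0.40 * co$extent[1]; ay <- 0.40 * co$extent[2]
    az <- 0.48 * co$extent[3]
    body <- ((X - co$center[1]) / ax)^2 + ((Y - co$center[2]) / ay)^2 +
      ((Z - co$center[3]) / az)^2
    inside <- body <= 1
    # Soft tissue near 0 HU with a gentle gradient plus smooth low-frequency
    # heterogeneity (~40 HU sd at the ~1 cm scale), emulating the texture
    # that makes local registration identifiable in real tissue.
    tex <- array(stats::rnorm(prod(d)), d)
    tex <- gaussian_smooth(vs_volume(tex, spec$spacing, c(0, 0, 0)),
                           sigma_mm = c(8, 8, 8))$data
    tex <- tex / stats::sd(tex) * 60   # fat/muscle/gland-scale contrast
    vol[inside] <- -20 + 40 * (X[inside] / co$extent[1]) + tex[inside]
    landmarks <- matrix(numeric(0), 0, 3)
    if (spec$n_structures > 0L) {
      landmarks <- matrix(0, spec$n_structures, 3)
      for (s in seq_len(spec$n_structures)) {
        # Centroids kept inside 60% of the body so deformations stay in view.
        ctr <- co$center + c(stats::runif(1, -0.25, 0.25) * co$extent[1],
                             stats::runif(1, -0.25, 0.25) * co$extent[2],
                             stats::runif(1, -0.30, 0.30) * co$extent[3])
        radii <- stats::runif(3, 4, 10) * c(1, 1, 1.2)
        r2 <- ((X - ctr[1]) / radii[1])^2 + ((Y - ctr[2]) / radii[2])^2 +
          ((Z - ctr[3]) / radii[3])^2
        value <- if (s %% 2L == 1L) 700 else 60
        w <- pmax(0, pmin(1, (1.2 - sqrt(r2)) / 0.4))  # smooth 0.8..1.2 edge
        vol <- vol * (1 - w) + value * w
        landmarks[s, ] <- ctr
      }
    }
    list(volume = vs_volume(vol, spec$spacing, c(0, 0, 0)),
         landmarks = landmarks)
  })
}

#' Simulate a CBCT-like image from a CT-like volume
#'
#' Applies a monotone *nonlinear* intensity remap (so CT and CBCT
#' intensities correlate but are deliberately not affine-related: an
#' intensity-difference cost fails while MI succeeds), a linear shading
#' ramp along z away from the central plane (cone-beam reconstruction
#' degrades linearly with distance from it), and Gaussian noise with sigma
#' equal to 3% of the output range.
#'
#' @param ct a CT-like [vs_volume()] (HU-like intensities).
#' @param seed integer seed for the noise.
#' @param noise,ramp set `FALSE` to disable either degradation.
#' @return A `vs_volume` with CBCT-number-like intensities in about
#'   `[0, 2000]`.
#' @export
simulate_cbct <- function(ct, seed = 1L, noise = TRUE, ramp = TRUE) {
  stopifnot_volume(ct)
  rng <- 2000
  v <- pmin(pmax((ct$data + 1000) / 4095, 0), 1)
  out <- rng * v^0.6                       # monotone, curved (not affine)
  if (ramp) {
    d <- ct$dims
    zc <- (d[3] - 1) / 2
    shade <- 1 - 0.15 * abs(((0:(d[3] - 1)) - zc) / zc)
    out <- sweep(out, 3, shade, "*")
  }
  if (noise)
    out <- out + with_seed(seed,
      array(stats::rnorm(prod(ct$dims), 0, 0.03 * rng), ct$dims))
  vs_volume(array(out, ct$dims), ct$spacing, ct$origin)
}

#' Ground-truth deformation field for a phantom
#'
#' Sum of a global rigid motion (the spec's translation and z-rotation
#' about the volume center) and 2-4 seeded Gaussian-bump displacements of
#' peak magnitude `deform_amplitude` (mm). Bump amplitudes are auto-capped,
#' if necessary, so the delivered field always satisfies
#' `jacobian_min > 0.2` -- the "truth" is never folded.
#'
#' @param spec a [phantom_spec()].
#' @return A [deformation_field()] on the phantom grid.
#' @export
make_ground_truth_field <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "vs_phantom_spec"))
  co <- phantom_coords(spec)
  geometry <- list(dims = spec$dims, spacing = spec$spacing, origin = c(0, 0, 0))
  Trig <- rigid_transform(
    euler_to_quat(0, 0, spec$rigid_rotation_deg * pi / 180),
    spec$rigid_translation, center = co$center)
  base <- rigid_field(Trig, geometry)
  u <- base$u
  if (spec$deform_amplitude > 0) {
    bumps <- with_seed(spec$seed + 1L, {
      nb <- sample(2:4, 1)
      lapply(seq_len(nb), function(b) list(
        center = co$center + stats::runif(3, -0.2, 0.2) * co$extent,
        dir = { v <- stats::rnorm(3); v / sqrt(sum(v^2)) },
        sigma = stats::runif(1, 18, 26)))
    })
    d <- spec$dims
    X <- array(rep((0:(d[1] - 1)) * spec$spacing[1], times = d[2] * d[3]), d)
    Y <- array(rep(rep((0:(d[2] - 1)) * spec$spacing[2], each = d[1]),
                   times = d[3]), d)
    Z <- array(rep((0:(d[3] - 1)) * spec$spacing[3], each = d[1] * d[2]), d)
    ub <- array(0, c(d, 3))
    for (b in bumps) {
      g <- exp(-((X - b$center[1])^2 + (Y - b$center[2])^2 +
                   (Z - b$center[3])^2) / (2 * b$sigma^2))
      for (c in 1:3) ub[, , , c] <- ub[, , , c] + b$dir[c] * g
    }
    # Normalize the (possibly overlapping) bump profile so its grid peak is
    # exactly the requested amplitude, then cap for topology if needed.
    peak <- max(sqrt(ub[, , , 1]^2 + ub[, , , 2]^2 + ub[, , , 3]^2))
    amp <- spec$deform_amplitude / peak
    repeat {
      cand <- deformation_field(u + amp * ub, spec$spacing, c(0, 0, 0))
      if (jacobian_min(cand) > 0.2) {
        u <- u + amp * ub
        break
      }
      amp <- amp * 0.8
    }
  }
  deformation_field(u, spec$spacing, c(0, 0, 0))
}

#' Full synthetic registration pair
#'
#' Floating image: the CT phantom. Reference image: the CT warped through
#' the ground-truth field (so the reference plays the deformed daily
#' acquisition) and then degraded into a CBCT-like image. Landmark
#' correspondences carry, for each CT landmark, its reference-space
#' position under the true field (found by fixed-point inversion of the
#' smooth field), so the baseline landmark error equals the true
#' displacement magnitude at those points.
#'
#' @param spec a [phantom_spec()].
#' @return `list(reference, floating, truth_field, landmarks)` where
#'   `landmarks` is a data.frame with CT-space (`ct_*`) and reference-space
#'   (`ref_*`) coordinates in mm.
#' @export
make_pair <- function(spec = phantom_spec()) {
  ctp <- make_ct_phantom(spec)
  field <- make_ground_truth_field(spec)
  deformed <- warp(ctp$volume, field, fill = -1000)
  reference <- simulate_cbct(deformed, seed = spec$seed + 2L)
  lms <- ctp$landmarks
  ref_pts <- matrix(NA_real_, nrow(lms), 3)
  if (nrow(lms) > 0L) {
    for (i in seq_len(nrow(lms))) {
      # Solve p + u(p) = l by fixed-point iteration (converges for |grad u|<1).
      p <- lms[i, ]
      for (it in 1:50) {
        q <- tryCatch(transform_point(field, p), error = function(e) NULL)
        if (is.null(q)) break
        step <- lms[i, ] - q
        p <- p + step
        if (sqrt(sum(step^2)) < 1e-9) break
      }
      ref_pts[i, ] <- p
    }
  }
  landmarks <- data.frame(ct_x = lms[, 1], ct_y = lms[, 2], ct_z = lms[, 3],
                          ref_x = ref_pts[, 1], ref_y = ref_pts[, 2],
                          ref_z = ref_pts[, 3])
  list(reference = reference, floating = ctp$volume, truth_field = field,
       landmarks = landmarks)
}

#' Landmark error of an estimated field on a phantom pair
#'
#' Mean distance between the field-mapped reference-space landmarks and
#' their true CT-space positions; `field = NULL` gives the pre-registration
#' baseline (pure displacement magnitude).
#'
#' @param landmarks the landmark table from [make_pair()].
#' @param field estimated [deformation_field()] (reference to CT), or `NULL`.
#' @return Mean error in mm, with per-landmark errors in `attr(, "errors")`.
#' @export
landmark_error <- function(landmarks, field = NULL) {
  ref <- as.matrix(landmarks[, c("ref_x", "ref_y", "ref_z")])
  ct <- as.matrix(landmarks[, c("ct_x", "ct_y", "ct_z")])
  mapped <- if (is.null(field)) ref else transform_point(field, ref)
  err <- sqrt(rowSums((mapped - ct)^2))
  out <- mean(err)
  attr(out, "errors") <- err
  out
}

#' Default window/levels for the synthetic pair
#'
#' Window/level selects which intensity band is "counted" in the MI
#' histogram, and the informative band is soft tissue: a window spanning
#' the full acquisition range would quantize tissue heterogeneity into a
#' single bin and blind the cost inside the body. The CT window brackets
#' the soft-tissue HU band (bone and air clamp to the ends, keeping their
#' edges); the CBCT window brackets the image of that band under the
#' simulated monotone intensity remap.
#'
#' @return A [parameter_set()] tuned to the phantom intensity ranges.
#' @param ... overrides forwarded to [parameter_set()].
#' @export
phantom_parameters <- function(...) {
  defaults <- list(ref_window = window_level(500, 1300),
                   flt_window = window_level(-300, 400),
                   global_ref_window = window_level(0, 2000),
                   global_flt_window = window_level(-1000, 1000))
  args <- utils::modifyList(defaults, list(...))
  do.call(parameter_set, args)
}
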