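test_that("apply_transform matches closed forms", {
  p <- c(3, -4, 5)
  expect_equal(apply_transform(identity_transform(), p), p)
  expect_equal(apply_transform(rigid_transform(translation = c(1, 2, 3)),
                               c(0, 0, 0)), c(1, 2, 3))
  T90 <- rotation_about_z(90)
  expect_equal(apply_transform(T90, c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-9)
  # rotation about a non-origin center
  Tc <- rotation_about_z(90, center = c(1, 1, 0))
  expect_equal(apply_transform(Tc, c(2, 1, 0)), c(1, 2, 0), tolerance = 1e-9)
  expect_error(rigid_transform(c(1, 1, 0, 0)), "unit quaternion")
})

test_that("compose/invert/recenter satisfy the group laws", {
  expect_equal(apply_transform(compose(identity_transform(),
                                       rotation_about_z(30)), c(1, 2, 3)),
               apply_transform(rotation_about_z(30), c(1, 2, 3)))
  Tinv <- invert(rigid_transform(translation = c(4, -1, 2)))
  expect_equal(Tinv$translation, c(-4, 1, -2))
  set.seed(23)
  worst <- 0
  for (i in 1:200) {
    q1 <- vsreg:::quat_normalize(rnorm(4)); q2 <- vsreg:::quat_normalize(rnorm(4))
    T1 <- rigid_transform(q1, rnorm(3, 0, 10), rnorm(3, 0, 10))
    T2 <- rigid_transform(q2, rnorm(3, 0, 10), rnorm(3, 0, 10))
    p <- rnorm(3, 0, 50)
    worst <- max(worst,
      abs(apply_transform(compose(T2, T1), p) -
            apply_transform(T2, apply_transform(T1, p))),
      abs(apply_transform(compose(T1, invert(T1)), p) - p),
      abs(apply_transform(recenter(T1, rnorm(3)), p) - apply_transform(T1, p)))
  }
  expect_lt(worst, 1e-9)
})

test_that("Euler/quaternion conversion round-trips away from gimbal lock", {
  set.seed(24)
  for (i in 1:50) {
    ang <- runif(3, -70, 70) * pi / 180
    q <- vsreg:::euler_to_quat(ang[1], ang[2], ang[3])
    expect_lt(max(abs(vsreg:::quat_to_euler(q) - ang)), 1e-9)
  }
})

test_that("downhill simplex finds quadratic and bound-constrained optima", {
  fit <- downhill_simplex(function(x) (x - 3)^2, 0, step = 1)
  expect_lt(abs(fit$par - 3), 1e-4)
  expect_true(fit$converged)

  fit2 <- downhill_simplex(function(p) p[1]^2 + p[2]^2, c(3, 3), step = 1,
                           lower = c(1, -5), upper = c(5, 5))
  expect_lt(abs(fit2$par[1] - 1), 1e-4)   # active bound
  expect_lt(abs(fit2$par[2]), 1e-3)

  expect_error(downhill_simplex(function(x) NaN, 0), "non-finite")
})

test_that("simplex beats a dense grid-search oracle on a curved 3D bowl", {
  rosen <- function(p) {
    100 * (p[2] - p[1]^2)^2 + (1 - p[1])^2 + (p[3] - 1)^2
  }
  # dense grid-search oracle over [-2, 2]^3
  gr <- seq(-2, 2, by = 0.1)
  g <- expand.grid(x = gr, y = gr, z = gr)
  v <- 100 * (g$y - g$x^2)^2 + (1 - g$x)^2 + (g$z - 1)^2
  gridarg <- as.numeric(g[which.min(v), ])
  best <- gridarg  # oracle optimum; agrees with the analytic (1, 1, 1)
  expect_lt(sum(abs(gridarg - c(1, 1, 1))), 1e-9)
  starts <- list(c(0, 0, 0), c(-1, 1, 0), c(2, -2, 2), c(0.5, 2, -1), c(-2, -2, -2))
  for (s in starts) {
    fit <- downhill_simplex(rosen, s, step = 0.5,
                            settings = simplex_settings(tol = 1e-10,
                                                        max_iter = 500L,
                                                        restarts = 3L))
    expect_lt(max(abs(fit$par - best)), 1e-2)
  }
})

test_that("self-registration from identity stays near identity", {
  pair <- small_pair()
  params <- phantom_parameters()
  ref <- preprocess_volume(pair$reference, params$ref_window)
  tr <- rigid_register(ref, ref, max_disp = 20, n_bins = 64, stride = 2)
  expect_true(attr(tr, "refined"))
  expect_lt(sqrt(sum(tr$translation^2)), 0.2 * max(ref$spacing))
  expect_lt(rotation_error_deg(tr, identity_transform()), 0.2)
  expect_gte(attr(tr, "mi_final"), attr(tr, "mi_init") - 1e-12)
})

test_that("known shift and rotation are recovered through the modality gap", {
  spec <- phantom_spec(dims = c(64L, 64L, 64L), spacing = c(1, 1, 1),
                       seed = 7, deform_amplitude = 0,
                       rigid_translation = c(4, 0, 0), rigid_rotation_deg = 5)
  pair <- cached("rigidpair", make_pair(spec))
  params <- phantom_parameters()
  # global-stage configuration: wide windows for coarse alignment
  ref <- preprocess_volume(pair$reference, params$global_ref_window)
  flt <- preprocess_volume(pair$floating, params$global_flt_window)
  tr <- rigid_register(ref, flt, max_disp = 50, n_bins = 64, stride = 2)
  truth <- rigid_transform(vsreg:::euler_to_quat(0, 0, 5 * pi / 180),
                           c(4, 0, 0), center = c(31.5, 31.5, 31.5))
  expect_lt(max(abs(tr$translation - c(4, 0, 0))), 0.5)      # 0.5 voxel @ 1 mm
  expect_lt(rotation_error_deg(tr, truth), 1)
})

test_that("the max_disp cap is honored on every call", {
  pair <- small_pair()
  params <- phantom_parameters()
  ref <- preprocess_volume(pair$reference, params$ref_window)
  flt <- preprocess_volume(pair$floating, params$flt_window)
  for (cap in c(0.5, 1, 3)) {
    tr <- rigid_register(ref, flt, region = list(lo = c(8L, 8L, 4L),
                                                 hi = c(32L, 32L, 16L)),
                         max_disp = cap, n_bins = 32, stride = 1)
    ctr <- voxel_to_physical(ref, (c(8, 8, 4) + c(32, 32, 16) - 1) / 2)
    disp <- sqrt(sum((apply_transform(tr, ctr) - ctr)^2))
    expect_lte(disp, cap + 1e-6)
  }
})

test_that("insufficient overlap returns the initialization, flagged", {
  pair <- small_pair()
  params <- phantom_parameters()
  ref <- preprocess_volume(pair$reference, params$ref_window)
  flt <- preprocess_volume(pair$floating, params$flt_window)
  far <- rigid_transform(translation = c(500, 0, 0))
  tr <- rigid_register(ref, flt, init = far, max_disp = 5)
  expect_false(attr(tr, "refined"))
  expect_equal(tr$translation, far$translation)
})
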