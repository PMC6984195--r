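geom <- list(dims = c(20L, 20L, 12L), spacing = c(1.5, 1.5, 3), origin = c(0, 0, 0))

control_grid <- function(transforms, gdims, geometry = geom) {
  # regular grid of cell centers covering the geometry
  cell <- geometry$dims / gdims * geometry$spacing
  centers <- as.matrix(expand.grid(
    x = (seq_len(gdims[1]) - 0.5) * cell[1] - geometry$spacing[1] / 2,
    y = (seq_len(gdims[2]) - 0.5) * cell[2] - geometry$spacing[2] / 2,
    z = (seq_len(gdims[3]) - 0.5) * cell[3] - geometry$spacing[3] / 2))
  n <- prod(gdims)
  quats <- matrix(0, n, 4); bvecs <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    T <- if (length(transforms) == 1L) transforms[[1]] else transforms[[i]]
    Rb <- vsreg:::rigid_to_Rb(T)
    quats[i, ] <- Rb$q
    bvecs[i, ] <- as.numeric(Rb$b)
  }
  list(dims = gdims, centers = centers, quats = quats, bvecs = bvecs)
}

test_that("constant control grids reproduce rigid motion exactly", {
  # identity
  f0 <- interpolate_field(control_grid(list(identity_transform()), c(2L, 2L, 2L)),
                          geom)
  expect_lt(max(abs(f0$u)), 1e-12)
  # pure translation: partition of unity makes it exact
  Tt <- rigid_transform(translation = c(2.5, -1, 4))
  ft <- interpolate_field(control_grid(list(Tt), c(3L, 3L, 2L)), geom)
  expect_lt(max(abs(ft$u[, , , 1] - 2.5)), 1e-9)
  expect_lt(max(abs(ft$u[, , , 2] + 1)), 1e-9)
  expect_lt(max(abs(ft$u[, , , 3] - 4)), 1e-9)
  # shared rotation about a common center
  Tr <- rotation_about_z(7, center = c(14, 14, 18))
  fr <- interpolate_field(control_grid(list(Tr), c(2L, 2L, 2L)), geom)
  idx <- as.matrix(expand.grid(i = 0:19, j = 0:19, k = 0:11))
  pts <- sweep(sweep(idx, 2, geom$spacing, "*"), 2, geom$origin, "+")
  expected <- apply_transform(Tr, pts) - pts
  got <- cbind(as.numeric(fr$u[, , , 1]), as.numeric(fr$u[, , , 2]),
               as.numeric(fr$u[, , , 3]))
  expect_lt(max(abs(got - expected)), 1e-6)
})

test_that("flipping a control quaternion's sign leaves the field unchanged", {
  set.seed(25)
  transforms <- lapply(1:8, function(i)
    rigid_transform(vsreg:::euler_to_quat(rnorm(1, 0, 0.05), rnorm(1, 0, 0.05),
                                          rnorm(1, 0, 0.05)),
                    rnorm(3, 0, 2), center = c(14, 14, 18)))
  g <- control_grid(transforms, c(2L, 2L, 2L))
  f1 <- interpolate_field(g, geom)
  g$quats[3, ] <- -g$quats[3, ]
  f2 <- interpolate_field(g, geom)
  expect_equal(f1$u, f2$u, tolerance = 1e-12)
})

test_that("incomplete leaf grids are refused", {
  g <- control_grid(list(identity_transform()), c(2L, 2L, 2L))
  g$centers <- g$centers[-1, ]
  expect_error(interpolate_field(g, geom), "incomplete")
})

test_that("warp implements backward trilinear resampling", {
  v <- random_volume(c(20, 20, 12), spacing = c(1.5, 1.5, 3), seed = 26)
  zero <- deformation_field(array(0, c(20, 20, 12, 3)), v$spacing, v$origin)
  expect_equal(warp(v, zero)$data, v$data)
  # one-voxel shift along x
  u <- array(0, c(20, 20, 12, 3)); u[, , , 1] <- v$spacing[1]
  sh <- warp(v, deformation_field(u, v$spacing, v$origin), fill = -1)
  expect_equal(sh$data[1:19, , ], v$data[2:20, , ])
  expect_true(all(sh$data[20, , ] == -1))
})

test_that("jacobian_min detects compression analytically", {
  zero <- deformation_field(array(0, c(10, 10, 10, 3)), c(1, 1, 1), c(0, 0, 0))
  expect_equal(jacobian_min(zero), 1)
  u <- array(0, c(10, 10, 10, 3)); u[, , , 2] <- 3
  expect_equal(jacobian_min(deformation_field(u, c(1, 1, 1), c(0, 0, 0))), 1)
  # linear compression u_x = -0.5 x: det(I + du/dx) = 0.5
  x <- (0:9) * 1.0
  uc <- array(0, c(10, 10, 10, 3))
  uc[, , , 1] <- array(rep(-0.5 * x, 100), c(10, 10, 10))
  expect_equal(jacobian_min(deformation_field(uc, c(1, 1, 1), c(0, 0, 0))), 0.5,
               tolerance = 1e-12)
})

test_that("transform_point interpolates and guards the extent", {
  set.seed(27)
  u <- array(rnorm(10 * 10 * 10 * 3), c(10, 10, 10, 3))
  f <- deformation_field(u, c(2, 2, 2), c(10, 0, 0))
  # exact at a voxel center
  p <- c(10 + 2 * 3, 2 * 4, 2 * 5)
  expect_equal(transform_point(f, p), p + u[4, 5, 6, ])
  # constant field anywhere
  uc <- array(2, c(10, 10, 10, 3))
  fc <- deformation_field(uc, c(2, 2, 2), c(0, 0, 0))
  expect_equal(transform_point(fc, c(3.7, 8.1, 11.9)), c(5.7, 10.1, 13.9))
  expect_error(transform_point(f, c(-5, 0, 0)), "outside")
  expect_error(deformation_field(array(NA_real_, c(2, 2, 2, 3)), c(1, 1, 1),
                                 c(0, 0, 0)), "finite")
})

test_that("rigid_field matches the closed-form motion of its transform", {
  T <- rigid_transform(vsreg:::euler_to_quat(0.02, -0.01, 0.05), c(1, 2, -1),
                       center = c(10, 10, 10))
  f <- rigid_field(T, geom)
  idx <- as.matrix(expand.grid(i = 0:19, j = 0:19, k = 0:11))
  pts <- sweep(sweep(idx, 2, geom$spacing, "*"), 2, geom$origin, "+")
  expected <- apply_transform(T, pts) - pts
  got <- cbind(as.numeric(f$u[, , , 1]), as.numeric(f$u[, , , 2]),
               as.numeric(f$u[, , , 3]))
  expect_lt(max(abs(got - expected)), 1e-6)
})
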