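test_that("phantom generation is bit-deterministic under a seed", {
  s <- small_spec(41)
  a <- make_ct_phantom(s)
  b <- make_ct_phantom(s)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$landmarks, b$landmarks)
  pa <- make_pair(s); pb <- make_pair(s)
  expect_identical(pa$reference$data, pb$reference$data)
  expect_identical(pa$truth_field$u, pb$truth_field$u)
  # different seeds give different layouts with the same statistical profile
  pc <- make_ct_phantom(small_spec(42))
  expect_false(identical(a$volume$data, pc$volume$data))
  expect_equal(range(a$volume$data)[1], -1000)
})

test_that("landmark bookkeeping follows n_structures", {
  none <- make_ct_phantom(small_spec(43, n_structures = 0L))
  expect_equal(nrow(none$landmarks), 0L)
  expect_true(all(none$volume$data <= 200))   # no bone without structures
  five <- make_ct_phantom(small_spec(44, n_structures = 5L))
  expect_equal(nrow(five$landmarks), 5L)
})

test_that("simulate_cbct is monotone but deliberately not affine", {
  ct <- make_ct_phantom(small_spec(45))$volume
  cb <- simulate_cbct(ct, seed = 1, noise = FALSE, ramp = FALSE)
  x <- as.numeric(ct$data); y <- as.numeric(cb$data)
  ord <- order(x)
  expect_true(all(diff(y[ord]) >= -1e-9))     # rank order preserved
  # the joint relation is a curve, not a line: linear fit leaves structure
  fit <- lm(y ~ x)
  expect_gt(summary(fit)$sigma, 10)
  expect_gt(cor(x, y, method = "spearman"), 0.999)
})

test_that("the modality gap preserves MI against a shuffled control", {
  ct <- make_ct_phantom(small_spec(46))$volume
  cb <- simulate_cbct(ct, seed = 2)
  wl_ct <- window_level(-1000, 1000)
  wl_cb <- window_level(0, 2000)
  a <- as.numeric(window_level_rescale(ct, wl_ct)$data)
  b <- as.numeric(window_level_rescale(cb, wl_cb)$data)
  set.seed(3)
  b_shuf <- sample(b)
  mi_real <- mutual_information(build_joint_histogram(a, b, 32L))
  mi_shuf <- mutual_information(build_joint_histogram(a, b_shuf, 32L))
  expect_gt(mi_real, mi_shuf + 0.5)
})

test_that("ground-truth fields honor amplitude, rigid part and topology", {
  z <- make_ground_truth_field(small_spec(47, deform_amplitude = 0,
                                          rigid_translation = c(0, 0, 0)))
  expect_lt(max(abs(z$u)), 1e-12)

  rig <- small_spec(48, deform_amplitude = 0, rigid_translation = c(2, -1, 3),
                    rigid_rotation_deg = 4)
  fr <- make_ground_truth_field(rig)
  co <- vsreg:::phantom_coords(rig)
  T <- rigid_transform(vsreg:::euler_to_quat(0, 0, 4 * pi / 180), c(2, -1, 3),
                       center = co$center)
  p <- c(30, 40, 36)
  expect_equal(transform_point(fr, p), apply_transform(T, p), tolerance = 1e-6)

  f6 <- make_ground_truth_field(small_spec(49, deform_amplitude = 6,
                                           rigid_translation = c(0, 0, 0)))
  mag <- sqrt(f6$u[, , , 1]^2 + f6$u[, , , 2]^2 + f6$u[, , , 3]^2)
  expect_gte(max(mag), 5.4)
  expect_lte(max(mag), 6.0 + 1e-9)
  expect_gt(jacobian_min(f6), 0.2)
})

test_that("pair construction gives consistent landmark correspondences", {
  pair <- small_pair(21)
  lms <- pair$landmarks
  expect_gt(nrow(lms), 0L)
  ref_pts <- as.matrix(lms[, c("ref_x", "ref_y", "ref_z")])
  ct_pts <- as.matrix(lms[, c("ct_x", "ct_y", "ct_z")])
  # applying the true field to the reference-space landmark recovers the CT
  # landmark: ground-truth landmark error is 0 by construction
  mapped <- transform_point(pair$truth_field, ref_pts)
  expect_lt(max(abs(mapped - ct_pts)), 1e-6)
  # baseline landmark error equals the true displacement magnitude
  base <- landmark_error(lms)
  u <- mapped - ref_pts
  expect_equal(as.numeric(base), mean(sqrt(rowSums(u^2))), tolerance = 1e-9)
  expect_equal(as.numeric(landmark_error(lms, pair$truth_field)), 0,
               tolerance = 1e-6)
})

test_that("truth fields of default-size phantoms never fold", {
  for (sd in c(1, 5)) {
    f <- make_ground_truth_field(phantom_spec(seed = sd))
    expect_gt(jacobian_min(f), 0.2)
  }
})
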