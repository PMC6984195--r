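test_that("subdivide produces 8, 4, or no children per the z-rate rule", {
  root <- subvolume_node(c(0L, 0L, 0L), c(64L, 64L, 64L))
  kids <- subdivide(root, z_rate = 0L, min_subvolume = c(16L, 16L, 8L))
  expect_length(kids, 8L)
  expect_true(all(vapply(kids, function(k) all(k$hi - k$lo == 32L), logical(1))))
  expect_true(all(vapply(kids, function(k) k$level == 1L, logical(1))))

  kids4 <- subdivide(root, z_rate = 1L, min_subvolume = c(16L, 16L, 8L))
  expect_length(kids4, 4L)  # initial volume into four subvolumes, z unsplit
  expect_true(all(vapply(kids4, function(k)
    all(k$hi - k$lo == c(32L, 32L, 64L)), logical(1))))

  # the canonical threshold: a 16 x 16 x 8 node is never split
  leafy <- subvolume_node(c(0L, 0L, 0L), c(16L, 16L, 8L))
  expect_length(subdivide(leafy, 0L, c(16L, 16L, 8L)), 0L)
  inner <- root
  inner$children <- kids
  expect_error(subdivide(inner), "not a leaf")
})

test_that("children partition the parent exactly, including odd extents", {
  for (dims in list(c(64L, 64L, 64L), c(33L, 17L, 9L), c(10L, 11L, 12L))) {
    node <- subvolume_node(c(0L, 0L, 0L), dims)
    kids <- subdivide(node, 0L, min_subvolume = c(2L, 2L, 2L))
    if (length(kids) == 0L) next
    # exhaustive voxel-membership check
    seen <- array(0L, dims)
    for (k in kids)
      seen[(k$lo[1] + 1):k$hi[1], (k$lo[2] + 1):k$hi[2], (k$lo[3] + 1):k$hi[3]] <-
        seen[(k$lo[1] + 1):k$hi[1], (k$lo[2] + 1):k$hi[2], (k$lo[3] + 1):k$hi[3]] + 1L
    expect_true(all(seen == 1L))
    # floor midpoints: sibling extents differ by at most one voxel per axis
    ext <- t(vapply(kids, function(k) k$hi - k$lo, integer(3)))
    expect_true(all(apply(ext, 2, function(e) diff(range(e))) <= 1L))
  }
})

test_that("children inherit the parent transform", {
  node <- subvolume_node(c(0L, 0L, 0L), c(32L, 32L, 32L),
                         transform = rigid_transform(translation = c(1, 2, 3)))
  kids <- subdivide(node, 0L, c(4L, 4L, 4L))
  for (k in kids) expect_equal(k$transform$translation, c(1, 2, 3))
})

test_that("max_displacement_bound follows the flexibility formula", {
  node <- subvolume_node(c(0L, 0L, 0L), c(32L, 32L, 32L))
  expect_equal(max_displacement_bound(node, c(1, 1, 1), 1), 12.8)
  expect_equal(max_displacement_bound(node, c(1, 1, 1), 0.5), 6.4)
  child <- subvolume_node(c(0L, 0L, 0L), c(16L, 16L, 16L))
  expect_equal(max_displacement_bound(child, c(1, 1, 1), 1), 6.4)
  # anisotropic spacing: the smallest physical extent governs
  expect_equal(max_displacement_bound(node, c(1.5, 1.5, 3), 1),
               0.4 * 32 * 1.5)
  expect_error(max_displacement_bound(node, c(1, 1, 1), 0), "flexibility")
})

test_that("octree level structure matches the closed-form counts", {
  pair <- small_pair()
  params <- phantom_parameters()
  hier <- cached("hier21", hierarchical_register(pair$reference, pair$floating,
                                                 params))
  # 48x48x24 with min 16x16x8: exactly one split -> 8 leaves on a 2x2x2 grid
  expect_equal(hier$levels, 1L)
  expect_equal(hier$n_leaves, 8L)
  expect_equal(hier$leaf_grid$dims, c(2L, 2L, 2L))
  leaves <- collect_leaves(hier$root)
  expect_length(leaves, 8L)
  # z_rate 1: first level splits in-plane only -> 4 leaves
  hier4 <- hierarchical_register(pair$reference, pair$floating,
                                 phantom_parameters(z_rate = 1L))
  expect_equal(hier4$n_leaves, 4L)
  expect_equal(hier4$leaf_grid$dims, c(2L, 2L, 1L))
})

test_that("null registration stays within a fraction of a voxel", {
  pair <- small_pair()
  params <- phantom_parameters()
  ref <- preprocess_volume(pair$reference, params$ref_window)
  hier <- hierarchical_register(ref, ref, params, preprocessed = TRUE)
  g <- hier$leaf_grid
  worst <- 0
  for (i in seq_len(nrow(g$centers))) {
    ctr <- g$centers[i, ]
    est <- as.numeric(vsreg:::quat_to_matrix(g$quats[i, ]) %*% ctr +
                        g$bvecs[i, ]) - ctr
    worst <- max(worst, sqrt(sum((est / ref$spacing)^2)))
  }
  expect_lt(worst, 0.3)
  field <- interpolate_field(hier)
  mag_vox <- sqrt((field$u[, , , 1] / ref$spacing[1])^2 +
                  (field$u[, , , 2] / ref$spacing[2])^2 +
                  (field$u[, , , 3] / ref$spacing[3])^2)
  expect_lt(max(mag_vox), 0.5)
})

test_that("per-leaf displacement obeys the bound relative to the parent", {
  pair <- small_pair()
  hier <- cached("hier21", hierarchical_register(pair$reference, pair$floating,
                                                 phantom_parameters()))
  walk <- function(node) {
    for (ch in node$children) {
      ctr <- voxel_to_physical(pair$reference, (ch$lo + ch$hi - 1) / 2)
      predicted <- apply_transform(node$transform, ctr)
      refined <- apply_transform(ch$transform, ctr)
      bound <- max_displacement_bound(ch, pair$reference$spacing,
                                      phantom_parameters()$flexibility)
      expect_lte(sqrt(sum((refined - predicted)^2)), bound + 1e-6)
      walk(ch)
    }
  }
  walk(hier$root)
})

test_that("leaf refinement never accepts a worse cost than its start", {
  pair <- small_pair()
  hier <- cached("hier21", hierarchical_register(pair$reference, pair$floating,
                                                 phantom_parameters()))
  walk <- function(node) {
    tr <- node$transform
    if (!is.null(attr(tr, "mi_init")))
      expect_gte(attr(tr, "mi_final"), attr(tr, "mi_init") - 1e-12)
    for (ch in node$children) walk(ch)
  }
  walk(hier$root)
})

test_that("hierarchical registration is deterministic", {
  pair <- small_pair()
  h1 <- cached("hier21", hierarchical_register(pair$reference, pair$floating,
                                               phantom_parameters()))
  h2 <- hierarchical_register(pair$reference, pair$floating,
                              phantom_parameters())
  expect_identical(h1$leaf_grid$quats, h2$leaf_grid$quats)
  expect_identical(h1$leaf_grid$bvecs, h2$leaf_grid$bvecs)
})

test_that("parameter_set validates its invariants", {
  expect_error(parameter_set(flexibility = 0), "flexibility")
  expect_error(parameter_set(min_subvolume = c(1L, 4L, 4L)), "min_subvolume")
  expect_error(parameter_set(z_rate = -1L), "z_rate")
  p <- parameter_set(name = "custom", flexibility = 2)
  expect_equal(p$flexibility, 2)
  expect_equal(p$name, "custom")
})
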