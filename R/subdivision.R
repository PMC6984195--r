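#' Registration parameter set
#'
#' The four tunables with the largest expected influence on CT-CBCT
#' deformable registration, plus solver settings: (1) window/level per image
#' role, (2) minimum subvolume size at which subdivision stops, (3) degree
#' of flexibility (how far subvolumes may move per level), and (4) the
#' z-subdivision rate (how many initial octree levels skip splitting along
#' the superior-inferior axis so subvolumes stay near-cubic).
#'
#' @param ref_window,flt_window [window_level()]s applied to the reference
#'   (CBCT) and floating (CT) images for subvolume refinement. Defaults map
#'   a CBCT-number-like and a soft-tissue CT range into `[0, 255]`.
#' @param global_ref_window,global_flt_window optional wider windows for the
#'   initial whole-volume rigid stage (`NULL` = same as the role windows).
#'   Coarse alignment is driven by bone/air topology and is more robust
#'   under a wide window, while fine subvolume stages need the soft-tissue
#'   band spread across the histogram.
#' @param min_subvolume per-axis voxel threshold (each >= 2) below which a
#'   node is not split; default 16 x 16 x 8.
#' @param flexibility positive scalar; larger values allow subvolumes more
#'   freedom to move (see [max_displacement_bound()]).
#' @param z_rate number of initial levels that split only in x and y.
#' @param smooth apply Gaussian smoothing during preprocessing.
#' @param detrend_z locally stationarize reference samples along z inside
#'   every MI region (see [rigid_register()]); counteracts cone-beam axial
#'   shading at the cost of discarding genuine axial contrast. Off by
#'   default.
#' @param equalize rank (equalized) binning of region samples (see
#'   [rigid_register()]); on by default.
#' @param n_bins_global,n_bins_subvolume histogram bins; the smaller count is
#'   used for subvolumes under `small_subvolume_voxels` voxels, where a dense
#'   joint histogram would be hopelessly sparse.
#' @param global_max_disp displacement cap (mm) for the initial whole-volume
#'   rigid stage.
#' @param global_stride,level_stride voxel sampling strides for the global
#'   stage and for subvolume refinement (1 = full resolution).
#' @param max_region_samples cap on MI samples per subvolume: the effective
#'   stride is raised above `level_stride` for regions with more voxels than
#'   this, keeping per-level cost bounded without touching small subvolumes.
#' @param simplex a [simplex_settings()]; steps are halved at each
#'   subdivision level.
#' @param small_subvolume_voxels effective-sample-count threshold below
#'   which the reduced bin count is used (a 64 x 64 joint histogram needs
#'   on the order of 10^4 samples to be usably dense).
#' @param name optional label used in sweep/batch result tables.
#' @return A `vs_params` list.
#' @export
parameter_set <- function(ref_window = window_level(0, 2000),
                          flt_window = window_level(-1000, 1000),
                          global_ref_window = NULL,
                          global_flt_window = NULL,
                          min_subvolume = c(16L, 16L, 8L),
                          flexibility = 1.0,
                          z_rate = 0L,
                          smooth = TRUE,
                          detrend_z = TRUE,
                          equalize = FALSE,
                          n_bins_global = 64L,
                          n_bins_subvolume = 32L,
                          global_max_disp = 50,
                          global_stride = 2L,
                          level_stride = 1L,
                          max_region_samples = 32768L,
                          simplex = simplex_settings(),
                          small_subvolume_voxels = 16384L,
                          name = "default") {
  min_subvolume <- as.integer(rep_len(min_subvolume, 3))
  if (any(min_subvolume < 2L)) stop("`min_subvolume` must be >= 2 per axis")
  if (!is.finite(flexibility) || flexibility <= 0)
    stop("`flexibility` must be > 0")
  if (z_rate < 0L) stop("`z_rate` must be >= 0")
  structure(list(ref_window = ref_window, flt_window = flt_window,
                 global_ref_window = global_ref_window,
                 global_flt_window = global_flt_window,
                 min_subvolume = min_subvolume,
                 flexibility = as.numeric(flexibility),
                 z_rate = as.integer(z_rate), smooth = isTRUE(smooth),
                 detrend_z = isTRUE(detrend_z),
                 equalize = isTRUE(equalize),
                 n_bins_global = as.integer(n_bins_global),
                 n_bins_subvolume = as.integer(n_bins_subvolume),
                 global_max_disp = as.numeric(global_max_disp),
                 global_stride = as.integer(global_stride),
                 level_stride = as.integer(level_stride),
                 max_region_samples = as.integer(max_region_samples),
                 simplex = simplex,
                 small_subvolume_voxels = as.integer(small_subvolume_voxels),
                 name = as.character(name)),
            class = "vs_params")
}

#' Octree subvolume node
#'
#' @param lo,hi 0-based half-open voxel index bounds per axis on the
#'   reference grid.
#' @param level subdivision level (root = 0).
#' @param transform the node's cumulative [rigid_transform()].
#' @return A `vs_subvolume` list with fields `level`, `lo`, `hi`,
#'   `transform`, `children` (possibly empty), `cell` (position in the leaf
#'   grid at its level).
#' @export
subvolume_node <- function(lo, hi, level = 0L, transform = identity_transform()) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (any(hi <= lo)) stop("subvolume bounds must be non-empty (half-open)")
  structure(list(level = as.integer(level), lo = lo, hi = hi,
                 transform = transform, children = list(),
                 cell = c(0L, 0L, 0L), refined = NA),
            class = "vs_subvolume")
}

#' Split a leaf subvolume into 8 (or 4) children
#'
#' Each axis splits at the integer midpoint (floor), so odd extents produce
#' children differing by one voxel. While `node$level < z_rate` the z axis is
#' left unsplit, yielding 4 children instead of 8 (keeps subvolumes
#' near-cubic when slices are thick). Children inherit the parent's
#' transform as their initial transform. Returns an empty list -- no split --
#' if any child would fall below `min_subvolume` on any split axis.
#'
#' @param node a leaf [subvolume_node()].
#' @param z_rate number of initial levels that do not divide along z.
#' @param min_subvolume per-axis voxel threshold.
#' @return List of 0, 4, or 8 child nodes.
#' @export
subdivide <- function(node, z_rate = 0L, min_subvolume = c(16L, 16L, 8L)) {
  if (length(node$children) > 0L) stop("subdivide: node is not a leaf")
  min_subvolume <- as.integer(rep_len(min_subvolume, 3))
  split_z <- node$level >= z_rate
  axes <- if (split_z) 1:3 else 1:2
  ext <- node$hi - node$lo
  for (a in axes) {
    if (ext[a] %/% 2L < min_subvolume[a]) return(list())
  }
  cuts <- lapply(1:3, function(a) {
    if (a %in% axes) {
      mid <- node$lo[a] + ext[a] %/% 2L
      list(c(node$lo[a], mid), c(mid, node$hi[a]))
    } else list(c(node$lo[a], node$hi[a]))
  })
  children <- list()
  for (kz in seq_along(cuts[[3]]))
    for (ky in seq_along(cuts[[2]]))
      for (kx in seq_along(cuts[[1]])) {
        ch <- subvolume_node(
          lo = c(cuts[[1]][[kx]][1], cuts[[2]][[ky]][1], cuts[[3]][[kz]][1]),
          hi = c(cuts[[1]][[kx]][2], cuts[[2]][[ky]][2], cuts[[3]][[kz]][2]),
          level = node$level + 1L, transform = node$transform)
        ch$cell <- c(2L * node$cell[1] + kx - 1L,
                     2L * node$cell[2] + ky - 1L,
                     if (split_z) 2L * node$cell[3] + kz - 1L else node$cell[3])
        children[[length(children) + 1L]] <- ch
      }
  children
}

#' Maximum allowable displacement for a subdivision level
#'
#' The hard constraint that keeps subvolume refinement from creating
#' image-folding artifacts: a subvolume may move its center at most
#' `flexibility * 0.4 * (smallest physical extent of the node)` mm relative
#' to its parent's prediction. Monotone in both flexibility and subvolume
#' size, so deeper (smaller) levels are progressively more constrained.
#'
#' @param node a [subvolume_node()].
#' @param spacing reference voxel spacing, mm.
#' @param flexibility positive scalar (parameter 3 of the sweep).
#' @return Displacement bound in mm.
#' @export
max_displacement_bound <- function(node, spacing, flexibility = 1.0) {
  if (!is.finite(flexibility) || flexibility <= 0)
    stop("`flexibility` must be > 0")
  ext_mm <- (node$hi - node$lo) * spacing
  flexibility * 0.4 * min(ext_mm)
}

#' Hierarchical volume-subdivision registration
#'
#' The full locally-rigid, globally-nonrigid engine: (1) a global rigid
#' registration of the whole (preprocessed) reference against the floating
#' image; (2) breadth-first over octree levels, every current leaf is split
#' ([subdivide()]) and each child is rigidly refined by MI ([rigid_register()])
#' starting from its parent's transform, with the displacement cap
#' [max_displacement_bound()]; (3) subdivision stops when no leaf can split.
#' Leaves at a given level are independent, so any processing order gives
#' identical results.
#'
#' @param ref reference (CBCT-like) [vs_volume()], native intensities.
#' @param flt floating (CT-like) [vs_volume()] on the same grid.
#' @param params a [parameter_set()].
#' @param preprocessed set `TRUE` if `ref`/`flt` are already windowed to
#'   `[0, 255]` (skips [preprocess_volume()]).
#' @return A `vs_hierarchy` list: `root` (the octree), `leaf_grid` (regular
#'   3D grid of finest-level transforms with their region centers, the input
#'   to [interpolate_field()]), `global` (the global rigid transform),
#'   `levels`, `n_leaves`, `n_unrefined`.
#' @export
hierarchical_register <- function(ref, flt, params = parameter_set(),
                                  preprocessed = FALSE) {
  stopifnot_volume(ref); stopifnot_volume(flt)
  if (!all(ref$dims == flt$dims))
    stop("hierarchical_register: images must share a grid")
  if (!preprocessed) {
    ref_g <- if (!is.null(params$global_ref_window))
      preprocess_volume(ref, params$global_ref_window, params$smooth) else NULL
    flt_g <- if (!is.null(params$global_flt_window))
      preprocess_volume(flt, params$global_flt_window, params$smooth) else NULL
    ref <- preprocess_volume(ref, params$ref_window, params$smooth)
    flt <- preprocess_volume(flt, params$flt_window, params$smooth)
    if (is.null(ref_g)) ref_g <- ref
    if (is.null(flt_g)) flt_g <- flt
  } else {
    ref_g <- ref
    flt_g <- flt
  }
  nvox <- function(node) prod(node$hi - node$lo)
  stride_for <- function(node)
    max(params$level_stride,
        ceiling((nvox(node) / params$max_region_samples)^(1 / 3)))
  # Bin count keyed on the *effective sample count* (voxels after striding):
  # a 64 x 64 joint histogram needs on the order of 10^4 samples to be
  # usably dense, so sparse regions fall back to the coarse binning.
  bins_for <- function(node)
    if (nvox(node) / stride_for(node)^3 < params$small_subvolume_voxels)
      params$n_bins_subvolume else params$n_bins_global

  root <- subvolume_node(c(0L, 0L, 0L), ref$dims)
  root$transform <- rigid_register(
    ref_g, flt_g, region = list(lo = root$lo, hi = root$hi),
    init = identity_transform(), max_disp = params$global_max_disp,
    settings = params$simplex, n_bins = params$n_bins_global,
    # No detrend at the global stage: axial shading is V-shaped about the
    # central plane over the whole volume, so a linear fit would remove
    # anatomical contrast instead; the trend is only locally linear.
    stride = params$global_stride, detrend_z = FALSE,
    equalize = params$equalize)
  root$refined <- attr(root$transform, "refined")

  level_settings <- function(level) {
    s <- params$simplex
    s$trans_step <- s$trans_step / 2^(level - 1)
    s$rot_step <- s$rot_step / 2^(level - 1)
    s
  }
  refine_leaf <- function(node) {
    bound <- max_displacement_bound(node, ref$spacing, params$flexibility)
    stride <- stride_for(node)
    tr <- rigid_register(
      ref, flt, region = list(lo = node$lo, hi = node$hi),
      init = node$transform, max_disp = bound,
      settings = level_settings(node$level),
      n_bins = bins_for(node), stride = stride,
      # Residual rotation per subvolume after the global stage is small and
      # poorly identifiable against texture noise at this scale; an
      # unconstrained angle wanders ~2 deg and swings subvolume corners by
      # a voxel. Bound it like the displacement: tighter with depth.
      rot_bound_deg = 2 / node$level,
      reg_weight = 0.3 / params$flexibility, detrend_z = params$detrend_z,
      equalize = params$equalize)
    node$refined <- attr(tr, "refined")
    node$transform <- tr
    node
  }
  grow <- function(node) {
    children <- subdivide(node, params$z_rate, params$min_subvolume)
    if (length(children) == 0L) return(node)
    node$children <- lapply(children, function(ch) grow(refine_leaf(ch)))
    node
  }
  root <- grow(root)

  leaves <- collect_leaves(root)
  lv <- vapply(leaves, function(n) n$level, integer(1))
  if (length(unique(lv)) != 1L)
    stop("internal: leaves at mixed levels; grid assembly requires uniform depth")
  cells <- t(vapply(leaves, function(n) n$cell, integer(3)))
  gdims <- apply(cells, 2, max) + 1L
  centers <- matrix(0, nrow(cells), 3)
  quats <- matrix(0, length(leaves), 4)
  bvecs <- matrix(0, length(leaves), 3)
  ord <- order(cells[, 3], cells[, 2], cells[, 1])
  leaves <- leaves[ord]
  for (i in seq_along(leaves)) {
    n <- leaves[[i]]
    centers[i, ] <- voxel_to_physical(ref, (n$lo + n$hi - 1) / 2)
    Rb <- rigid_to_Rb(n$transform)
    quats[i, ] <- Rb$q
    bvecs[i, ] <- Rb$b
  }
  structure(list(root = root,
                 leaf_grid = list(dims = gdims, centers = centers,
                                  quats = quats, bvecs = bvecs),
                 global = root$transform, levels = max(lv),
                 n_leaves = length(leaves),
                 n_unrefined = sum(!vapply(leaves, function(n)
                   isTRUE(n$refined), logical(1))),
                 ref_geometry = list(dims = ref$dims, spacing = ref$spacing,
                                     origin = ref$origin)),
            class = "vs_hierarchy")
}

#' Collect the leaf nodes of a subdivision tree
#' @param node a [subvolume_node()] (typically the root).
#' @return List of leaf nodes, depth-first.
#' @export
collect_leaves <- function(node) {
  if (length(node$children) == 0L) return(list(node))
  do.call(c, lapply(node$children, collect_leaves))
}

#' @export
print.vs_hierarchy <- function(x, ...) {
  cat(sprintf("<vs_hierarchy> %d levels, %d finest leaves (%s grid), %d unrefined\n",
              x$levels, x$n_leaves, paste(x$leaf_grid$dims, collapse = "x"),
              x$n_unrefined))
  invisible(x)
}
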