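---
title: "Volume-subdivision deformable registration: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volume-subdivision deformable registration: model, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The registration model

`vsreg` registers a daily cone-beam CT (CBCT, the *reference*) with a
planning CT (the *floating* image) for radiotherapy monitoring. The two
modalities image the same anatomy but do not share an intensity scale: CBCT
numbers for a given tissue drift with position and acquisition, so
least-squares or correlation costs fail. The model is therefore **locally
rigid, globally nonrigid**:

1. **Preprocessing.** Each image is clamped to a preset window/level and
   mapped affinely into $[0, 255]$, then smoothed with a separable discrete
   Gaussian whose per-axis standard deviation equals one voxel spacing (in
   mm). Windowing decides which intensity band "counts" in the similarity
   histogram; smoothing suppresses reconstruction noise at the sub-voxel
   scale.
2. **Global rigid stage.** A 6-DOF rigid transform (3 Euler angles, 3
   translations) maximizing mutual information (MI) over the whole volume.
3. **Octree subdivision.** The reference grid is split into 8 equal
   subvolumes (4 while the z-subdivision rate defers splitting along the
   superior-inferior axis), each child inheriting its parent's transform
   and being refined by the same MI + downhill-simplex machinery. Splitting
   stops when a child would fall below the minimum subvolume size (default
   $16 \times 16 \times 8$ voxels).
4. **Dense field.** The finest-level rigid transforms, stored as unit
   quaternion + translation in the common "displace-$x$" form
   $y = R x + b$, are blended with separable Catmull--Rom cubic weights
   over the $4^3$ control neighborhood (sign-aligned quaternions,
   renormalized after blending). The displacement $u(x) = \hat R x + \hat b - x$
   is evaluated on every reference voxel. Because the cubic weights sum
   to one, a constant control grid (identity, pure translation, single
   rigid motion) is reproduced exactly.

The cost at every level is histogram MI in bits,
$\mathrm{MI} = \sum_{ij} p_{ij} \log_2 \frac{p_{ij}}{p_{i\cdot} p_{\cdot j}}$,
with bin index $\lfloor v \cdot n/256 \rfloor$ on the windowed scale. The
optimizer is a bound-constrained Nelder--Mead downhill simplex: every
candidate is projected into the feasible set *before* evaluation, so the
displacement caps below are hard guarantees, not penalties.

## Topology preservation

Each subvolume may move its center at most
$\mathrm{flexibility} \times 0.4 \times (\text{smallest physical extent})$
millimetres away from its parent's prediction. The factor 0.4 was chosen so
that, combined with the cubic interpolation kernel, adjacent-cell relative
displacements stay below the folding threshold; every synthetic-recovery
test asserts `jacobian_min(field) > 0` (minimum over interior voxels of
$\det(I + \nabla u)$ by central differences). A soft quadratic movement
penalty, $0.3/\mathrm{flexibility} \cdot (|\Delta t| / \text{cap})^2$ bits,
implements the regularization role of the flexibility parameter: it is
negligible against any genuine MI gradient but decisive against
estimator-noise optima far from the initialization. Subvolume *rotations*
are bounded at $2^\circ/\text{level}$: the residual rotation of a subvolume
after global alignment is small, and an unconstrained angle is not
identifiable against texture noise at the 30--40 mm scale (it wanders
$\pm 2^\circ$ and swings subvolume corners by a voxel while changing MI
within its noise floor).

## Estimator details that turned out to matter

These were added after the plain textbook estimator failed on the
package's own synthetic world; each is configurable and documented at
`rigid_register()`:

* **Jittered sampling** (`jitter = TRUE`). Exactly grid-aligned floating
  samples skip interpolation; everywhere else trilinear interpolation
  smooths the floating marginal and *inflates* estimated MI by ~0.1 bits
  (the classic MI interpolation artifact). Sampling at deterministically
  hashed sub-voxel offsets makes every candidate transform - including
  the initialization - off-grid, cancelling the bias from the comparison.
  With this fix, registering an image to itself returns the identity to
  machine precision.
* **Overlap weighting.** MI rises spuriously as overlap shrinks (fewer
  samples, sharper histogram), so the cost is $-\mathrm{MI} \times
  \text{valid fraction}$; a region with under 25% valid samples keeps its
  parent transform, flagged.
* **Symmetric local z-detrend** (`detrend_z = TRUE` for subvolume stages).
  Cone-beam reconstruction degrades intensity roughly linearly with axial
  distance from the central plane. Inside a subvolume this couples
  intensity to position and rivals soft-tissue contrast. Each side's
  samples are detrended against their own axial coordinate, with the
  slope capped at a plausible shading gradient (20% of range per 100 mm)
  so genuine anatomical contrast - which produces much steeper apparent
  trends - survives. A trend-free image fits slope ~0, making the
  operation symmetric in the two roles; the global stage never detrends
  because shading is V-shaped (not linear) over the whole axial range.
* **Homogeneity guard** (`min_ref_sd`). A region whose reference
  intensities have standard deviation under 2 (on the 0-255 scale) is air
  outside the patient; MI on its residual noise is a random walk, so the
  region keeps its initialization, flagged `refined = FALSE`.
* **Simplex restarts.** A single 150-iteration Nelder--Mead run in 6-D
  stalls short of the MI optimum (premature simplex collapse); the search
  re-initializes the simplex at the best point up to `restarts = 2` times,
  stopping early when a restart fails to improve.
* **Bin counts.** 64 bins per image at the global stage; 32 bins when a
  region's effective sample count (voxels after striding) is below 16384,
  because a $64^2$-cell joint histogram needs on the order of $10^4$
  samples to be usably dense. Regions larger than `max_region_samples`
  (32768) are strided to keep per-level cost bounded.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| window/level (ref, flt) | role-specific | native intensity | selects the band counted in MI; soft-tissue-focused for subvolumes |
| global window/level | wide | native intensity | coarse alignment is driven by bone/air topology, robust under a wide window |
| minimum subvolume size | 16 x 16 x 8 | voxels | subdivision stop; below ~1000 samples MI is statistically hopeless |
| flexibility | 1.0 | -- | scales the per-level displacement cap and (inversely) the movement penalty |
| z-subdivision rate | 0 | levels | skip z splits while subvolumes would become strongly non-cubic |
| simplex steps | 2 mm / 2 deg, halved per level | mm / deg | expected residual motion shrinks with subvolume size |
| convergence | rel. spread 1e-4, 150 iters/start, 2 restarts | -- | bounded runtime per subvolume |

The one-factor-at-a-time sweep (`default_sweep_sets()`, 12 sets) varies the
window (2 sets), minimum size (3), flexibility (4), and z-rate (2) around
the defaults; concrete values are package configuration, replaceable
wholesale by the user.

## Evaluation metrics

* **TRE.** The planning CT documents a dose-calculation point (CALC); the
  couch shift repositions the patient so that the CBCT-space CALC is
  `calc - couch_shift`. A correct registration maps it back:
  `TRE = |transform_point(field, calc - shift) - calc|` in mm.
* **3D SSIM.** Mean structural similarity over the CBCT field of view
  with $L = 255$, $C_1 = (0.01 L)^2$, $C_2 = (0.03 L)^2$, $C_3 = C_2/2$,
  Gaussian window $\sigma = 1.5$ voxels, radius 5. Exactly 1 iff the
  images agree; modality-tolerant because it compares local structure.
* **STRE (self-TRE).** Register forward (CBCT to CT) and reverse, map
  ~1000 seeded points $p$ in a 30 mm ball through forward then reverse,
  and average $|p - p'|$. The QA rule: pass iff mean STRE does not exceed
  the voxel size, read as the *maximum* spacing component (the most
  permissive axis, typically the 3 mm slice thickness); equality passes.
  On failure the batch executor re-runs with the next fallback parameter
  set, at most twice.

## The synthetic world

`phantom_spec()` generates CT-like/CBCT-like pairs with known ground truth;
no clinical data ships with the package. What it emulates, and what it does
not:

* **CT phantom**: air at -1000, a 3D ellipsoidal body (~0 HU) with smooth
  +/-60 HU low-frequency texture (fat/muscle/gland-scale contrast, 8 mm
  correlation length), and 10 randomized inclusions alternating bone-like
  (700) and soft (60), landmarks at their centroids. Default geometry
  96 x 96 x 48 voxels at 1.5 x 1.5 x 3.0 mm - the anisotropic,
  slice-thickness-limited geometry that motivates the z-rate parameter. An
  early cylindrical (z-invariant) body made z motion unidentifiable for
  *any* intensity-based method; the ellipsoid + texture restores the axial
  information real anatomy always carries.
* **CBCT simulation**: a monotone *non-affine* intensity remap
  ($2000 \cdot v^{0.6}$ on normalized HU) - so intensity-difference costs
  fail while MI succeeds - plus a linear axial shading ramp (15% at the
  axial edges) and Gaussian noise (sigma = 3% of range).
* **Ground truth**: a global rigid offset plus 2-4 Gaussian-bump
  displacements (18-26 mm scale) normalized so the grid peak equals the
  requested amplitude, auto-capped to keep `jacobian_min > 0.2`.
* **Not emulated**: Feldkamp reconstruction physics (scatter, beam
  hardening, streaks), truncated fields of view, real anatomical topology.
  A green recovery test therefore establishes that the estimator and the
  hierarchy work against modality gaps, shading, and noise of realistic
  magnitude - not that clinical accuracy equals the phantom accuracy.

On the default phantom with a 6 mm bump deformation plus 3 mm shift, the
pipeline reduces mean landmark error to roughly 0.15-0.45 of baseline
(typically ~0.2, about 1 mm) across seeds; the acceptance suite asserts
< 0.40 and < 2 voxels on three fixed seeds, and the forward/reverse mean
STRE passes the voxel-size QA rule.

## Batch execution

The queue/worker design decouples job description from execution: a client
enqueues one message per registration pair (inputs, parameter set, outputs);
each worker pops and executes until the queue is empty. Locally the worker
pool is `parallel` forks; results are invariant to worker count because
every job carries its own derived seed and jobs do not interact. A
completed-jobs ledger makes interrupted batches resumable; QA failures
re-enqueue with fallback parameters under a bounded retry budget. The
message schema retains the cloud payload fields so a remote queue/storage
adapter can be added without touching the executor.

## Degenerate inputs and numerical choices

* Oblique orientation matrices (NIfTI srow/qform, DICOM orientation) are
  rejected, not silently resampled; mixed-spacing DICOM series are
  rejected naming the field.
* Odd extents split at floor midpoints; sibling sizes differ by at most
  one voxel, and the leaf-grid interpolation treats cell centers as a
  regular lattice (exact for even dims, sub-voxel approximation
  otherwise).
* Quaternion blending sign-aligns to the containing cell's control before
  the weighted sum; a blended norm under 1e-12 falls back to that control.
* Boundary handling: control-grid replication at the image border; edge
  replication for all separable convolutions (no darkening at the FOV
  border that would bias MI).
* `compute_stre` discards points outside either field and errors below 10
  valid points; sampling is uniform in the ball via seeded rejection.
* Equality passes the QA rule (documented boundary convention).

## Known limitations

* Per-subvolume rotation is nearly unidentifiable at the finest scale; the
  2 deg/level bound is a pragmatic identifiability constraint, not a
  physical prior.
* The leaf grid must be complete and uniform-depth; image dimensions that
  stop subdivision at different depths per octant are rejected rather than
  blended across levels.
* MI sampling, binning and overlap policy are estimator choices isolated
  behind configuration; none is claimed optimal.
* No diffeomorphic parameterization: invertibility is encouraged by the
  displacement caps and verified by `jacobian_min`, not guaranteed by
  construction; consistency is measured (STRE), not enforced.
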