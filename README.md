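# vsreg — volume-subdivision deformable registration of CT and CBCT

Radiotherapy patients are imaged with a planning CT once and with a
cone-beam CT (CBCT) at every treatment fraction. Tracking anatomical change
(weight loss, tumor shrinkage) across these images needs *deformable* image
registration, and CT↔CBCT registration is stubbornly multimodal: CBCT does
not assign consistent intensities to a tissue type, so intensity-difference
costs fail. `vsreg` implements a locally rigid, globally nonrigid method for
exactly this problem, aimed at medical-imaging researchers and at anyone who
needs a transparent, fully scriptable registration + QA + batch pipeline in
R.

## The method

1. **Preprocess** both images: clamp to a preset window/level, rescale into
   [0, 255], Gaussian-smooth at voxel scale.
2. **Global rigid registration** (6-DOF) maximizing histogram **mutual
   information** `MI = Σ p_ij log2(p_ij / (p_i· p_·j))` with a
   bound-constrained **downhill simplex** (Nelder–Mead; every candidate is
   projected into the feasible set before evaluation).
3. **Octree volume subdivision**: split the reference into 8 (or 4, while
   the z-subdivision rate defers axial splits) subvolumes, rigidly refine
   each by MI starting from its parent's transform, recurse until the
   minimum subvolume size (default 16 × 16 × 8 voxels). Each level's motion
   is hard-capped at `flexibility × 0.4 × (smallest subvolume extent)` mm so
   the composite field never folds (`det(I + ∇u) > 0`, checked).
4. **Dense deformation field** by quaternion-based tricubic
   (Catmull–Rom) interpolation of the finest-level rigid transforms;
   backward-warp the planning CT onto the CBCT grid.
5. **Evaluate & QA**: target registration error (TRE) at the documented
   dose-calculation point (CALC) combined with the couch shift; 3D SSIM over
   the CBCT field of view; and the self-TRE (**STRE**) consistency check —
   forward + reverse registration round-trip distance over ~1000 seeded
   points, which must not exceed the voxel size, else the batch executor
   re-runs with fallback parameters.

A deterministic synthetic phantom module (CT-like volume, monotone
non-affine CBCT remap + axial shading + noise, known smooth ground-truth
deformations, landmarks) replaces clinical data everywhere: all tests run
from code alone.

## Worked example

```r
library(vsreg)

pair <- make_pair(phantom_spec(seed = 1))         # CBCT-like ref, CT-like flt
hier <- hierarchical_register(pair$reference, pair$floating,
                              phantom_parameters())
hier
#> <vs_hierarchy> 2 levels, 64 finest leaves (4x4x4 grid), 8 unrefined

field <- interpolate_field(hier)
field
#> <vs_field> 96x96x48 voxels, |u| max 7.086 mm, mean 3.468 mm
jacobian_min(field)
#> [1] 0.838

landmark_error(pair$landmarks)            # before registration: 4.84 mm
landmark_error(pair$landmarks, field)     # after:               0.96 mm

ann <- case_annotation(calc = colMeans(pair$landmarks[, 1:3]),
                       couch_shift = c(3, 0, 0))
compute_tre(ann, field)
#> [1] 2.32
```

The hierarchy report says the 96×96×48 phantom was subdivided twice (8 then
64 subvolumes; the 8 "unrefined" leaves are air outside the body, which
carry no registrable structure and keep their parent transform). The dense
field displaces voxels by up to 7.1 mm, its minimum Jacobian determinant
0.838 certifies no folding, and the mean landmark error drops from 4.84 mm
to 0.96 mm — under the coarsest voxel dimension (3 mm). The TRE of 2.32 mm
is the residual *deformable* displacement at the CALC point that a
couch-shift-only correction would miss.

SSIM before/after (0.705 → 0.893 on this pair) and the STRE QA are produced
by the batch executor:

```r
job <- job_message("demo", ref = pair$reference, flt = pair$floating,
                   ann = ann, params = phantom_parameters(),
                   meta = list(seed = 7))
res <- make_executor(compute_stre = TRUE)(job)
res$mean_stre; res$qa_pass
```

Batch and sweep runs are driven by TSV manifests (`run_batch()`,
`parameter_sweep()`, `default_sweep_sets()` for the 12-set
one-factor-at-a-time design), or from the command line:

```sh
Rscript -e 'vsreg::vsreg_cli()' phantom --out demo --seed 1
Rscript -e 'vsreg::vsreg_cli()' batch --manifest manifest.tsv --out results.tsv --workers 4
```

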