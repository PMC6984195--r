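Package: vsreg
Title: Volume-Subdivision Deformable Registration of CT and CBCT Volumes
Version: 0.1.0
Authors@R: person("VS", "Registration Contributors", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Locally rigid, globally nonrigid registration of 3D medical
    image volumes by hierarchical octree volume subdivision. Each subvolume
    is rigidly refined by maximizing histogram mutual information with a
    bound-constrained downhill simplex search, and the finest-level rigid
    transforms are blended into a dense, topology-preserving deformation
    field by quaternion-based tricubic interpolation. Includes NIfTI,
    MetaImage and DICOM-series volume I/O, intensity windowing and Gaussian
    preprocessing, target registration error and 3D structural similarity
    evaluation, a forward/reverse self-consistency (STRE) quality check, a
    one-factor-at-a-time parameter sweep harness, a queue/worker batch
    executor, and a deterministic synthetic CT/CBCT phantom generator with
    known ground-truth deformations.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    parallel,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
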