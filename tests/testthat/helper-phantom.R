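# Shared fixtures, built in code and cached per test run. Small phantoms
# (48 x 48 x 24 at the default anisotropic spacing) keep orchestration and
# sweep tests fast; the full-size default phantom is reserved for the
# acceptance suite.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

small_spec <- function(seed = 21L, ...) {
  args <- utils::modifyList(
    list(dims = c(48L, 48L, 24L), seed = seed, deform_amplitude = 4,
         rigid_translation = c(2, 0, 0)),
    list(...))
  do.call(phantom_spec, args)
}

small_pair <- function(seed = 21L) {
  cached(sprintf("pair%d", seed), make_pair(small_spec(seed)))
}

# Write a small pair to disk (NIfTI) for manifest-driven tests; returns the
# directory. One pair per seed, reused across tests.
small_pair_dir <- function(seed = 21L) {
  cached(sprintf("pairdir%d", seed), {
    dir <- file.path(tempdir(), sprintf("vsreg-pair-%d", seed))
    dir.create(dir, showWarnings = FALSE)
    p <- small_pair(seed)
    write_volume(p$reference, file.path(dir, "ref.nii.gz"))
    write_volume(p$floating, file.path(dir, "flt.nii.gz"))
    dir
  })
}

# Deterministic random volume for I/O and metric tests.
random_volume <- function(dims = c(8L, 8L, 8L), spacing = c(1, 1, 1),
                          origin = c(0, 0, 0), seed = 1L, lo = 0, hi = 255) {
  set.seed(seed)
  vs_volume(array(runif(prod(dims), lo, hi), dims), spacing, origin)
}

rotation_about_z <- function(deg, center = c(0, 0, 0)) {
  half <- deg * pi / 360
  rigid_transform(c(cos(half), 0, 0, sin(half)), center = center)
}

# Angle (degrees) of the relative rotation between two transforms.
rotation_error_deg <- function(T_est, T_true) {
  q <- vsreg:::quat_multiply(T_est$rotation,
                             vsreg:::quat_conjugate(T_true$rotation))
  2 * acos(min(1, abs(q[1]))) * 180 / pi
}

# Independent brute-force MI oracle: explicit probability-table loops,
# no shared code with mutual_information().
mi_oracle <- function(counts) {
  total <- sum(counts)
  p <- counts / total
  pr <- apply(p, 1, sum)
  pc <- apply(p, 2, sum)
  acc <- 0
  for (i in seq_len(nrow(p)))
    for (j in seq_len(ncol(p)))
      if (p[i, j] > 0)
        acc <- acc + p[i, j] * (log(p[i, j]) - log(pr[i]) - log(pc[j])) / log(2)
  acc
}

# All count matrices of shape r x c with a given total, as rows of a matrix.
enumerate_histograms <- function(r, c, total) {
  cells <- r * c
  compositions <- function(n, k) {
    if (k == 1L) return(matrix(n, 1, 1))
    out <- list()
    for (first in 0:n) {
      rest <- compositions(n - first, k - 1L)
      out[[length(out) + 1L]] <- cbind(first, rest, deparse.level = 0)
    }
    do.call(rbind, out)
  }
  compositions(total, cells)
}
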