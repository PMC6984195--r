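zero_field <- function(dims = c(30L, 30L, 30L), spacing = c(2, 2, 2),
                       origin = c(0, 0, 0), d = c(0, 0, 0)) {
  u <- array(0, c(dims, 3))
  for (c in 1:3) u[, , , c] <- d[c]
  deformation_field(u, spacing, origin)
}

test_that("TRE follows the CALC + inverse-couch-shift construction", {
  f0 <- zero_field()
  ann0 <- case_annotation(c(20, 20, 20), c(0, 0, 0))
  expect_equal(compute_tre(ann0, f0), 0)
  # registration that exactly undoes the couch shift: field == shift
  ann <- case_annotation(c(20, 20, 20), c(3, 4, 0))
  expect_equal(compute_tre(ann, zero_field(d = c(3, 4, 0))), 0)
  # zero field, shift (3,4,0): Euclidean norm
  expect_equal(compute_tre(ann, f0), 5)
  expect_error(compute_tre(case_annotation(c(500, 0, 0)), f0), "outside")
  expect_warning(case_annotation(c(0, 0, 0), c(60, 0, 0)), "50 mm")
})

test_that("TRE is equivariant under a shared constant displacement", {
  set.seed(28)
  for (i in 1:10) {
    d <- runif(3, -3, 3)
    ann1 <- case_annotation(c(25, 25, 25), c(1, 2, 0.5))
    ann2 <- case_annotation(c(25, 25, 25), c(1, 2, 0.5) + d)
    expect_equal(compute_tre(ann1, zero_field(d = c(0.4, -0.2, 1))),
                 compute_tre(ann2, zero_field(d = c(0.4, -0.2, 1) + d)),
                 tolerance = 1e-9)
  }
})

test_that("STRE is zero for inverse pairs and |d| for a one-sided shift", {
  ctr <- c(30, 30, 30)
  expect_lt(compute_stre(zero_field(d = c(2, 1, -1)), zero_field(d = -c(2, 1, -1)),
                         ctr, 15, 200L, seed = 1L), 1e-9)
  expect_lt(compute_stre(zero_field(), zero_field(), ctr, 15, 200L, seed = 1L),
            1e-12)
  s <- compute_stre(zero_field(d = c(3, 0, 4)), zero_field(), ctr, 15, 200L,
                    seed = 2L)
  expect_equal(as.numeric(s), 5, tolerance = 1e-9)
  expect_equal(attr(s, "n_valid"), 200L)
})

test_that("STRE sampling is seeded and errors below 10 valid points", {
  f <- zero_field(d = c(1, 0, 0))
  r <- zero_field()
  s1 <- compute_stre(f, r, c(30, 30, 30), 20, 100L, seed = 7L)
  s2 <- compute_stre(f, r, c(30, 30, 30), 20, 100L, seed = 7L)
  expect_identical(attr(s1, "stre"), attr(s2, "stre"))
  expect_error(compute_stre(f, r, c(500, 500, 500), 5, 100L, seed = 1L),
               "valid")
})

test_that("qa_check applies the voxel-size rule with <= passing", {
  expect_true(qa_check(1.5, 3.0)$passed)
  rep <- qa_check(3.1, 3.0)
  expect_false(rep$passed)
  expect_equal(rep$action, "rerun_with_new_parameters")
  expect_true(qa_check(3.0, 3.0)$passed)      # boundary convention: pass
  expect_equal(qa_check(3.0, 3.0)$action, "none")
  expect_error(qa_check(-1, 3), "positive")
  expect_equal(qa_voxel_size(c(1.17, 1.17, 3)), 3)
})

test_that("annotation sidecars round-trip through delimited text", {
  tmp <- withr::local_tempdir()
  anns <- list(case_annotation(c(1.5, -2, 30), c(0.5, 1, -0.25), "caseA"),
               case_annotation(c(10, 20, 30), c(0, 0, 0), "caseB"))
  p <- file.path(tmp, "ann.tsv")
  write_annotations(anns, p)
  back <- read_annotations(p)
  expect_named(back, c("caseA", "caseB"))
  expect_equal(back$caseA$calc, anns[[1]]$calc)
  expect_equal(back$caseA$couch_shift, anns[[1]]$couch_shift)
  writeLines("not,a,valid\nheader,at,all", file.path(tmp, "bad.csv"))
  expect_error(read_annotations(file.path(tmp, "bad.csv")), "missing columns")
})

test_that("parameter_sweep covers the Cartesian design and isolates failures", {
  p1 <- small_pair(31)
  p2 <- small_pair(32)
  ann <- function(id) case_annotation(c(36, 36, 36), c(2, 0, 0), id)
  pairs <- list(list(ref = p1$reference, flt = p1$floating, ann = ann("c1")),
                list(ref = p2$reference, flt = p2$floating, ann = ann("c2")))
  sets <- list(default = phantom_parameters(),
               loflex = phantom_parameters(flexibility = 0.5, name = "loflex"),
               broken = local({
                 s <- phantom_parameters()
                 s$ref_window$wmax <- s$ref_window$wmin  # degenerate window
                 s$name <- "broken"
                 s
               }))
  res <- parameter_sweep(pairs, sets, seed = 3L)
  expect_equal(nrow(res), 6L)   # 2 pairs x 3 sets
  expect_setequal(res$status[res$set == "broken"], "failed")
  ok <- res[res$status == "done", ]
  expect_equal(nrow(ok), 4L)
  expect_true(all(is.finite(ok$tre_mm)))
  per_set <- attr(res, "per_set")
  expect_equal(per_set$n_failed[per_set$set == "broken"], 2L)
  expect_true(is.finite(per_set$mean_tre[per_set$set == "default"]))
})
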