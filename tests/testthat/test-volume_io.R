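test_that("volume construction validates geometry", {
  expect_error(vs_volume(matrix(0, 2, 2)), "3D array")
  expect_error(vs_volume(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)), "positive")
  expect_error(vs_volume(array(0, c(2, 2, 2)), origin = c(0, NA, 0)), "finite")
  v <- vs_volume(array(7, c(8, 8, 8)), spacing = c(1.5, 1.5, 3))
  expect_equal(v$dims, c(8L, 8L, 8L))
})

test_that("coordinate maps are mutually inverse and anchored at the origin", {
  v <- vs_volume(array(0, c(10, 12, 8)), spacing = c(1.17, 1.17, 3),
                 origin = c(-50, -60, 10))
  expect_equal(physical_to_voxel(v, v$origin), c(0, 0, 0))
  expect_equal(voxel_to_physical(v, c(1, 1, 1)), v$origin + v$spacing)
  set.seed(4)
  pts <- matrix(runif(300, -100, 100), ncol = 3)
  back <- voxel_to_physical(v, physical_to_voxel(v, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("NIfTI round-trips exactly for integer data and float data", {
  tmp <- withr::local_tempdir()
  set.seed(2)
  ct <- vs_volume(array(sample(-1024:3071, 8^3, TRUE), c(8, 8, 8)),
                  spacing = c(1.17, 1.17, 3), origin = c(-5, 2, 40))
  p <- file.path(tmp, "ct.nii")
  write_volume(ct, p)
  back <- read_volume(p)
  expect_identical(back$data, ct$data)
  expect_equal(back$spacing, ct$spacing, tolerance = 1e-6)
  expect_equal(back$origin, ct$origin, tolerance = 1e-5)

  fv <- random_volume(c(6, 5, 4), seed = 3, lo = 0, hi = 1)
  pf <- file.path(tmp, "float.nii.gz")
  write_volume(fv, pf)
  backf <- read_volume(pf)
  expect_lt(max(abs(backf$data - fv$data)), 1e-6)
})

test_that("MetaImage round-trips and mixed metadata are honored", {
  tmp <- withr::local_tempdir()
  v <- random_volume(c(7, 6, 5), spacing = c(2, 2, 2.5), origin = c(1, -2, 3),
                     seed = 5)
  p <- file.path(tmp, "vol.mhd")
  write_volume(v, p)
  expect_true(file.exists(file.path(tmp, "vol.raw")))
  back <- read_volume(p)
  expect_lt(max(abs(back$data - v$data)), 1e-6)
  expect_equal(back$spacing, v$spacing)
  expect_equal(back$origin, v$origin)
})

test_that("NIfTI header spacing agrees with an independent reader (nibabel)", {
  has_nibabel <- nzchar(Sys.which("python")) &&
    system2("python", c("-c", shQuote("import nibabel")), stdout = FALSE,
            stderr = FALSE) == 0
  skip_if(!has_nibabel, "python/nibabel unavailable for the header oracle")
  tmp <- withr::local_tempdir()
  v <- vs_volume(array(seq_len(60), c(5, 4, 3)), spacing = c(1.17, 1.17, 3),
                 origin = c(-10, 4, 25))
  p <- file.path(tmp, "hdr.nii")
  write_volume(v, p)
  out <- system2("python", c("-c", shQuote(paste0(
    "import nibabel, json; img = nibabel.load('", p, "'); ",
    "print(json.dumps([list(map(float, img.header.get_zooms())), ",
    "img.get_fdata().flatten(order='F').tolist()[:5]]))"))),
    stdout = TRUE)
  parsed <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_equal(as.numeric(parsed[[1]]), v$spacing, tolerance = 1e-6)
  expect_equal(as.numeric(parsed[[2]]), as.numeric(v$data)[1:5])
})

test_that("oblique NIfTI orientation is rejected, not silently mishandled", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "oblique.nii")
  write_volume(random_volume(c(4, 4, 4), seed = 6), p)
  r <- readBin(p, "raw", file.size(p))
  # srow_x starts at byte offset 280: make it oblique (x row gains a y term).
  r[280 + 4 + 1:4] <- writeBin(0.5, raw(), 4, endian = "little")
  writeBin(r, p)
  expect_error(read_volume(p), "oblique")
})

test_that("failed writes leave no partial file behind", {
  missing_dir <- file.path(tempdir(), "vsreg-does-not-exist", "sub")
  p <- file.path(missing_dir, "x.nii")
  expect_error(suppressWarnings(write_volume(random_volume(seed = 7), p)))
  expect_false(file.exists(p))
  expect_error(write_volume(random_volume(seed = 7), "bad-extension.xyz"),
               "infer format")
})

test_that("resample_to_grid is exact on identical grids and zero-pads", {
  v <- random_volume(c(16, 16, 16), spacing = c(2, 2, 2), seed = 8)
  expect_equal(resample_to_grid(v, v)$data, v$data)

  target <- vs_volume(array(0, c(32, 32, 32)), spacing = c(2, 2, 2),
                      origin = c(-16, -16, -16))
  out <- resample_to_grid(v, target, fill = 0)
  expect_equal(out$dims, target$dims)
  # Region strictly outside the moving extent is exactly the fill value.
  expect_true(all(out$data[1:7, , ] == 0))

  const <- vs_volume(array(42, c(16, 16, 16)), spacing = c(2, 2, 2))
  out2 <- resample_to_grid(const, const)
  expect_true(all(out2$data == 42))
  # Interior of a finer target stays constant (interpolation of a constant).
  fine <- vs_volume(array(0, c(12, 12, 12)), spacing = c(1, 1, 1),
                    origin = c(5, 5, 5))
  expect_true(all(abs(resample_to_grid(const, fine)$data - 42) < 1e-12))
})

test_that("deformation fields round-trip as 3-vector NIfTI", {
  tmp <- withr::local_tempdir()
  set.seed(9)
  u <- array(rnorm(6 * 5 * 4 * 3), c(6, 5, 4, 3))
  f <- deformation_field(u, c(1.5, 1.5, 3), c(0, 0, 0))
  p <- file.path(tmp, "field.nii.gz")
  write_field(f, p)
  back <- read_field(p)
  expect_equal(back$u, f$u)
  expect_equal(back$spacing, f$spacing, tolerance = 1e-6)
  # scalar volume is refused by read_field
  write_volume(random_volume(seed = 1), file.path(tmp, "s.nii"))
  expect_error(read_field(file.path(tmp, "s.nii")), "3-vector")
})

test_that("DICOM series read sorts slices by position and honors geometry", {
  tmp <- withr::local_tempdir()
  set.seed(10)
  vol <- vs_volume(array(sample(-1000:2000, 6 * 5 * 4, TRUE), c(6, 5, 4)),
                   spacing = c(1.17, 1.3, 3), origin = c(-20, -10, 50))
  d1 <- file.path(tmp, "ordered")
  write_dicom_series(vol, d1)
  back <- read_volume(d1, format = "dicom_series")
  expect_equal(back$data, vol$data)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin)

  # File names scrambled relative to z: k-order must follow positions.
  d2 <- file.path(tmp, "scrambled")
  write_dicom_series(vol, d2, scramble_names = TRUE)
  back2 <- read_volume(d2)
  expect_equal(back2$data, vol$data)
})

test_that("inconsistent DICOM series are rejected with the offending field", {
  tmp <- withr::local_tempdir()
  d <- file.path(tmp, "mixed")
  dir.create(d)
  m <- matrix(seq_len(20), 5, 4)
  write_dicom_slice(file.path(d, "a.dcm"), m, c(0, 0, 0), c(1, 1))
  write_dicom_slice(file.path(d, "b.dcm"), m, c(0, 0, 3), c(1, 1))
  write_dicom_slice(file.path(d, "c.dcm"), m, c(0, 0, 7), c(1, 1))
  expect_error(read_volume(d), "mixed slice spacing")

  d3 <- file.path(tmp, "mixedxy")
  dir.create(d3)
  write_dicom_slice(file.path(d3, "a.dcm"), m, c(0, 0, 0), c(1, 1))
  write_dicom_slice(file.path(d3, "b.dcm"), m, c(0, 0, 3), c(2, 2))
  expect_error(read_volume(d3), "PixelSpacing")
})
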