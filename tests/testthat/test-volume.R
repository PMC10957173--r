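test_that("volume write/read round-trips values and affine", {
  vals <- array(1, dim = c(4, 4, 4))
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-3, -3, -3)
  v <- volume_grid(vals, aff)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  r <- read_volume(f)
  expect_identical(r$values, vals)
  expect_equal(r$affine, aff, tolerance = 1e-12)

  # floating values round-trip within 1e-7 relative
  set.seed(42)
  vals2 <- array(rnorm(4^3) * 100, dim = c(4, 4, 4))
  f2 <- tempfile(fileext = ".nii.gz")
  write_volume(volume_grid(vals2, aff), f2)
  expect_equal(read_volume(f2)$values, vals2, tolerance = 1e-7)
})

test_that("read_volume applies the format's slope/intercept scaling", {
  skip_if_not_installed("oro.nifti")
  n <- oro.nifti::nifti(array(3L, dim = c(2, 2, 2)), datatype = 4)
  n@scl_slope <- 2
  n@scl_inter <- 0
  f <- tempfile()
  oro.nifti::writeNIfTI(n, f)
  r <- read_volume(paste0(f, ".nii.gz"))
  expect_equal(unique(as.vector(r$values)), 6)
})

test_that("read_volume rejects non-3-D images and missing files", {
  expect_error(read_volume(tempfile()), "not found")
  img <- RNifti::asNifti(matrix(1, 4, 4))
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "3-D")
})

test_that("world_to_voxel inverts the affine with half-away rounding", {
  v <- make_volume(array(0, dim = c(8, 8, 8)))
  r <- world_to_voxel(v, rbind(c(2, 3, 4)))
  expect_equal(r$index[1, ], c(2L, 3L, 4L))
  expect_false(r$oob[1])

  v2 <- make_volume(array(0, dim = c(8, 8, 8)), voxel_mm = 2,
                    origin = c(-10, -10, -10))
  r2 <- world_to_voxel(v2, rbind(c(0, 0, 0), c(-12, 0, 0)))
  expect_equal(r2$index[1, ], c(5L, 5L, 5L))
  expect_true(r2$oob[2])   # maps to index -1: flagged, not clamped
  expect_equal(r2$index[2, 1], -1L)

  # half-away rounding: voxel coordinate 2.5 -> 3, -0.5 -> -1
  r3 <- world_to_voxel(v, rbind(c(2.5, 0, 0), c(-0.5, 0, 0)))
  expect_equal(r3$index[1, 1], 3L)
  expect_equal(r3$index[2, 1], -1L)
})

test_that("resampling preserves identity, constants and linear ramps", {
  set.seed(1)
  vals <- array(rnorm(6^3), dim = c(6, 6, 6))
  v <- make_volume(vals)
  for (mode in c("trilinear", "nearest")) {
    expect_equal(resample_to_grid(v, v, mode)$values, vals, tolerance = 1e-12)
  }

  const <- make_volume(array(7, dim = c(6, 6, 6)))
  target <- make_volume(array(0, dim = c(3, 3, 3)), origin = c(1, 1, 1))
  out <- resample_to_grid(const, target, "trilinear")
  expect_true(all(out$values == 7))

  # 1-D ramp 0,10 along x; target voxel center midway -> 5
  ramp <- make_volume(array(rep(c(0, 10), 4), dim = c(2, 2, 2)))
  tgt <- make_volume(array(0, dim = c(1, 1, 1)), origin = c(0.5, 0, 0))
  expect_equal(as.vector(resample_to_grid(ramp, tgt, "trilinear")$values), 5)

  # outside-source voxels are missing, not zero
  far <- make_volume(array(0, dim = c(2, 2, 2)), origin = c(100, 0, 0))
  expect_true(all(is.na(resample_to_grid(const, far, "trilinear")$values)))
})

test_that("nearest resampling of labels never invents labels", {
  set.seed(2)
  lab_vals <- array(sample(c(0, 3, 5, 9), 6^3, replace = TRUE), dim = c(6, 6, 6))
  lv <- label_volume(make_volume(lab_vals),
                     data.frame(label = c(3, 5, 9), name = c("a", "b", "c")))
  tgt <- make_volume(array(0, dim = c(4, 4, 4)), voxel_mm = 1.3,
                     origin = c(0.2, 0.1, 0.4))
  out <- resample_to_grid(lv, tgt, "nearest")
  got <- unique(as.vector(out$values[!is.na(out$values)]))
  expect_true(all(got %in% c(0, 3, 5, 9)))
  expect_error(resample_to_grid(lv, tgt, "trilinear"), "label")
})

test_that("smoothing preserves constants, matches a dense convolution oracle, and validates fwhm", {
  const <- make_volume(array(4.2, dim = c(8, 8, 8)))
  sm <- smooth_volume(const, fwhm_mm = 5)
  expect_lt(max(abs(sm$values - 4.2)), 1e-9)

  # impulse response vs direct dense 3-D convolution of the truncated,
  # renormalized Gaussian product kernel (sigma = 1 voxel)
  d <- c(17, 17, 17)
  imp <- array(0, dim = d); imp[9, 9, 9] <- 1
  fwhm <- 2 * sqrt(2 * log(2))  # sigma = 1 voxel at 1 mm voxels
  got <- smooth_volume(make_volume(imp), fwhm)$values
  r <- 4
  k1 <- exp(-(-r:r)^2 / 2); k1 <- k1 / sum(k1)
  oracle <- array(0, dim = d)
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    oracle[9 + dx, 9 + dy, 9 + dz] <- k1[dx + r + 1] * k1[dy + r + 1] * k1[dz + r + 1]
  }
  # away from edges the normalizing mask blur is 1, so plain convolution applies
  expect_lt(max(abs(got - oracle)), 1e-6)

  expect_error(smooth_volume(const, 0), "positive")

  # masked smoothing of a mask-constant field returns the constant
  maskv <- array(0, dim = c(8, 8, 8)); maskv[3:6, 3:6, 3:6] <- 1
  field <- array(rnorm(8^3), dim = c(8, 8, 8))
  field[maskv == 1] <- 2.5
  out <- smooth_volume(make_volume(field), 6, mask = make_volume(maskv))
  expect_lt(max(abs(out$values[maskv == 1] - 2.5)), 1e-9)
})
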