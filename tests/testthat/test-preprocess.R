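# volume preprocessing: NIfTI I/O, resampling, reorientation, crop/pad,
# binarization

test_that("NIfTI round-trip preserves values, spacing and orientation", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "v.nii.gz")
  vals <- array((runif(20^3) < 0.3) * 1.0, c(20, 20, 20))
  v <- volume_image(vals, spacing = c(2, 2, 2), dtype_role = "binary")
  write_nifti(v, f)
  r <- read_nifti(f)
  expect_equal(r$values, vals)
  expect_equal(r$spacing, c(2, 2, 2))
  expect_equal(r$orientation, "RAS")
  expect_equal(r$dtype_role, "binary")
})

test_that("anisotropic spacing written by an independent writer is read verbatim", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "aniso.nii.gz")
  img <- RNifti::asNifti(array(rnorm(6 * 7 * 8), c(6, 7, 8)))
  RNifti::pixdim(img) <- c(0.5, 0.5, 1.0)
  RNifti::writeNifti(img, f)
  v <- read_nifti(f)
  expect_equal(v$spacing, c(0.5, 0.5, 1.0))
  expect_equal(dim(v$values), c(6L, 7L, 8L))
  expect_equal(v$dtype_role, "HU")
})

test_that("isotropic resampling preserves physical extent", {
  # 30 voxels at 2 mm -> 60 voxels at 1 mm on every axis
  v <- volume_image(array(rnorm(30^3), c(30, 30, 30)), spacing = c(2, 2, 2))
  r <- resample_isotropic(v, 1)
  expect_equal(dim(r$values), c(60L, 60L, 60L))
  expect_equal(r$spacing, c(1, 1, 1))
  expect_equal(dim(r$values) * r$spacing, dim(v$values) * v$spacing)

  # already at target: identity
  v1 <- volume_image(array(rnorm(10^3), c(10, 10, 10)), spacing = c(1, 1, 1))
  expect_identical(resample_isotropic(v1, 1)$values, v1$values)

  # constant volume stays constant under linear interpolation
  vc <- volume_image(array(700, c(12, 12, 12)), spacing = c(1.7, 0.5, 2.3))
  rc <- resample_isotropic(vc, 1)
  expect_true(all(rc$values == 700))

  # binary volumes stay binary (nearest neighbour)
  vb <- volume_image(array((runif(12^3) < 0.4) * 1.0, c(12, 12, 12)),
                     spacing = c(0.5, 0.5, 1), dtype_role = "binary")
  rb <- resample_isotropic(vb, 1)
  expect_true(all(rb$values %in% c(0, 1)))
  expect_error(resample_isotropic(v1, -1), "positive")
})

test_that("canonical reorientation matches a direct index-reversal oracle", {
  vals <- array(seq_len(4 * 5 * 6), c(4, 5, 6))
  # single flipped axis: LAS -> RAS reverses axis 1 only
  v <- volume_image(vals, orientation = "LAS")
  r <- reorient_canonical(v)
  expect_equal(r$orientation, "RAS")
  expect_equal(r$values, vals[4:1, , ])
  expect_equal(sort(as.numeric(r$values)), sort(as.numeric(vals)))

  # already canonical: identity; and idempotence
  vr <- volume_image(vals, orientation = "RAS")
  expect_identical(reorient_canonical(vr)$values, vals)
  expect_identical(reorient_canonical(r)$values, r$values)

  # axis permutation carries spacing along
  vp <- volume_image(vals, spacing = c(1, 2, 3), orientation = "ASR")
  rp <- reorient_canonical(vp)
  expect_equal(dim(rp$values), c(6L, 4L, 5L))
  expect_equal(rp$spacing, c(3, 1, 2))
  expect_error(reorient_canonical(volume_image(vals, orientation = "RAX")),
               "orientation")
  expect_error(reorient_canonical(volume_image(vals, orientation = "RAR")),
               "orientation")
})

test_that("crop_or_pad centres content, pads with zeros, crops to the window", {
  vals <- array(0, c(10, 10, 10))
  vals[5:6, 5:6, 5:6] <- 1
  v <- volume_image(vals, dtype_role = "binary")
  # pure padding preserves foreground
  p <- crop_or_pad(v, 20)
  expect_equal(dim(p$values), c(20L, 20L, 20L))
  expect_equal(sum(p$values), sum(vals))
  expect_equal(p$values[10:11, 10:11, 10:11], vals[5:6, 5:6, 5:6])
  # identity when already at size
  expect_identical(crop_or_pad(v, 10)$values, vals)
  # crop smaller than the foreground bounding box loses exactly the
  # out-of-window count
  vb <- volume_image(ball_volume(20, 8), dtype_role = "binary")
  cr <- crop_or_pad(vb, 10)
  lead <- (20 - 10) %/% 2
  inside <- vb$values[lead + 1:10, lead + 1:10, lead + 1:10]
  expect_equal(sum(cr$values), sum(inside))
  # pad back to a larger-than-original side recovers the centred original
  back <- crop_or_pad(crop_or_pad(v, 14), 10)
  expect_equal(back$values, vals)
  # odd difference: extra voxel goes to the trailing side
  vo <- volume_image(array(1, c(3, 3, 3)), dtype_role = "binary")
  po <- crop_or_pad(vo, 4)
  expect_equal(sum(po$values[4, , ]), 0)  # trailing plane is padding
  expect_equal(po$values[2:4 - 1, 1:3, 1:3], vo$values)
})

test_that("HU binarization thresholds at >= 500 and is a fixed point", {
  vals <- array(c(499, 500, 501, 0, -1000, 2000, 250, 499.999),
                c(2, 2, 2))
  v <- volume_image(vals, dtype_role = "HU")
  b <- binarize_hu(v)
  expect_equal(as.numeric(b$values),
               as.numeric(vals >= 500))
  expect_equal(b$dtype_role, "binary")
  # re-binarizing a binary mask at threshold <= 1 changes nothing
  expect_identical(binarize_hu(b, 0.5)$values, b$values)
  z <- binarize_hu(volume_image(array(0, c(3, 3, 3)), dtype_role = "HU"))
  expect_equal(sum(z$values), 0)
})

test_that("the full preprocessing pipeline is deterministic and composes", {
  vals <- array(rnorm(20^3, mean = 300, sd = 400), c(20, 20, 20))
  v <- volume_image(vals, spacing = c(2, 1, 1), orientation = "LPS")
  a <- preprocess_volume(v, side = 24, target_mm = 1, threshold = 500)
  b <- preprocess_volume(v, side = 24, target_mm = 1, threshold = 500)
  expect_identical(a$values, b$values)
  expect_equal(dim(a$values), c(24L, 24L, 24L))
  expect_equal(a$spacing, c(1, 1, 1))
  expect_equal(a$orientation, "RAS")
  expect_true(all(a$values %in% c(0, 1)))
})
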