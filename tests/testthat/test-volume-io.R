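test_that("NIfTI write/read round-trips data, spacing and origin", {
  set.seed(1)
  v <- volume3d(array(rnorm(6 * 5 * 4), c(6, 5, 4)),
                spacing = c(0.2, 0.2, 0.2), origin = c(10, -5, 3))
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, p)
  w <- read_volume(p)
  expect_equal(w$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(w$origin, v$origin, tolerance = 1e-6)
  expect_lt(max(abs(w$data - v$data)), 1e-6)

  v1 <- volume3d(array(7.0, c(1, 1, 1)))
  p1 <- withr::local_tempfile(fileext = ".nii")
  write_volume(v1, p1)
  expect_equal(read_volume(p1)$data[1, 1, 1], 7.0)

  z <- volume3d(array(0, c(8, 8, 8)))
  pz <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(z, pz)
  expect_true(all(read_volume(pz)$data == 0))
})

test_that("4D images with a trailing singleton are squeezed, others rejected", {
  a4 <- array(seq_len(3 * 3 * 3), c(3, 3, 3, 1))
  p <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(a4), p)
  v <- read_volume(p)
  expect_equal(dim(v$data), c(3L, 3L, 3L))

  a4b <- array(0, c(3, 3, 3, 2))
  pb <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(a4b), pb)
  expect_error(read_volume(pb), "3D")
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "no such file")
})

test_that("minmax_rescale maps extremes to 0/1, is monotone and handles degenerate ranges", {
  v <- volume3d(array(c(10, 15, 20), c(3, 1, 1)))
  expect_equal(as.numeric(minmax_rescale(v)$data), c(0, 0.5, 1))

  expect_true(all(minmax_rescale(volume3d(array(4, c(3, 3, 3))))$data == 0))

  u <- volume3d(array(seq(0, 1, length.out = 27), c(3, 3, 3)))
  expect_equal(minmax_rescale(u)$data, u$data, tolerance = 1e-12)

  set.seed(2)
  r <- volume3d(array(rnorm(64), c(4, 4, 4)))
  s <- minmax_rescale(r)
  expect_true(all(s$data >= 0 & s$data <= 1))
  expect_equal(order(r$data), order(s$data))  # monotone

  # support mask: extrema from the masked region only
  m <- binary_mask(array(c(1, 1, 0, 0), c(4, 1, 1)),
                   reference = volume3d(array(c(2, 4, 8, 16), c(4, 1, 1))))
  sm <- minmax_rescale(volume3d(array(c(2, 4, 8, 16), c(4, 1, 1))), m)
  expect_equal(as.numeric(sm$data), c(0, 1, 1, 1))

  bad <- volume3d(array(c(1, NA, 3, 4), c(4, 1, 1)))
  expect_error(minmax_rescale(bad), "finite")
})

test_that("downsample honors factor, preserves constants and the field of view", {
  v <- smooth_volume(18, seed = 3)
  expect_volumes_equal(downsample(v, 1), v)

  u <- volume3d(array(rnorm(9^3), c(9, 9, 9)), spacing = c(1, 2, 3))
  d <- downsample(u, 3)
  expect_equal(dim(d$data), c(3L, 3L, 3L))
  expect_equal(d$spacing, c(3, 6, 9))
  expect_equal(d$origin, u$origin)

  k <- volume3d(array(5, c(12, 12, 12)))
  expect_true(all(abs(downsample(k, 3)$data - 5) < 1e-12))

  expect_error(downsample(v, 0), "factor")

  # band-limited volume: downsample then re-interpolate is close to original
  big <- volume3d(echoreg:::gaussian_smooth(array(rnorm(24^3), c(24, 24, 24)), 3))
  ds <- downsample(big, 2)
  back <- resample(ds, identity_transform(), big)
  interior <- big$data[5:20, 5:20, 5:20]
  backint <- back$data[5:20, 5:20, 5:20]
  expect_lt(mean(abs(backint - interior)), 0.02 * diff(range(big$data)))
})

test_that("resample is exact on coinciding grids and for integer-voxel shifts", {
  v <- smooth_volume(12, seed = 4)
  expect_volumes_equal(resample(v, identity_transform(), v), v, tol = 1e-12)

  sh <- resample(v, rigid_transform(c(1, 0, 0)), v)  # T(X) = X + 1mm = next voxel
  expect_lt(max(abs(sh$data[1:11, , ] - v$data[2:12, , ])), 1e-12)
  expect_true(all(sh$data[12, , ] == 0))  # border fill
})

test_that("resample moves a delta spike to the position computed by direct coordinate mapping", {
  n <- 15
  a <- array(0, c(n, n, n))
  a[11, 8, 8] <- 1
  v <- volume3d(a)
  ctr <- volume_center(v)  # (7,7,7) mm
  T90 <- rigid_transform(rotation = c(0, 0, 90), center = ctr)
  out <- resample(v, T90, v)
  # brute-force oracle: reference voxel X receives moving value at T(X);
  # the spike at index (11,8,8) (world (10,7,7)) is picked up by the
  # reference world point X with T(X) = (10,7,7)
  Xw <- transform_points(transform_invert(T90), c(10, 7, 7))
  idx <- round(Xw + 1)
  expect_equal(out$data[idx[1], idx[2], idx[3]], 1, tolerance = 1e-9)
  expect_equal(sum(out$data > 0.5), 1L)
})

test_that("resample through T then its inverse restores the interior of smooth volumes", {
  v <- smooth_volume(20, seed = 5)
  v <- minmax_rescale(v)
  tr <- rigid_transform(c(1.3, -0.7, 0.4), c(4, -3, 2), center = volume_center(v))
  fwd <- resample(v, tr, v)
  back <- resample(fwd, transform_invert(tr), v)
  interior <- as.vector(v$data[7:14, 7:14, 7:14])
  restored <- as.vector(back$data[7:14, 7:14, 7:14])
  expect_lt(mean(abs(restored - interior)), 0.03)
})

test_that("binary masks enforce {0,1} values and matching geometry", {
  ref <- volume3d(array(0, c(4, 4, 4)), spacing = c(2, 2, 2))
  m <- binary_mask(array(1, c(4, 4, 4)), reference = ref)
  expect_equal(m$spacing, ref$spacing)
  expect_error(binary_mask(array(0.5, c(4, 4, 4)), reference = ref), "0 or 1")
  expect_error(binary_mask(array(1, c(3, 4, 4)), reference = ref), "shape")
})
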