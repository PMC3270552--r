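test_that("an empty phantom spec yields a constant tissue block", {
  spec <- phantom_spec(shape = c(16, 16, 16), n_sulci = 0, falx = FALSE,
                       lesion = NULL, noise_sigma = 0, seed = 1)
  out <- generate_mr_phantom(spec)
  expect_equal(diff(range(out$volume$data)), 0)
  expect_true(all(out$truth$centerline$data == 0))
})

test_that("valley centrelines are strictly darker than the tissue background", {
  spec <- phantom_spec(shape = c(32, 32, 32), noise_sigma = 0,
                       speckle_var = 0, seed = 2)
  out <- generate_mr_phantom(spec)
  sk <- out$truth$centerline$data == 1
  outside <- sk == 0 & out$truth$lesion_mask$data == 0
  expect_true(all(out$volume$data[sk] < max(out$volume$data[outside])))
  expect_lt(mean(out$volume$data[sk]), 0.5 * mean(out$volume$data[outside]))
})

test_that("phantom generation is bit-reproducible from the seed alone", {
  a <- generate_mr_phantom(phantom_spec(shape = c(24, 24, 24), seed = 9))
  b <- generate_mr_phantom(phantom_spec(shape = c(24, 24, 24), seed = 9))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$centerline$data, b$truth$centerline$data)

  c2 <- generate_mr_phantom(phantom_spec(shape = c(24, 24, 24), seed = 10))
  expect_false(identical(a$volume$data, c2$volume$data))
})

test_that("phantom truth masks share the volume geometry and are binary", {
  fx <- make_registration_fixture(seed = 3, shape = c(24, 24, 24))
  for (mask in list(fx$truth$centerline, fx$truth$lesion_mask,
                    fx$truth$shadow_mask, fx$truth$fov_mask)) {
    expect_s3_class(mask, "binary_mask")
    expect_true(same_grid(mask, fx$mr))
    expect_true(all(mask$data %in% c(0, 1)))
  }
  expect_true(any(fx$truth$lesion_mask$data == 1))
})

test_that("simulated ultrasound is bright on structures, zero in shadow, unit-mean speckle", {
  cl <- noiseless_phantom()
  iface <- echoreg:::dilate1(cl$truth$centerline$data) == 1
  bg <- cl$truth$centerline$data == 0 & cl$truth$lesion_mask$data == 0
  for (i in 1:2) bg <- bg & echoreg:::dilate1((!bg) + 0) == 0
  expect_gt(mean(cl$us$data[iface]), 3 * mean(cl$us$data[bg]))

  # speckle multiplies a noiseless field by unit-mean noise
  spec_n <- phantom_spec(shape = c(48, 48, 48), noise_sigma = 0,
                         speckle_var = 0.2, seed = 5)
  mrp <- generate_mr_phantom(spec_n)
  usn <- simulate_us_from_mr(mrp$truth, spec_n)$volume
  bright <- cl$us$data > 0.5
  ratio <- usn$data[bright] / cl$us$data[bright]
  expect_lt(abs(mean(ratio) - 1), 3 * sqrt(0.2 / sum(bright)) + 0.01)

  spec_s <- phantom_spec(shape = c(32, 32, 32), seed = 6,
                         shadow = list(axis = 3, from = 0.7, frac = 0.2))
  mrp_s <- generate_mr_phantom(spec_s)
  us_s <- simulate_us_from_mr(mrp_s$truth, spec_s)
  shadow <- us_s$truth$shadow_mask$data == 1
  expect_gt(sum(shadow), 0)
  expect_true(all(us_s$volume$data[shadow] == 0))
})

test_that("a limited field of view zeroes everything outside the crop box", {
  spec <- phantom_spec(shape = c(32, 32, 32), seed = 7,
                       fov = list(lo = c(0.2, 0.2, 0), hi = c(0.8, 0.8, 1)))
  mrp <- generate_mr_phantom(spec)
  us <- simulate_us_from_mr(mrp$truth, spec)
  outside <- us$truth$fov_mask$data == 0
  expect_gt(sum(outside), 0)
  expect_true(all(us$volume$data[outside] == 0))
})

test_that("US brightness and MR probability share support on noiseless phantoms", {
  cl <- noiseless_phantom()
  usm <- us_probability_map(cl$us)
  mrm <- mr_probability_map(cl$denoised, cl$truth$lesion_mask, 1, 2)
  a <- usm$data > 0.5
  b_dil <- echoreg:::dilate1((mrm$data > 0.25) + 0) == 1
  # most bright-US voxels sit on or next to high MR probability
  expect_gt(sum(a & b_dil) / sum(a), 0.5)
})

test_that("a misaligning true transform moves the simulated US content", {
  spec <- phantom_spec(shape = c(24, 24, 24), noise_sigma = 0,
                       speckle_var = 0, seed = 8)
  mrp <- generate_mr_phantom(spec)
  aligned <- simulate_us_from_mr(mrp$truth, spec)$volume
  tr <- rigid_transform(c(3, 0, 0), center = volume_center(mrp$volume))
  moved <- simulate_us_from_mr(mrp$truth, spec, t_true = tr)$volume
  # moved US at X equals aligned US at T(X): shifting back must agree
  shifted_back <- resample(volume3d(aligned$data, aligned$spacing,
                                    aligned$origin), tr, aligned)
  interior <- 5:20
  expect_lt(max(abs(moved$data[interior, interior, interior] -
                    shifted_back$data[interior, interior, interior])), 1e-9)
})

test_that("fixture invariants: self-registration and seed separation", {
  fm <- small_fixture_maps()
  res <- register(fm$maps$us_map, fm$maps$mr_map, init = fm$fx$t_true)
  omega <- warping_index(fm$fx$t_true, res$transform, fm$maps$us_map)
  expect_lt(omega, 0.5)

  f1 <- make_registration_fixture(seed = 1, shape = c(24, 24, 24))
  f2 <- make_registration_fixture(seed = 2, shape = c(24, 24, 24))
  expect_false(identical(f1$us$data, f2$us$data))
  expect_false(identical(f1$mr$data, f2$mr$data))
})

test_that("phantom spec validation catches impossible geometry", {
  expect_error(phantom_spec(shape = c(4, 4, 4)), "at least 8")
  expect_error(phantom_spec(shape = c(32, 32, 32),
                            lesion = list(center = c(1, 1, 1), radius = 10)),
               "fit")
  expect_error(phantom_spec(fov = list(lo = c(0.5, 0, 0), hi = c(0.4, 1, 1))),
               "fov")
})
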