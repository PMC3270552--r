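# Shared fixtures, built once per test session and memoised.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small pre-aligned phantom pair with probability maps (unit-test scale)
small_fixture_maps <- function() {
  cached("small48", function() {
    fx <- make_registration_fixture(seed = 7, shape = c(48, 48, 48))
    maps <- build_probability_maps(fx$mr, fx$us, fx$brain_mask,
                                   fx$lesion_mask)
    list(fx = fx, maps = maps)
  })
}

# noiseless phantom (no speckle, no MR noise) for map-geometry checks
noiseless_phantom <- function() {
  cached("clean48", function() {
    spec <- phantom_spec(shape = c(48, 48, 48), noise_sigma = 0,
                         speckle_var = 0, seed = 5)
    mrp <- generate_mr_phantom(spec)
    usp <- simulate_us_from_mr(mrp$truth, spec)
    den <- nlm_denoise(mrp$volume)
    list(spec = spec, mr = mrp$volume, truth = usp$truth,
         us = usp$volume, denoised = den)
  })
}

# random rigid transforms for property loops
random_transforms <- function(n, t_max = 10, r_max = 20, center = c(0, 0, 0),
                              seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    rigid_transform(runif(3, -t_max, t_max), runif(3, -r_max, r_max), center))
}

# quick smooth test volume
smooth_volume <- function(n = 16, seed = 1) {
  set.seed(seed)
  a <- array(rnorm(n^3), c(n, n, n))
  volume3d(echoreg:::gaussian_smooth(a, 2), c(1, 1, 1), c(0, 0, 0))
}

expect_volumes_equal <- function(a, b, tol = 1e-10) {
  expect_true(same_grid(a, b, tol = 1e-5))
  expect_lt(max(abs(a$data - b$data)), tol)
}
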