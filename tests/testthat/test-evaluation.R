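make_pairs <- function(n, transform, noise = 0, seed = 1) {
  set.seed(seed)
  src <- matrix(runif(3 * n, -40, 40), n, 3)
  tgt <- transform_points(transform, src)
  if (noise > 0) tgt <- tgt + matrix(rnorm(3 * n, 0, noise), n, 3)
  landmark_pairs(src, tgt)
}

test_that("rigid landmark fit recovers exact correspondences to machine precision", {
  idp <- make_pairs(10, identity_transform())
  fit0 <- fit_rigid_landmarks(idp)
  expect_lt(max(abs(transform_matrix(fit0) - diag(4))), 1e-9)

  tr <- rigid_transform(c(4, -7, 2), c(12, -8, 25), center = c(3, 3, 3))
  pairs <- make_pairs(10, tr, seed = 2)
  fit <- fit_rigid_landmarks(pairs)
  expect_lt(max(abs(transform_matrix(fit) - transform_matrix(tr))), 1e-9)
})

test_that("rigid landmark fit never returns a reflection and flags degenerate input", {
  set.seed(3)
  src <- matrix(runif(30, -20, 20), 10, 3)
  tgt <- src %*% diag(c(-1, 1, 1))  # mirrored correspondence
  fit <- fit_rigid_landmarks(landmark_pairs(src, tgt))
  expect_gt(det(transform_matrix(fit)[1:3, 1:3]), 0)

  line <- cbind(seq_len(5), seq_len(5) * 2, seq_len(5) * 3)
  expect_error(fit_rigid_landmarks(landmark_pairs(line, line)), "collinear")
  expect_error(fit_rigid_landmarks(landmark_pairs(src[1:2, ], tgt[1:2, ])),
               "at least 3")
})

test_that("fit is invariant to pair relabeling and equivariant to joint rigid motion", {
  tr <- rigid_transform(c(1, 2, 3), c(5, -4, 8), center = c(0, 0, 0))
  pairs <- make_pairs(8, tr, seed = 4)
  perm <- sample(8)
  fit1 <- fit_rigid_landmarks(pairs)
  fit2 <- fit_rigid_landmarks(landmark_pairs(pairs$source[perm, ],
                                             pairs$target[perm, ]))
  expect_lt(max(abs(transform_matrix(fit1) - transform_matrix(fit2))), 1e-9)

  g <- rigid_transform(c(-5, 3, 1), c(9, 14, -6))
  moved <- landmark_pairs(transform_points(g, pairs$source),
                          transform_points(g, pairs$target))
  fit3 <- fit_rigid_landmarks(moved)
  exp_m <- transform_matrix(g) %*% transform_matrix(tr) %*%
    solve(transform_matrix(g))
  expect_lt(max(abs(transform_matrix(fit3) - exp_m)), 1e-8)
})

test_that("initial error reproduces hand-computed distances", {
  p <- landmark_pairs(diag(3), diag(3))
  e0 <- initial_error(p)
  expect_equal(e0$mean, 0)
  expect_equal(e0$sd, 0)

  src <- matrix(runif(30), 10, 3)
  tgt <- sweep(src, 2, c(3, 4, 0), `+`)
  e1 <- initial_error(landmark_pairs(src, tgt))
  expect_equal(e1$mean, 5, tolerance = 1e-12)
  expect_equal(e1$sd, 0, tolerance = 1e-12)

  two <- landmark_pairs(matrix(0, 2, 3),
                        rbind(c(1, 0, 0), c(3, 0, 0)))
  e2 <- initial_error(two)
  expect_equal(e2$mean, 2)
  expect_equal(e2$sd, sqrt(2))
})

test_that("leave-one-out TRE is zero for exact rigid pairs and counts n fits", {
  tr <- rigid_transform(c(2, -1, 4), c(6, 3, -9), center = c(1, 1, 1))
  pairs <- make_pairs(10, tr, seed = 5)
  res <- tre_leave_one_out(pairs)
  expect_lt(max(res$tre), 1e-9)
  expect_equal(res$mean, mean(res$tre))

  p4 <- make_pairs(4, tr, seed = 6)
  expect_length(tre_leave_one_out(p4)$tre, 4L)
  expect_error(tre_leave_one_out(make_pairs(3, tr)), "at least 4")
})

test_that("TRE grows monotonically with landmark noise", {
  tr <- rigid_transform(c(2, -3, 1), c(4, -2, 7))
  sigmas <- c(0.5, 1, 2)
  mean_tre <- sapply(sigmas, function(s) {
    mean(sapply(1:100, function(rep)
      tre_leave_one_out(make_pairs(10, tr, noise = s, seed = 1000 + rep))$mean))
  })
  expect_gt(mean_tre[1], 0)
  expect_true(all(diff(mean_tre) > 0))
})

test_that("warping index closed forms hold and match a brute-force voxel oracle", {
  dom <- volume3d(array(0, c(11, 11, 11)), spacing = c(5, 5, 5))
  tr <- rigid_transform(c(2, 1, -3), c(4, 8, -2), center = c(25, 25, 25))
  expect_equal(warping_index(tr, tr, dom), 0)

  a <- rigid_transform(c(5, 1, 2), c(3, -2, 9), center = c(10, 0, 5))
  b <- transform_compose(rigid_transform(c(3, 4, 0)), a, center = a$center)
  expect_equal(warping_index(a, b, dom), 5, tolerance = 1e-12)

  rotA <- identity_transform(center = c(25, 25, 25))
  rotB <- rigid_transform(rotation = c(0, 0, 2), center = c(25, 25, 25))
  X <- voxel_world_coords(dom)
  brute <- mean(sqrt(rowSums((X - transform_points(rotB, X))^2)))
  expect_equal(warping_index(rotA, rotB, dom), brute, tolerance = 1e-9)
})

test_that("warping index is a pseudo-metric on transforms over a fixed domain", {
  dom <- volume3d(array(0, c(8, 8, 8)), spacing = c(4, 4, 4))
  trs <- random_transforms(9, t_max = 8, r_max = 15, center = c(14, 14, 14),
                           seed = 7)
  for (i in c(1, 4, 7)) {
    a <- trs[[i]]; b <- trs[[i + 1]]; c3 <- trs[[i + 2]]
    expect_equal(warping_index(a, b, dom), warping_index(b, a, dom),
                 tolerance = 1e-12)
    expect_lte(warping_index(a, c3, dom),
               warping_index(a, b, dom) + warping_index(b, c3, dom) + 1e-12)
  }
})

test_that("warping index respects a binary-mask domain", {
  base <- volume3d(array(0, c(6, 6, 6)))
  mk <- array(0, c(6, 6, 6)); mk[1, 1, 1] <- 1
  mask <- binary_mask(mk, reference = base)
  rot <- rigid_transform(rotation = c(0, 0, 90), center = c(0, 0, 0))
  # single voxel at the rotation centre: zero displacement there
  expect_equal(warping_index(identity_transform(), rot, mask), 0)
  empty <- binary_mask(array(0, c(6, 6, 6)), reference = base)
  expect_error(warping_index(rot, rot, empty), "empty")
})

test_that("random rigid transforms obey their bounds, moments and seeding", {
  set.seed(8)
  z <- random_rigid_transform(0, 0)
  expect_equal(c(z$translation, z$rotation), rep(0, 6))

  set.seed(9)
  draws <- t(replicate(1000, {
    tr <- random_rigid_transform(5, 5)
    c(tr$translation, tr$rotation)
  }))
  expect_true(all(draws >= 0 & draws <= 5))
  se <- 5 / sqrt(12) / sqrt(1000)
  expect_lt(max(abs(colMeans(draws) - 2.5)), 3 * se * sqrt(6))

  set.seed(10); t1 <- random_rigid_transform(5, 5)
  set.seed(10); t2 <- random_rigid_transform(5, 5)
  expect_identical(t1$translation, t2$translation)

  set.seed(11)
  sym <- t(replicate(200, random_rigid_transform(5, 5, symmetric = TRUE)$translation))
  expect_true(any(sym < 0) && all(abs(sym) <= 5))
})

test_that("robustness report aggregation identities hold in degenerate settings", {
  fm <- small_fixture_maps()
  cheap <- optimizer_config(max_iterations = 2, pyramid_factors = c(6L))
  empty <- robustness_study(fm$maps$us_map, fm$maps$mr_map, n_trials = 0,
                            cfg = cheap, seed = 1)
  expect_true(is.na(empty$success_rate))

  inf_thr <- robustness_study(fm$maps$us_map, fm$maps$mr_map, n_trials = 2,
                              cfg = cheap, threshold = Inf, seed = 2)
  expect_equal(inf_thr$success_rate, 100)
  expect_equal(inf_thr$success_rate,
               100 * sum(inf_thr$success) / inf_thr$n_trials)
  expect_equal(length(inf_thr$omega), 2L)
})

test_that("landmark CSV round-trips through the documented schema", {
  tr <- rigid_transform(c(1, 2, 3), c(4, 5, 6))
  pairs <- make_pairs(6, tr, seed = 12)
  p <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(pairs, p)
  back <- read_landmarks(p)
  expect_equal(back$source, pairs$source, ignore_attr = TRUE)
  expect_equal(back$target, pairs$target, ignore_attr = TRUE)
})
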