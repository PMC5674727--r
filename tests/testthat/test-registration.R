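test_that("transformation fits recover identity, translation, and quadratic maps", {
  set.seed(8)
  pts <- cbind(runif(20, 1, 500), runif(20, 1, 500))
  for (model in c("similarity", "affine", "polynomial2")) {
    tf <- fit_transform(pts, pts, model)
    expect_equal(transform_points(tf, pts), pts, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # pure translation on 4 points: rotation 0, scale 1
  p4 <- cbind(c(10, 200, 10, 200), c(10, 10, 200, 200))
  tf <- fit_transform(p4, p4 + rep(c(7, -3), each = 4), "similarity")
  expect_equal(tf$params, c(1, 0, 7, -3), tolerance = 1e-10)
  # exact quadratic map recovered from 20 correspondences
  truth <- make_transform("polynomial2",
    c(5, 1.01, 0.02, 1e-5, -2e-5, 1e-5, -3, 0.01, 0.99, 2e-5, 1e-5, -1e-5))
  dst <- transform_points(truth, pts)
  rec <- fit_transform(pts, dst, "polynomial2")
  expect_equal(rec$params, truth$params, tolerance = 1e-6)
})

test_that("degenerate fit geometry raises informative errors", {
  expect_error(fit_transform(cbind(1, 1), cbind(2, 2), "similarity"),
               "at least 2")
  same <- cbind(rep(5, 3), rep(5, 3))
  expect_error(fit_transform(same, same + 1, "similarity"), "coincident")
  col <- cbind(1:5, 2 * (1:5))
  expect_error(fit_transform(col, col, "affine"), "collinear")
  expect_error(fit_transform(col[rep(1, 7), ] + cbind(1:7, 2 * (1:7)),
                             cbind(1:7, 1:7), "polynomial2"),
               "rank-deficient")
})

test_that("similarity and affine inverses compose to the identity", {
  tf <- make_transform("similarity", c(0.99 * cos(0.1), 0.99 * sin(0.1),
                                       15, -8))
  pts <- cbind(runif(10, 1, 400), runif(10, 1, 400))
  expect_equal(transform_points(invert_transform(tf),
                                transform_points(tf, pts)),
               pts, tolerance = 1e-10, ignore_attr = TRUE)
  af <- make_transform("affine", c(1.02, 0.03, 4, -0.02, 0.97, 9))
  expect_equal(transform_points(invert_transform(af),
                                transform_points(af, pts)),
               pts, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("model selection maps inlier counts to the documented classes", {
  expect_equal(select_model(7), "similarity")
  expect_equal(select_model(8), "similarity")
  expect_equal(select_model(9), "affine")
  expect_equal(select_model(30), "affine")
  expect_equal(select_model(31), "polynomial2")
  expect_equal(select_model(500), "polynomial2")
})

test_that("MSAC recovers exact and noisy inlier sets", {
  set.seed(5)
  truth <- make_transform("similarity", c(cos(0.05), sin(0.05), 12, -6))
  n_in <- 20
  src <- cbind(runif(n_in, 1, 500), runif(n_in, 1, 500))
  dst <- transform_points(truth, src)
  pf <- data.frame(x = dst[, 1], y = dst[, 2])
  pm <- data.frame(x = src[, 1], y = src[, 2])
  matches <- data.frame(idx_fixed = 1:n_in, idx_moving = 1:n_in, ratio = 0)
  r <- msac(matches, pf, pm, max_distance = 5, seed = 2)
  expect_equal(r$inliers, 1:n_in)

  # 30 noisy inliers + 30 uniform outliers
  set.seed(6)
  src <- cbind(runif(30, 1, 500), runif(30, 1, 500))
  dst <- transform_points(truth, src) + matrix(rnorm(60, 0, 0.5), 30, 2)
  out_f <- cbind(runif(30, 1, 500), runif(30, 1, 500))
  out_m <- cbind(runif(30, 1, 500), runif(30, 1, 500))
  pf <- data.frame(x = c(dst[, 1], out_f[, 1]), y = c(dst[, 2], out_f[, 2]))
  pm <- data.frame(x = c(src[, 1], out_m[, 1]), y = c(src[, 2], out_m[, 2]))
  matches <- data.frame(idx_fixed = 1:60, idx_moving = 1:60, ratio = 0)
  r20 <- msac(matches, pf, pm, max_distance = 20, seed = 3)
  expect_gte(sum(r20$inliers <= 30), 28)
  expect_lte(sum(r20$inliers > 30), 2)
  # inlier count is non-decreasing in the distance threshold
  counts <- vapply(c(1, 20, 60, 80), function(d) {
    length(msac(matches, pf, pm, max_distance = d, seed = 3)$inliers)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  # too few matches fails gracefully
  expect_equal(msac(matches[1, ], pf, pm, 20, seed = 1)$status, "failed")
})

test_that("MSAC leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(msac(data.frame(idx_fixed = 1:5, idx_moving = 1:5, ratio = 0),
                 data.frame(x = 1:5 * 10, y = 1:5 * 7),
                 data.frame(x = 1:5 * 10, y = 1:5 * 7),
                 max_distance = 5, seed = 9))
  expect_identical(runif(1), before)
})

test_that("image warping is exact for identity, round trips, and rotation", {
  set.seed(4)
  img <- matrix(runif(40 * 40), 40, 40)
  w <- warp_image(img, identity_transform())
  expect_equal(unclass(w), img, ignore_attr = TRUE, tolerance = 1e-12)
  # +10 then -10 translation round trip (interior exact)
  t1 <- make_transform("similarity", c(1, 0, 10, 0))
  t2 <- make_transform("similarity", c(1, 0, -10, 0))
  rt <- warp_image(warp_image(img, t1), t2)
  inner <- 12:28
  expect_equal(rt[inner, inner], img[inner, inner], tolerance = 1e-12,
               ignore_attr = TRUE)
  # 90-degree rotation about the centre maps the grid onto itself
  n <- 21; c0 <- (n + 1) / 2
  checker <- (outer(1:n, 1:n, "+") %% 2) * 0.8 + 0.1
  th <- pi / 2
  a <- cos(th); b <- sin(th)
  rot <- make_transform("similarity", c(a, b, c0 - a * c0 + b * c0,
                                        c0 - b * c0 - a * c0))
  wr <- warp_image(checker, rot)
  expected <- t(checker)[, n:1]      # counter-clockwise image content
  mism <- max(abs(unclass(wr) - expected))
  expect_lt(mism, 1e-9)
})

test_that("register_pair on an identical pair reaches near-zero error", {
  ph <- generate_fundus(phantom_config(size = 291L, seed = 42))
  lm <- data.frame(x_fixed = c(100, 180, 140, 200, 120),
                   y_fixed = c(100, 120, 200, 180, 160))
  lm$x_moving <- lm$x_fixed; lm$y_moving <- lm$y_fixed
  res <- register_pair(ph$img, ph$img,
                       register_config(repeats_per_distance = 5L),
                       landmarks = lm, seed = 3)
  expect_equal(res$status, "success")
  expect_lt(res$tre, 0.5)
})

test_that("registration of a known affine phantom warp stays below 5 px", {
  pair <- generate_pair(phantom_config(seed = 55),
                        transform_spec = list(model = "affine",
                                              rotation_deg = 3, scale = 1.01,
                                              overlap = 0.9, shear = 0.01),
                        category = "S")
  res <- register_pair(pair$fixed, pair$moving,
                       register_config(repeats_per_distance = 20L),
                       landmarks = pair$landmarks, seed = 5)
  expect_equal(res$status, "success")
  expect_lt(res$tre, 5)
})

test_that("registration failure is reported, never raised", {
  blank <- as_gray_image(matrix(0.5, 128, 128))
  # one warning per image with no detectable points
  expect_warning(expect_warning(
    res <- register_pair(blank, blank,
                         register_config(repeats_per_distance = 2L),
                         seed = 1)))
  expect_equal(res$status, "failed")
  expect_match(res$reason, "no feature")
})

test_that("registration results are bit-identical across runs with one seed", {
  pair <- generate_pair(phantom_config(size = 291L, seed = 12),
                        transform_spec = list(overlap = 0.92,
                                              rotation_deg = 2),
                        category = "S")
  cfg <- register_config(repeats_per_distance = 5L)
  r1 <- register_pair(pair$fixed, pair$moving, cfg,
                      landmarks = pair$landmarks, seed = 77)
  r2 <- register_pair(pair$fixed, pair$moving, cfg,
                      landmarks = pair$landmarks, seed = 77)
  expect_identical(r1, r2)
})
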