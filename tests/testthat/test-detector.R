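test_that("candidate lattice covers exactly [4, M-3] x [4, N-3]", {
  g10 <- candidate_grid(matrix(0, 10, 10))
  expect_equal(nrow(g10), 16L)
  expect_setequal(unique(g10$x), 4:7)
  expect_setequal(unique(g10$y), 4:7)
  expect_equal(nrow(candidate_grid(matrix(0, 8, 8))), 4L)
  g7 <- candidate_grid(matrix(0, 7, 7))
  expect_equal(nrow(g7), 1L)
  expect_equal(c(g7$x, g7$y), c(4L, 4L))
  expect_equal(nrow(suppressMessages(candidate_grid(matrix(0, 6, 9)))), 0L)
})

test_that("ring geometry is the 8-neighborhood and the radius-3 digital circle", {
  io <- inner_ring_offsets()
  oo <- outer_ring_offsets()
  expect_equal(nrow(io), 8L)
  expect_equal(nrow(oo), 16L)
  expect_true(all(pmax(abs(io[, 1]), abs(io[, 2])) == 1L))
  expect_equal(nrow(unique(io)), 8L)
  expect_equal(nrow(unique(oo)), 16L)
  # FAST-style circle: 4 axial points at distance 3, 12 intermediate
  r <- sqrt(oo[, 1]^2 + oo[, 2]^2)
  expect_equal(sum(r == 3 & (oo[, 1] == 0 | oo[, 2] == 0)), 4L)
  expect_true(all(r >= sqrt(8) - 1e-9 & r <= sqrt(10) + 1e-9))
  # consecutive positions are adjacent on the circle (cyclic ordering)
  steps <- abs(diff(rbind(oo, oo[1, , drop = FALSE])))
  expect_true(all(pmax(steps[, 1], steps[, 2]) == 1L))
})

test_that("ring sampling respects bounds, constants, and 90-degree rotation", {
  const <- matrix(0.4, 12, 12)
  s <- sample_rings(const, 6L, 6L)
  expect_equal(length(s$inner), 8L)
  expect_equal(length(s$outer), 16L)
  expect_true(all(s$inner == 0.4) && all(s$outer == 0.4))
  expect_error(sample_rings(const, 3L, 6L), "bounds")
  expect_error(sample_rings(const, 6L, 10L), "bounds")
  # rotating the patch 90 degrees permutes the outer ring by 4 positions
  set.seed(5)
  n <- 13L
  patch <- matrix(runif(n * n), n, n)
  rot_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
  c0 <- 7L
  s0 <- sample_rings(patch, c0, c0)
  s1 <- sample_rings(rot_cw(patch), c0, c0)
  expect_equal(s1$outer, s0$outer[((seq_len(16) - 1 - 4) %% 16) + 1])
  expect_equal(s1$inner, s0$inner[((seq_len(8) - 1 - 2) %% 8) + 1])
})

test_that("inner-ring test recognizes +, x, both, and neither", {
  # ring order: up, ur, right, dr, down, dl, left, ul
  plus_only <- c(0.8, 0.5, 0.2, 0.5, 0.8, 0.5, 0.2, 0.5)
  r <- inner_ring_test(plus_only)
  expect_true(r$passed)
  expect_equal(r$shapes, "+")
  expect_equal(r$beta, 0.5)
  expect_false(inner_ring_test(rep(0.5, 8))$passed)
  both <- c(0.9, 0.8, 0.1, 0.2, 0.9, 0.8, 0.1, 0.2)
  rb <- inner_ring_test(both)
  expect_true(rb$passed)
  expect_setequal(rb$shapes, c("+", "x"))
  expect_equal(rb$beta, median(both))
  # opposite polarity: axial pair darker than lateral pair
  dark_axial <- c(0.1, 0.5, 0.9, 0.5, 0.1, 0.5, 0.9, 0.5)
  expect_true(inner_ring_test(dark_axial)$passed)
  # gradient-like (one bright, one dark in the same pair) fails
  ramp <- c(0.9, 0.7, 0.5, 0.3, 0.1, 0.3, 0.5, 0.7)
  expect_false(inner_ring_test(ramp)$passed)
  # beta stays within the inner-ring value range
  expect_gte(rb$beta, min(both)); expect_lte(rb$beta, max(both))
})

test_that("outer-ring labels follow the three-way rule with inclusive boundaries", {
  eps <- 0.0010
  beta <- 0.5
  expect_equal(label_outer(0.5, beta, eps), "s")
  expect_equal(label_outer(beta + eps, beta, eps), "s")
  expect_equal(label_outer(beta - eps, beta, eps), "s")
  expect_equal(label_outer(0.4, beta, eps), "d")
  expect_equal(label_outer(beta + eps + 1e-9, beta, eps), "l")
  expect_equal(label_outer(c(0, 0.5, 1), beta, eps), c("d", "s", "l"))
  expect_error(label_outer(0.5, beta, -0.1))
})

test_that("outer-ring pattern test follows the arc rules", {
  lab <- function(s) strsplit(s, "")[[1]]
  expect_true(outer_ring_test(lab("ddddllllddddllll")))    # d4 l4 d4 l4
  expect_false(outer_ring_test(rep("s", 16)))
  expect_false(outer_ring_test(lab("dllllddddllllsss")))   # arc of 1 + s-run of 3
  expect_false(outer_ring_test(lab("ddddddddllllllll")))   # only one arc of each
  expect_false(outer_ring_test(lab("dddddddddlllllll")))   # d-arc of length 9
  expect_true(outer_ring_test(lab("ddsslldddsllddll")))    # s-gaps allowed
  expect_false(outer_ring_test(lab("ddssddssllssllss")))   # adjacent same-label arcs
  expect_true(outer_ring_test(lab("ddlldddlllddllss")))
})

test_that("response strength is the mean dark deficit plus mean light excess", {
  beta <- 0.5
  outer <- c(rep(beta - 0.2, 8), rep(beta + 0.2, 8))
  labels <- c(rep("d", 8), rep("l", 8))
  expect_equal(response_strength(outer, labels, beta), 0.4)
  expect_equal(response_strength(rep(beta, 16), rep("s", 16), beta), 0)
  doubled <- c(rep(beta - 0.4, 8), rep(beta + 0.4, 8))
  expect_equal(response_strength(doubled, labels, beta),
               2 * response_strength(outer, labels, beta))
  expect_equal(response_strength(outer, rep("d", 16), beta), 0)
})

test_that("non-maxima suppression keeps local maxima with lexicographic ties", {
  iso <- data.frame(x = 5L, y = 5L, response = 0.2)
  expect_equal(nrow(nonmax_suppress(iso)), 1L)
  two <- data.frame(x = c(5L, 6L), y = c(5L, 5L), response = c(0.3, 0.5))
  kept <- nonmax_suppress(two)
  expect_equal(kept$response, 0.5)
  tie <- data.frame(x = c(6L, 5L), y = c(5L, 5L), response = c(0.4, 0.4))
  kept <- nonmax_suppress(tie)
  expect_equal(nrow(kept), 1L)
  expect_equal(c(kept$x, kept$y), c(5L, 5L))
  # chain: middle maximum kills both neighbors (pure, non-greedy rule)
  chain <- data.frame(x = 4:6, y = rep(5L, 3), response = c(0.3, 0.5, 0.4))
  expect_equal(nonmax_suppress(chain)$response, 0.5)
  # distant points never interact
  far <- data.frame(x = c(5L, 9L), y = c(5L, 5L), response = c(0.1, 0.9))
  expect_equal(nrow(nonmax_suppress(far)), 2L)
})

test_that("subpixel refinement finds the parabola vertex, clamped", {
  m <- matrix(0.1, 7, 7)
  m[4, 3:5] <- c(0.2, 0.5, 0.4)   # 1D parabola along x
  p <- subpixel_refine(m, 4L, 4L)
  expect_equal(p[1], 4 + (0.2 - 0.4) / (2 * (0.2 - 2 * 0.5 + 0.4)))
  expect_equal(p[1], 4.25)
  # symmetric peak: no offset
  s <- matrix(0.1, 5, 5); s[2:4, 2:4] <- c(0.2, 0.3, 0.2, 0.3, 0.9, 0.3,
                                           0.2, 0.3, 0.2)
  expect_equal(subpixel_refine(s, 3L, 3L), c(3, 3))
  # flat neighborhood: degenerate fallback
  expect_equal(subpixel_refine(matrix(0.4, 5, 5), 3L, 3L), c(3, 3))
  # offsets clamp to half a pixel
  e <- matrix(0, 5, 5); e[3, 2:4] <- c(0, 0.49, 0.5)
  expect_lte(abs(subpixel_refine(e, 3L, 3L)[1] - 3), 0.5)
})

test_that("octave coordinates lift by powers of two about pixel centres", {
  expect_equal(to_input_coords(7.5, 3.25, 0), cbind(x = 7.5, y = 3.25))
  # (10, 20) in octave 2: factor 4 about the half-pixel origin
  expect_equal(to_input_coords(10, 20, 2),
               cbind(x = (10 - 0.5) * 4 + 0.5, y = (20 - 0.5) * 4 + 0.5))
  expect_equal(to_input_coords(10, 20, 2), cbind(x = 38.5, y = 78.5))
  # the centre pixel is a fixed point of the lifting
  expect_equal(to_input_coords(0.5, 0.5, 3), cbind(x = 0.5, y = 0.5))
  # working-to-native rescale is a separate multiplicative factor
  expect_equal(2912 / 583, 4.9948, tolerance = 1e-4)
})

test_that("detector returns nothing on a constant image", {
  img <- as_gray_image(matrix(0.5, 64, 64))
  expect_warning(pts <- detect_dsaddle(img), "no feature points")
  expect_equal(nrow(pts), 0L)
})

test_that("detector finds points on vessels of high and low contrast", {
  card <- vessel_card(contrasts = c(0.5, 0.1), width = 3)
  pts <- detect_dsaddle(card$img)
  expect_gt(nrow(pts), 0L)
  expect_gte(count_on_mask(pts, card$masks[[1]], 2), 1L)
  expect_gte(count_on_mask(pts, card$masks[[2]], 2), 1L)
})

test_that("detection on a vessel is robust across its contrast range", {
  # the ring tests are ordinal, so low-contrast vessels are found about as
  # often as high-contrast ones (the detector's design goal)
  counts <- vapply(c(0.05, 0.1, 0.25, 0.5), function(ct) {
    card <- vessel_card(contrasts = ct, width = 4)
    count_on_mask(detect_dsaddle(card$img), card$masks[[1]], 3)
  }, numeric(1))
  expect_true(all(counts > 0))
  expect_gte(min(counts), 0.3 * max(counts))
})

test_that("detections are 90-degree rotation covariant away from borders", {
  ph <- generate_fundus(phantom_config(size = 201L, seed = 4))
  img <- ph$img
  rot_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
  p0 <- detect_dsaddle(img)
  p1 <- detect_dsaddle(as_gray_image(rot_cw(unclass(img))))
  n <- nrow(img)
  # (x, y) -> (n + 1 - y, x) under clockwise rotation
  ex <- n + 1 - p0$y; ey <- p0$x
  interior <- p0$x > 20 & p0$x < n - 20 & p0$y > 20 & p0$y < n - 20
  dmin <- vapply(which(interior), function(i) {
    min(sqrt((p1$x - ex[i])^2 + (p1$y - ey[i])^2))
  }, numeric(1))
  expect_gt(mean(dmin <= 1), 0.95)
})

test_that("detection is deterministic and in-bounds across octaves", {
  ph <- generate_fundus(phantom_config(size = 201L, seed = 9))
  p1 <- detect_dsaddle(ph$img)
  p2 <- detect_dsaddle(ph$img)
  expect_identical(p1, p2)
  expect_gt(nrow(p1), 0L)
  for (o in unique(p1$octave)) {
    po <- p1[p1$octave == o, ]
    oct_dim <- dim(ph$img)
    for (i in seq_len(o)) oct_dim <- ceiling(oct_dim / 2)
    sx <- ncol(ph$img) / oct_dim[2]; sy <- nrow(ph$img) / oct_dim[1]
    ox <- (po$x - 0.5) / sx + 0.5; oy <- (po$y - 0.5) / sy + 0.5
    expect_true(all(ox >= 3.5 & ox <= oct_dim[2] - 2.5))
    expect_true(all(oy >= 3.5 & oy <= oct_dim[1] - 2.5))
  }
  expect_true(all(p1$response >= 0))
})

test_that("compiled bulk ring testing agrees with the reference implementation", {
  set.seed(31)
  for (rep in 1:3) {
    # coarse quantization provokes ties and s-labels
    dog <- matrix(sample(seq(0, 1, by = 0.05), 30 * 30, replace = TRUE),
                  30, 30)
    eps <- 0.06
    bulk <- dsaddle:::ring_test_bulk(dog, eps)
    ref <- do.call(rbind, lapply(seq_len(nrow(candidate_grid(dog))), function(i) {
      g <- candidate_grid(dog)[i, ]
      s <- sample_rings(dog, g$x, g$y)
      it <- inner_ring_test(s$inner)
      if (!it$passed) return(NULL)
      labs <- label_outer(s$outer, it$beta, eps)
      if (!outer_ring_test(labs)) return(NULL)
      data.frame(x = g$x, y = g$y,
                 response = response_strength(s$outer, labs, it$beta),
                 beta = it$beta)
    }))
    if (is.null(ref)) ref <- data.frame(x = integer(0), y = integer(0),
                                        response = numeric(0),
                                        beta = numeric(0))
    rownames(ref) <- NULL
    expect_equal(bulk$points, ref)
  }
})
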