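#' Configuration of the synthetic fundus phantom
#'
#' The generator emulates the gross appearance of a fundus photograph:
#' a circular field of view on a dark frame, a branching vessel tree whose
#' widths and contrasts span the configured ranges, a bright optic disc,
#' multiplicative illumination falloff towards the frame boundary,
#' dark-spot occlusions, and additive Gaussian noise. Defaults mirror the
#' working conditions of fundus registration studies: 583-pixel working
#' resolution, vessel widths 2-12 px, contrasts 0.05-0.5.
#'
#' @param size image side in pixels (default 583, the working resolution).
#' @param n_vessels number of root vessels leaving the optic disc.
#' @param vessel_width_range full width range of vessels, pixels.
#' @param vessel_contrast_range valley depth range in intensity units.
#' @param illumination_gradient amplitude of the radial falloff in `[0, 1]`.
#' @param dark_spots list with `count` and `radius_range` (pixels).
#' @param noise_sigma additive Gaussian sensor noise standard deviation at
#'   the working resolution. The default 0.005 models 8-bit capture noise
#'   (about 0.025) attenuated by the 5x area-averaging downsample from the
#'   native to the working resolution.
#' @param texture_amplitude standard deviation of the spatially correlated
#'   background texture (choroidal mottle / nonuniform pigmentation); part
#'   of the anatomy, so it warps with the scene between the two views of a
#'   pair.
#' @param texture_scale correlation length of the background texture, px.
#' @param bit_depth intensity quantization of the emitted image (default 8,
#'   as produced by fundus cameras and PNG files; `Inf` for continuous).
#' @param seed integer; all randomness of a phantom flows from it.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(size = 583L, n_vessels = 9L,
                           vessel_width_range = c(2, 12),
                           vessel_contrast_range = c(0.05, 0.5),
                           illumination_gradient = 0.25,
                           dark_spots = list(count = 3L,
                                             radius_range = c(8, 30)),
                           noise_sigma = 0.005, texture_amplitude = 0.04,
                           texture_scale = 4, bit_depth = 8L, seed = 1L) {
  stopifnot(size >= 64L, n_vessels >= 0L,
            vessel_width_range[1] <= vessel_width_range[2],
            vessel_contrast_range[1] <= vessel_contrast_range[2],
            noise_sigma >= 0)
  structure(list(size = as.integer(size), n_vessels = as.integer(n_vessels),
                 vessel_width_range = vessel_width_range,
                 vessel_contrast_range = vessel_contrast_range,
                 illumination_gradient = illumination_gradient,
                 dark_spots = dark_spots, noise_sigma = noise_sigma,
                 texture_amplitude = texture_amplitude,
                 texture_scale = texture_scale,
                 bit_depth = bit_depth, seed = as.integer(seed)),
            class = "phantom_config")
}

# Sample the anatomy (vessel tree + disc) in fixed-frame coordinates.
# The tree extends well beyond the field of view so that warped (moving)
# views still contain anatomy. Caller provides the RNG state.
sample_scene <- function(cfg) {
  S <- cfg$size
  center <- c((S + 1) / 2, (S + 1) / 2)
  extent <- 1.25 * S
  disc_angle <- runif(1, 0, 2 * pi)
  disc <- list(center = center + 0.55 * 0.48 * S *
                 c(cos(disc_angle), sin(disc_angle)),
               radius = 0.09 * S, brightness = 0.16)
  vessels <- list()
  if (cfg$n_vessels > 0L) {
    queue <- lapply(seq_len(cfg$n_vessels), function(i) {
      list(pos = disc$center,
           dir = disc_angle + pi + runif(1, -2.2, 2.2),
           width = runif(1, cfg$vessel_width_range[1],
                         cfg$vessel_width_range[2]),
           contrast = runif(1, cfg$vessel_contrast_range[1],
                            cfg$vessel_contrast_range[2]),
           depth = 0L)
    })
    while (length(queue) > 0L && length(vessels) < 40L) {
      v <- queue[[1]]; queue <- queue[-1]
      pts <- matrix(NA_real_, 600L, 2L)
      pos <- v$pos; dir <- v$dir
      n_pts <- 0L
      for (s in seq_len(600L)) {
        pts[s, ] <- pos
        n_pts <- s
        dir <- dir + rnorm(1, 0, 0.06)
        pos <- pos + 2 * c(cos(dir), sin(dir))
        if (sqrt(sum((pos - center)^2)) > extent) break
        if (v$depth < 2L && runif(1) < 0.012 && length(queue) < 25L) {
          queue[[length(queue) + 1L]] <-
            list(pos = pos,
                 dir = dir + sample(c(-1, 1), 1) * runif(1, 0.4, 0.9),
                 width = max(v$width * 0.72, cfg$vessel_width_range[1]),
                 contrast = max(v$contrast * 0.85,
                                cfg$vessel_contrast_range[1]),
                 depth = v$depth + 1L)
        }
      }
      vessels[[length(vessels) + 1L]] <-
        list(path = pts[seq_len(n_pts), , drop = FALSE],
             width = v$width, contrast = v$contrast)
    }
  }
  # background texture: correlated Gaussian field over an extended frame so
  # warped (moving) views sample the same anatomy-locked mottle
  tex_origin <- floor(-0.7 * S)
  tex_n <- ceiling(2.4 * S)
  tex <- NULL
  if (cfg$texture_amplitude > 0) {
    tex <- gaussian_blur(matrix(rnorm(tex_n * tex_n), tex_n, tex_n),
                         cfg$texture_scale, trunc_factor = 3)
    tex <- tex / sd(tex)
  }
  list(vessels = vessels, disc = disc, size = S, center = center,
       fov_radius = 0.48 * S,
       texture = list(field = tex, origin = tex_origin))
}

# Resample a polyline to roughly constant arc-length spacing.
resample_polyline <- function(path, spacing) {
  if (nrow(path) < 2L) return(path)
  seg <- sqrt(rowSums(diff(path)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total < spacing) return(path[c(1, nrow(path)), , drop = FALSE])
  t_out <- seq(0, total, by = spacing)
  cbind(approx(s, path[, 1], xout = t_out)$y,
        approx(s, path[, 2], xout = t_out)$y)
}

# Render one view of a scene. Degradations (illumination offset, dark
# spots, noise) are drawn from render_seed so the two views of a pair are
# independently degraded; the anatomy-locked background texture is sampled
# through view_tf (this frame -> scene frame), identity when NULL.
render_view <- function(scene, cfg, render_seed, view_tf = NULL) {
  S <- scene$size
  center <- scene$center
  R <- scene$fov_radius
  xx <- matrix(seq_len(S), S, S, byrow = TRUE)
  yy <- matrix(seq_len(S), S, S)
  r2_center <- (xx - center[1])^2 + (yy - center[2])^2
  fov <- r2_center <= R^2

  img <- matrix(0.55, S, S)
  tex <- scene$texture
  if (!is.null(tex$field)) {
    sc_xy <- if (is.null(view_tf)) cbind(as.vector(xx), as.vector(yy))
             else transform_points(view_tf, cbind(as.vector(xx),
                                                  as.vector(yy)))
    tv <- interp_bilinear(tex$field,
                          matrix(sc_xy[, 1] - tex$origin, S, S),
                          matrix(sc_xy[, 2] - tex$origin, S, S))
    img <- img + cfg$texture_amplitude * tv
  }
  d <- scene$disc
  img <- img + d$brightness *
    exp(-((xx - d$center[1])^2 + (yy - d$center[2])^2)^2 / d$radius^4)

  depth <- matrix(0, S, S)
  mask <- matrix(FALSE, S, S)
  for (v in scene$vessels) {
    sigma_v <- max(v$width / 2.355, 0.6)
    rad <- ceiling(2.5 * sigma_v)
    pts <- resample_polyline(v$path, max(0.5, sigma_v / 2))
    for (i in seq_len(nrow(pts))) {
      px <- pts[i, 1]; py <- pts[i, 2]
      c0 <- max(1L, floor(px) - rad); c1 <- min(S, ceiling(px) + rad)
      r0 <- max(1L, floor(py) - rad); r1 <- min(S, ceiling(py) + rad)
      if (c0 > c1 || r0 > r1) next
      wx <- seq.int(c0, c1); wy <- seq.int(r0, r1)
      dd <- outer((wy - py)^2, (wx - px)^2, "+")
      depth[wy, wx] <- pmax(depth[wy, wx],
                            v$contrast * exp(-dd / (2 * sigma_v^2)))
      cx <- round(px); cy <- round(py)
      if (cx >= 1L && cx <= S && cy >= 1L && cy <= S) mask[cy, cx] <- TRUE
    }
  }
  img <- img - depth

  with_seed(render_seed, {
    ill_c <- center + runif(2, -0.07, 0.07) * S
    d_ill <- sqrt((xx - ill_c[1])^2 + (yy - ill_c[2])^2)
    ill <- pmax(1 - cfg$illumination_gradient * (d_ill / R)^3, 0.2)
    img <- img * ill
    ns <- cfg$dark_spots$count
    if (ns > 0L) {
      for (i in seq_len(ns)) {
        ang <- runif(1, 0, 2 * pi); rr <- runif(1, 0, 0.8 * R)
        sc <- center + rr * c(cos(ang), sin(ang))
        srad <- runif(1, cfg$dark_spots$radius_range[1],
                      cfg$dark_spots$radius_range[2])
        sdep <- runif(1, 0.2, 0.5)
        dd <- (xx - sc[1])^2 + (yy - sc[2])^2
        img <- img * (1 - sdep * exp(-dd / srad^2))
      }
    }
    if (cfg$noise_sigma > 0) {
      img <- img + matrix(rnorm(S * S, 0, cfg$noise_sigma), S, S)
    }
    # the aperture mask is optical: the frame sees no photons and its
    # residual dark current is crushed by black-level quantization
    img[!fov] <- 0.02
  })
  mask[!fov] <- FALSE
  img <- pmin(pmax(img, 0), 1)
  # camera quantization: real acquisitions (and PNG fixtures) are 8-bit
  bd <- if (is.null(cfg$bit_depth)) 8L else cfg$bit_depth
  if (is.finite(bd)) {
    levels <- 2^bd - 1
    img <- round(img * levels) / levels
  }
  list(img = as_gray_image(img), vessel_mask = mask)
}

#' Generate a synthetic fundus image
#'
#' @param cfg a [phantom_config()].
#' @return list with `img` (gray image), `vessel_mask` (logical centerline
#'   mask, the detection oracle), and `scene` (the sampled anatomy).
#' @export
generate_fundus <- function(cfg = phantom_config()) {
  scene <- with_seed(cfg$seed, sample_scene(cfg))
  out <- render_view(scene, cfg, render_seed = cfg$seed * 2L + 1L)
  out$scene <- scene
  out
}

# Solve the centre distance of two equal circles of radius R whose lens
# intersection is `overlap` of one circle's area.
overlap_to_distance <- function(overlap, R) {
  if (overlap <= 0 || overlap > 1) {
    stop("requested overlap ", overlap, " is infeasible: must lie in (0, 1]")
  }
  if (overlap >= 1) return(0)
  lens <- function(d) {
    (2 * R^2 * acos(d / (2 * R)) - (d / 2) * sqrt(4 * R^2 - d^2)) /
      (pi * R^2) - overlap
  }
  uniroot(lens, c(0, 2 * R - 1e-9), tol = 1e-10)$root
}

# Invert a transformation at specific points (Newton for polynomial2).
invert_points <- function(tf, xy) {
  if (tf$model != "polynomial2") {
    return(transform_points(invert_transform(tf), xy))
  }
  p <- tf$params
  guess_tf <- approximate_inverse(tf, c(min(xy[, 1]) - 50, max(xy[, 1]) + 50,
                                        min(xy[, 2]) - 50, max(xy[, 2]) + 50))
  z <- transform_points(guess_tf, xy)
  for (it in 1:12) {
    f <- transform_points(tf, z) - xy
    x <- z[, 1]; y <- z[, 2]
    j11 <- p[2] + 2 * p[4] * x + p[5] * y
    j12 <- p[3] + p[5] * x + 2 * p[6] * y
    j21 <- p[8] + 2 * p[10] * x + p[11] * y
    j22 <- p[9] + p[11] * x + 2 * p[12] * y
    det <- j11 * j22 - j12 * j21
    z <- z - cbind((j22 * f[, 1] - j12 * f[, 2]) / det,
                   (-j21 * f[, 1] + j11 * f[, 2]) / det)
    if (max(abs(f)) < 1e-12) break
  }
  z
}

# Build the ground-truth transformation (moving -> fixed) about the image
# centre: rotation theta, scale s, optional shear (affine) or centred
# quadratic perturbation (polynomial2), then translation t.
build_true_transform <- function(model, center, theta, s, t,
                                 shear = c(0, 0), quad = 0) {
  cx <- center[1]; cy <- center[2]
  Rm <- s * matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  if (model == "similarity") {
    a <- Rm[1, 1]; b <- Rm[2, 1]
    tx <- cx + t[1] - (a * cx - b * cy)
    ty <- cy + t[2] - (b * cx + a * cy)
    return(make_transform("similarity", c(a, b, tx, ty)))
  }
  M <- Rm %*% (diag(2) + matrix(c(0, shear[2], shear[1], 0), 2, 2))
  if (model == "affine") {
    tv <- c(cx, cy) + t - M %*% c(cx, cy)
    return(make_transform("affine", c(M[1, 1], M[1, 2], tv[1],
                                      M[2, 1], M[2, 2], tv[2])))
  }
  # polynomial2: exact fit to the closed-form map on a grid
  qc <- if (length(quad) == 6L) quad else
    runif(6, -quad, quad)
  fmap <- function(xy) {
    u <- xy[, 1] - cx; v <- xy[, 2] - cy
    lin <- cbind(M[1, 1] * u + M[1, 2] * v, M[2, 1] * u + M[2, 2] * v)
    cbind(cx + t[1] + lin[, 1] + qc[1] * u^2 + qc[2] * u * v + qc[3] * v^2,
          cy + t[2] + lin[, 2] + qc[4] * u^2 + qc[5] * u * v + qc[6] * v^2)
  }
  g <- seq(-300, 300, length.out = 7)
  src <- cbind(rep(g + cx, 7), rep(g + cy, each = 7))
  fit_transform(src, fmap(src), "polynomial2")
}

#' Generate a synthetic fundus image pair with known ground truth
#'
#' The moving image is a warped, independently degraded view of the same
#' (category S/P) or a perturbed (category A) anatomy; the warp is the
#' known ground-truth transformation and ten landmark correspondences are
#' sampled on vessel centerlines visible in both fields of view.
#'
#' Category defaults follow the three registration applications:
#' super-resolution `S` (overlap 86-100%, rotation 0-5 deg), mosaicking
#' `P` (overlap 17-89%, rotation 0-7 deg), longitudinal `A` (overlap
#' 95-100%, rotation 0-4 deg, anatomy jittered plus small lesions).
#'
#' @param cfg a [phantom_config()]; `cfg$seed` drives everything.
#' @param transform_spec optional list overriding the ground truth: fields
#'   `model` (`"similarity"`, `"affine"`, `"polynomial2"`), `rotation_deg`
#'   (scalar or range), `scale` (scalar or range), `overlap` (target
#'   fraction, scalar or range), `shear` (scalar magnitude, affine),
#'   `quad` (scalar magnitude of the centred quadratic coefficients).
#' @param category `"S"`, `"P"` or `"A"`.
#' @return object of class `phantom_pair`: `fixed`, `moving` (gray
#'   images), `fixed_mask`, `moving_mask` (centerline oracles),
#'   `true_transform` (moving -> fixed), `landmarks`, `overlap_fraction`
#'   (measured on the FOV masks), `overlap_target`, `category`, `seed`.
#' @export
generate_pair <- function(cfg = phantom_config(),
                          transform_spec = list(),
                          category = c("S", "P", "A")) {
  category <- match.arg(category)
  defaults <- switch(category,
    S = list(model = "similarity", rotation_deg = c(0, 5),
             scale = c(0.98, 1.02), overlap = c(0.86, 1)),
    P = list(model = "similarity", rotation_deg = c(0, 7),
             scale = c(0.98, 1.02), overlap = c(0.17, 0.89)),
    A = list(model = "similarity", rotation_deg = c(0, 4),
             scale = c(0.98, 1.02), overlap = c(0.95, 1)))
  spec <- utils::modifyList(defaults, transform_spec)
  pick <- function(v) if (length(v) == 2L) runif(1, v[1], v[2]) else v

  S <- cfg$size
  scene <- with_seed(cfg$seed, sample_scene(cfg))
  center <- scene$center
  R <- scene$fov_radius

  tf_bits <- with_seed(cfg$seed + 17L, {
    theta <- pick(spec$rotation_deg) * pi / 180
    s <- pick(spec$scale)
    ov <- pick(spec$overlap)
    dmag <- overlap_to_distance(min(ov, 1), R)
    phi <- runif(1, 0, 2 * pi)
    shear <- if (!is.null(spec$shear)) runif(2, -spec$shear, spec$shear)
             else c(0, 0)
    quad <- if (!is.null(spec$quad)) runif(6, -spec$quad, spec$quad) else 0
    list(theta = theta, s = s, overlap = ov,
         t = dmag * c(cos(phi), sin(phi)), shear = shear, quad = quad)
  })
  true_tf <- build_true_transform(spec$model, center, tf_bits$theta,
                                  tf_bits$s, tf_bits$t,
                                  shear = tf_bits$shear,
                                  quad = tf_bits$quad)

  # moving-frame anatomy: inverse-warp the polylines (perturbed for A)
  scene_mov <- scene
  if (category == "A") {
    scene_mov <- with_seed(cfg$seed + 23L, perturb_scene(scene_mov))
  }
  sc <- abs(det(linear_part(true_tf, center)))^0.5
  scene_mov$vessels <- lapply(scene_mov$vessels, function(v) {
    v$path <- invert_points(true_tf, v$path)
    v$width <- v$width / sc
    v
  })
  scene_mov$disc$center <- invert_points(true_tf,
                                         rbind(scene_mov$disc$center))[1, ]
  scene_mov$disc$radius <- scene_mov$disc$radius / sc

  fixed <- render_view(scene, cfg, render_seed = cfg$seed * 2L + 1L)
  moving <- render_view(scene_mov, cfg, render_seed = cfg$seed * 2L + 2L,
                        view_tf = true_tf)

  landmarks <- with_seed(cfg$seed + 31L,
                         sample_landmarks(scene, true_tf, center, R))

  # measured FOV overlap of the warped pair
  xx <- matrix(seq_len(S), S, S, byrow = TRUE)
  yy <- matrix(seq_len(S), S, S)
  fov_fixed <- (xx - center[1])^2 + (yy - center[2])^2 <= R^2
  back <- invert_points(true_tf, cbind(as.vector(xx), as.vector(yy)))
  fov_mov <- matrix((back[, 1] - center[1])^2 +
                    (back[, 2] - center[2])^2 <= (R / sc)^2, S, S)
  overlap_meas <- sum(fov_fixed & fov_mov) / sum(fov_fixed)

  structure(list(fixed = fixed$img, moving = moving$img,
                 fixed_mask = fixed$vessel_mask,
                 moving_mask = moving$vessel_mask,
                 true_transform = true_tf, landmarks = landmarks,
                 overlap_fraction = overlap_meas,
                 overlap_target = tf_bits$overlap,
                 category = category, seed = cfg$seed, config = cfg),
            class = "phantom_pair")
}

# linear part (Jacobian) of a transformation at a point
linear_part <- function(tf, at) {
  p <- tf$params
  switch(tf$model,
    similarity = matrix(c(p[1], p[2], -p[2], p[1]), 2, 2),
    affine = matrix(c(p[1], p[4], p[2], p[5]), 2, 2),
    polynomial2 = {
      x <- at[1]; y <- at[2]
      matrix(c(p[2] + 2 * p[4] * x + p[5] * y,
               p[8] + 2 * p[10] * x + p[11] * y,
               p[3] + p[5] * x + 2 * p[6] * y,
               p[9] + p[11] * x + 2 * p[12] * y), 2, 2)
    })
}

# Category-A anatomy perturbation: smooth tortuosity jitter of each vessel
# plus a couple of small lesions rendered as extra short wide "vessels".
perturb_scene <- function(scene) {
  scene$vessels <- lapply(scene$vessels, function(v) {
    n <- nrow(v$path)
    if (n < 4L) return(v)
    tt <- seq_len(n)
    amp <- runif(1, 0.6, 1.8)
    lambda <- runif(1, 60, 160)
    phase <- runif(2, 0, 2 * pi)
    v$path <- v$path + cbind(amp * sin(2 * pi * tt * 2 / lambda + phase[1]),
                             amp * sin(2 * pi * tt * 2 / lambda + phase[2]))
    v
  })
  for (i in 1:2) {
    ang <- runif(1, 0, 2 * pi); rr <- runif(1, 0.2, 0.7) * scene$fov_radius
    pos <- scene$center + rr * c(cos(ang), sin(ang))
    step <- runif(1, 0, 2 * pi)
    path <- rbind(pos, pos + 4 * c(cos(step), sin(step)),
                  pos + 8 * c(cos(step), sin(step)))
    scene$vessels[[length(scene$vessels) + 1L]] <-
      list(path = path, width = runif(1, 4, 8),
           contrast = runif(1, 0.1, 0.3))
  }
  scene
}

# Ten well-spread landmarks on vessel centerlines visible in both FOVs.
sample_landmarks <- function(scene, true_tf, center, R, n_landmarks = 10L) {
  pts <- do.call(rbind, lapply(scene$vessels, function(v)
    resample_polyline(v$path, 4)))
  if (is.null(pts) || nrow(pts) == 0L) stop("scene has no vessels to land on")
  in_fixed <- sqrt((pts[, 1] - center[1])^2 +
                   (pts[, 2] - center[2])^2) < R - 25
  pts <- pts[in_fixed, , drop = FALSE]
  back <- invert_points(true_tf, pts)
  in_mov <- sqrt((back[, 1] - center[1])^2 +
                 (back[, 2] - center[2])^2) < R - 25
  pts <- pts[in_mov, , drop = FALSE]
  back <- back[in_mov, , drop = FALSE]
  if (nrow(pts) < n_landmarks) stop("too few visible vessel points for landmarks")
  ord <- sample.int(nrow(pts))
  min_dist <- scene$size / 12
  repeat {
    sel <- integer(0)
    for (i in ord) {
      if (length(sel) == 0L ||
          min(sqrt((pts[sel, 1] - pts[i, 1])^2 +
                   (pts[sel, 2] - pts[i, 2])^2)) >= min_dist) {
        sel <- c(sel, i)
        if (length(sel) == n_landmarks) break
      }
    }
    if (length(sel) == n_landmarks || min_dist < 2) break
    min_dist <- min_dist / 1.5
  }
  sel <- sel[seq_len(min(n_landmarks, length(sel)))]
  data.frame(x_fixed = pts[sel, 1], y_fixed = pts[sel, 2],
             x_moving = back[sel, 1], y_moving = back[sel, 2])
}

#' Export a phantom pair as a plain-file fixture
#'
#' Writes `fixed.png`, `moving.png`, `landmarks.csv` and `truth.json`
#' (model, parameters, overlap, category, seed). `native_scale` additionally
#' writes `landmarks_native.csv` with coordinates multiplied to a native
#' resolution, exercising the working-vs-native evaluation path.
#'
#' @param pair a `phantom_pair`.
#' @param dir output directory (created).
#' @param native_scale native/working resolution ratio (default 1).
#' @return `dir`, invisibly.
#' @export
export_fixture <- function(pair, dir, native_scale = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gray_png(pair$fixed, file.path(dir, "fixed.png"))
  write_gray_png(pair$moving, file.path(dir, "moving.png"))
  lm <- pair$landmarks
  con <- file(file.path(dir, "landmarks.csv"), "w")
  writeLines("# x_fixed,y_fixed,x_moving,y_moving; 1-based pixel centres", con)
  writeLines("x_fixed,y_fixed,x_moving,y_moving", con)
  writeLines(sprintf("%.10f,%.10f,%.10f,%.10f", lm$x_fixed, lm$y_fixed,
                     lm$x_moving, lm$y_moving), con)
  close(con)
  if (native_scale != 1) {
    lmn <- lm * native_scale
    write_landmarks(lmn, file.path(dir, "landmarks_native.csv"))
  }
  jsonlite::write_json(
    list(model = pair$true_transform$model,
         params = pair$true_transform$params,
         overlap = pair$overlap_fraction,
         overlap_target = pair$overlap_target,
         category = pair$category, seed = pair$seed,
         native_scale = native_scale),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname export_fixture
#' @export
import_fixture <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(fixed = read_fundus_image(file.path(dir, "fixed.png")),
       moving = read_fundus_image(file.path(dir, "moving.png")),
       landmarks = read_landmarks(file.path(dir, "landmarks.csv")),
       true_transform = make_transform(truth$model, truth$params),
       overlap_fraction = truth$overlap, category = truth$category,
       seed = truth$seed, native_scale = truth$native_scale)
}
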