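# Independent brute-force oracle for the cyclic outer-ring pattern test:
# a label string passes iff some rotation starts at the beginning of a dark
# arc and the linearized string matches alternating d/l arcs of length 2-8
# separated by at most two s, with at least two arcs of each label.
oracle_outer_ring <- function(labels) {
  n <- length(labels)
  pat <- "^(d{2,8}s{0,2}l{2,8}s{0,2}){2,}$"
  for (r in seq_len(n) - 1L) {
    rot <- paste(labels[((seq_len(n) - 1L + r) %% n) + 1L], collapse = "")
    if (grepl(pat, rot)) return(TRUE)
  }
  FALSE
}

# enumerate all length-n label strings over {d, s, l}
all_label_strings <- function(n) {
  g <- do.call(expand.grid, rep(list(c("d", "s", "l")), n))
  as.matrix(g)
}

# curved-vessel test card: gently bending Gaussian-valley vessels of the
# given contrasts crossing a brighter disc, plus fixed tiny noise. The
# curvature sweeps through orientations so the discrete ring geometry meets
# the vessel at many angles.
vessel_card <- function(size = 201L, contrasts = 0.4, width = 3,
                        noise_seed = 99L) {
  xx <- matrix(seq_len(size), size, size, byrow = TRUE)
  yy <- matrix(seq_len(size), size, size)
  c0 <- (size + 1) / 2
  img <- matrix(0.35, size, size)
  img <- img + 0.35 * exp(-(((xx - c0)^2 + (yy - c0)^2) / (0.45 * size)^2)^2)
  sigma_v <- max(width / 2.355, 0.6)
  masks <- list()
  offsets <- seq(-0.25, 0.25, length.out = length(contrasts)) * size
  for (i in seq_along(contrasts)) {
    tx <- seq(5, size - 5, by = 0.5)
    ty <- c0 + offsets[i] + 0.12 * size * sin(2 * pi * tx / (0.9 * size))
    depth <- matrix(0, size, size)
    mask <- matrix(FALSE, size, size)
    rad <- ceiling(3 * sigma_v)
    for (s in seq_along(tx)) {
      cs <- max(1L, floor(tx[s]) - rad):min(size, ceiling(tx[s]) + rad)
      rs <- max(1L, floor(ty[s]) - rad):min(size, ceiling(ty[s]) + rad)
      dd <- outer((rs - ty[s])^2, (cs - tx[s])^2, "+")
      depth[rs, cs] <- pmax(depth[rs, cs], exp(-dd / (2 * sigma_v^2)))
      mask[round(ty[s]), round(tx[s])] <- TRUE
    }
    img <- img - contrasts[i] * depth
    masks[[i]] <- mask
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(noise_seed)
  img <- img + matrix(rnorm(size^2, 0, 0.002), size, size)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255
  list(img = as_gray_image(img), masks = masks)
}

# count detections within dist_px of a centerline mask
count_on_mask <- function(points, mask, dist_px = 2) {
  if (nrow(points) == 0L) return(0L)
  idx <- which(mask, arr.ind = TRUE)
  sum(vapply(seq_len(nrow(points)), function(i) {
    min(sqrt((idx[, "col"] - points$x[i])^2 +
             (idx[, "row"] - points$y[i])^2)) <= dist_px
  }, logical(1)))
}
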