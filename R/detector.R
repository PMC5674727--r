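#' Ring geometry around a candidate point
#'
#' The inner ring is the 8-neighborhood of the candidate (3x3 minus centre);
#' the outer ring is the 16-pixel digital (Bresenham) circle of radius 3.
#' Both are returned in fixed clockwise order starting at 12 o'clock
#' (y increases downwards), so rotating the image by 90 degrees permutes the
#' outer ring by 4 positions.
#'
#' @return integer matrix with columns `dx`, `dy`.
#' @export
inner_ring_offsets <- function() {
  cbind(dx = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L),
        dy = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L))
}

#' @rdname inner_ring_offsets
#' @export
outer_ring_offsets <- function() {
  cbind(dx = c(0L, 1L, 2L, 3L, 3L, 3L, 2L, 1L,
               0L, -1L, -2L, -3L, -3L, -3L, -2L, -1L),
        dy = c(-3L, -3L, -2L, -1L, 0L, 1L, 2L, 3L,
               3L, 3L, 2L, 1L, 0L, -1L, -2L, -3L))
}

#' Candidate lattice of an octave
#'
#' Candidates are all pixels with `x` in `[4, M - 3]` and `y` in `[4, N - 3]`
#' (1-based), the positions whose radius-3 outer ring fits inside the image.
#'
#' @param dog DoG image matrix of the octave (only its dimensions are used).
#' @return data.frame with integer columns `x`, `y` (possibly 0 rows).
#' @export
candidate_grid <- function(dog) {
  m <- ncol(dog); n <- nrow(dog)
  if (m < 7L || n < 7L) {
    message(sprintf("octave %dx%d too small for candidates", m, n))
    return(data.frame(x = integer(0), y = integer(0)))
  }
  xs <- seq.int(4L, m - 3L)
  ys <- seq.int(4L, n - 3L)
  expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
}

#' Sample the inner and outer rings at a candidate point
#'
#' @param dog DoG image matrix.
#' @param x,y 1-based candidate position, inside the [candidate_grid()]
#'   bounds.
#' @return list with `inner` (8 values) and `outer` (16 values), clockwise
#'   from 12 o'clock.
#' @export
sample_rings <- function(dog, x, y) {
  m <- ncol(dog); n <- nrow(dog)
  if (x < 4L || x > m - 3L || y < 4L || y > n - 3L) {
    stop(sprintf("candidate (%d, %d) violates the ring bounds for %dx%d",
                 x, y, m, n))
  }
  io <- inner_ring_offsets()
  oo <- outer_ring_offsets()
  list(inner = dog[cbind(y + io[, "dy"], x + io[, "dx"])],
       outer = dog[cbind(y + oo[, "dy"], x + oo[, "dx"])])
}

#' Inner-ring pattern test
#'
#' Tests the 8 inner-ring intensities for the two saddle shapes: `+` compares
#' the axial pair (top, bottom) against (left, right), `x` compares the two
#' diagonal pairs. A shape passes when the minimum of one pair strictly
#' exceeds the maximum of the orthogonal pair, in either polarity. The
#' central intensity `beta` is the median of the 4 pixels of the passing
#' shape, or of all 8 when both shapes pass.
#'
#' @param inner 8 intensities in ring order (clockwise from 12 o'clock).
#' @return list with `passed` (logical), `shapes` (character subset of
#'   `c("+", "x")`), `beta` (numeric, `NA` when failed).
#' @export
inner_ring_test <- function(inner) {
  stopifnot(length(inner) == 8L, all(is.finite(inner)))
  top <- inner[1]; right <- inner[3]; bottom <- inner[5]; left <- inner[7]
  ur <- inner[2]; dr <- inner[4]; dl <- inner[6]; ul <- inner[8]
  pair_test <- function(a1, a2, b1, b2) {
    min(a1, a2) > max(b1, b2) || max(a1, a2) < min(b1, b2)
  }
  plus <- pair_test(top, bottom, left, right)
  cross <- pair_test(ur, dl, dr, ul)
  shapes <- c("+", "x")[c(plus, cross)]
  if (!plus && !cross) {
    return(list(passed = FALSE, shapes = character(0), beta = NA_real_))
  }
  vals <- c(if (plus) c(top, bottom, left, right),
            if (cross) c(ur, dl, dr, ul))
  list(passed = TRUE, shapes = shapes, beta = median(vals))
}

#' Three-way labeling of the outer ring
#'
#' Each outer-ring intensity is labeled relative to the central intensity
#' `beta` with tolerance `epsilon`: `d` (darker) when `I < beta - epsilon`,
#' `s` (similar) when `beta - epsilon <= I <= beta + epsilon` (boundaries
#' inclusive), `l` (lighter) when `I > beta + epsilon`.
#'
#' @param outer intensities on the outer ring.
#' @param beta central intensity reference.
#' @param epsilon non-negative tolerance (default 0.0010 on the
#'   `[0, 1]`-normalized absolute DoG image).
#' @return character vector over `c("d", "s", "l")` of the same length.
#' @export
label_outer <- function(outer, beta, epsilon = 0.0010) {
  stopifnot(epsilon >= 0)
  ifelse(outer < beta - epsilon, "d",
         ifelse(outer > beta + epsilon, "l", "s"))
}

# Cyclic run-length encoding: runs of equal labels with first/last merged
# when they share a label. Returns data.frame(label, length).
cyclic_rle <- function(labels) {
  r <- rle(labels)
  if (length(r$values) > 1L && r$values[1] == r$values[length(r$values)]) {
    r$lengths[1] <- r$lengths[1] + r$lengths[length(r$lengths)]
    r$values <- r$values[-length(r$values)]
    r$lengths <- r$lengths[-length(r$lengths)]
  }
  data.frame(label = r$values, length = r$lengths,
             stringsAsFactors = FALSE)
}

#' Outer-ring saddle pattern test
#'
#' The cyclic label string passes when: every maximal run of `s` is at most
#' 2 long; every arc (maximal run) of `d` or `l` has length between 2 and 8;
#' after dropping the `s` runs, consecutive arcs strictly alternate between
#' `d` and `l`; and there are at least two arcs of each label (a saddle has
#' two dark and two bright sectors).
#'
#' @param labels cyclic character vector over `c("d", "s", "l")` (length 16
#'   in the detector; any length >= 4 is accepted for analysis).
#' @return logical.
#' @export
outer_ring_test <- function(labels) {
  stopifnot(all(labels %in% c("d", "s", "l")))
  if (all(labels == labels[1])) return(FALSE)  # includes all-s
  runs <- cyclic_rle(labels)
  if (any(runs$label == "s" & runs$length > 2L)) return(FALSE)
  arcs <- runs[runs$label != "s", , drop = FALSE]
  if (nrow(arcs) < 4L) return(FALSE)
  if (any(arcs$length < 2L | arcs$length > 8L)) return(FALSE)
  lab <- arcs$label
  nxt <- c(lab[-1], lab[1])
  if (any(lab == nxt)) return(FALSE)  # must alternate cyclically
  sum(lab == "d") >= 2L && sum(lab == "l") >= 2L
}

#' Response strength of a passing candidate
#'
#' Contrast of the saddle pattern about `beta`: the mean deficit of the dark
#' pixels plus the mean excess of the light pixels. Monotone in contrast,
#' which is what non-maxima suppression needs.
#'
#' @param outer outer-ring intensities.
#' @param labels labels from [label_outer()].
#' @param beta central intensity.
#' @return non-negative numeric; 0 when either label class is absent.
#' @export
response_strength <- function(outer, labels, beta) {
  d <- labels == "d"; l <- labels == "l"
  if (!any(d) || !any(l)) return(0)
  mean(beta - outer[d]) + mean(outer[l] - beta)
}

#' Non-maxima suppression over a 3x3 neighborhood
#'
#' Applied only to octave 0 (features in higher octaves are already coarse).
#' A point survives when its response is at least that of every other
#' passing point in its 3x3 neighborhood; exact ties are broken by keeping
#' the lexicographically smallest `(y, x)`.
#'
#' @param points data.frame with columns `x`, `y`, `response` (one octave).
#' @return the surviving subset, original order preserved.
#' @export
nonmax_suppress <- function(points) {
  n <- nrow(points)
  if (n <= 1L) return(points)
  # dense response field over the occupied bounding box (one point per cell)
  y0 <- min(points$y) - 1L; x0 <- min(points$x) - 1L
  nr <- max(points$y) - y0 + 2L; nc <- max(points$x) - x0 + 2L
  r <- matrix(-Inf, nr, nc)
  r[cbind(points$y - y0, points$x - x0)] <- points$response
  killed <- matrix(FALSE, nr, nc)
  shift <- function(m, dy, dx, fill = -Inf) {
    out <- matrix(fill, nr, nc)
    ys <- max(1L, 1L + dy):min(nr, nr + dy)
    xs <- max(1L, 1L + dx):min(nc, nc + dx)
    out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
    out
  }
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    rn <- shift(r, dy, dx)
    # a neighbor earlier in (y, x) order wins exact response ties
    lex_prior <- dy > 0L || (dy == 0L && dx > 0L)
    killed <- killed | (if (lex_prior) rn >= r else rn > r)
  }
  keep <- !killed[cbind(points$y - y0, points$x - x0)]
  points[keep, , drop = FALSE]
}

#' Subpixel position refinement
#'
#' Fits a 1D quadratic independently along each axis through the centre row
#' and column of the 3x3 `|DoG|` neighborhood and moves the point to the
#' parabola vertex, clamped to half a pixel. Flat or non-concave profiles
#' leave the integer position unchanged.
#'
#' @param dog DoG image matrix of the octave.
#' @param x,y integer candidate position with a full 3x3 neighborhood.
#' @return numeric `c(x, y)` refined position.
#' @export
subpixel_refine <- function(dog, x, y) {
  vertex <- function(a, b, c) {
    den <- a - 2 * b + c
    if (abs(den) < 1e-12) return(0)
    off <- (a - c) / (2 * den)
    min(max(off, -0.5), 0.5)
  }
  dx <- vertex(dog[y, x - 1L], dog[y, x], dog[y, x + 1L])
  dy <- vertex(dog[y - 1L, x], dog[y, x], dog[y + 1L, x])
  c(x + dx, y + dy)
}

# Vectorized subpixel_refine over many points of one octave.
subpixel_refine_bulk <- function(dog, x, y) {
  axis_offset <- function(a, b, c) {
    den <- a - 2 * b + c
    off <- ifelse(abs(den) < 1e-12, 0, (a - c) / (2 * den))
    pmin(pmax(off, -0.5), 0.5)
  }
  dx <- axis_offset(dog[cbind(y, x - 1L)], dog[cbind(y, x)],
                    dog[cbind(y, x + 1L)])
  dy <- axis_offset(dog[cbind(y - 1L, x)], dog[cbind(y, x)],
                    dog[cbind(y + 1L, x)])
  cbind(x + dx, y + dy)
}

#' Lift octave coordinates to input-image coordinates
#'
#' Positions in octave `o` are scaled by `2^o` about the pixel-centre
#' origin: `x_in = (x_oct - 0.5) * 2^o + 0.5`, which keeps detections
#' covariant with image rotations. When the octave was produced by
#' ceiling-halving of odd dimensions, supply `scale` as the exact ratio
#' `input_dim / octave_dim`. For evaluation at a native resolution other
#' than the working one, multiply further by `original_dim / working_dim`.
#'
#' @param x,y coordinates in octave space.
#' @param octave 0-based octave index.
#' @param scale optional exact `c(scale_x, scale_y)` overriding `2^octave`.
#' @return numeric `cbind(x, y)` in input-image coordinates.
#' @export
to_input_coords <- function(x, y, octave, scale = NULL) {
  if (is.null(scale)) scale <- rep(2^octave, 2L)
  cbind(x = (x - 0.5) * scale[1] + 0.5, y = (y - 0.5) * scale[2] + 0.5)
}

#' Detect D-Saddle feature points
#'
#' Runs the full stage-1 pipeline: build the multiresolution DoG pyramid,
#' screen every candidate with the inner and outer ring pattern tests on the
#' normalized absolute DoG of each octave, non-maxima suppress octave 0,
#' refine to subpixel precision and lift all positions to input-image
#' coordinates. Deterministic for fixed input and configuration.
#'
#' @param img gray image (matrix in `[0, 1]`) or a prebuilt `dog_pyramid`.
#' @param sigma0,k,n_octaves pyramid parameters, see [build_pyramid()].
#' @param epsilon outer-ring label tolerance on the normalized `|DoG|`
#'   (default 0.0010).
#' @return data.frame with columns `x`, `y` (subpixel, input coordinates),
#'   `octave`, `response`, `beta`, ordered by octave then `y`, `x`. The
#'   attribute `candidate_stats` holds per-octave counts of candidates and
#'   inner-ring survivors.
#' @export
detect_dsaddle <- function(img, sigma0 = 1.0, k = 1.6, n_octaves = 4L,
                           epsilon = 0.0010) {
  pyr <- if (inherits(img, "dog_pyramid")) img else {
    build_pyramid(img, sigma0 = sigma0, k = k, n_octaves = n_octaves)
  }
  out <- vector("list", length(pyr$octaves))
  stats <- data.frame(octave = integer(0), n_candidates = integer(0),
                      n_inner_pass = integer(0), n_pass = integer(0))
  for (i in seq_along(pyr$octaves)) {
    oc <- pyr$octaves[[i]]
    res <- ring_test_bulk(oc$dog, epsilon)
    stats <- rbind(stats, data.frame(octave = oc$octave,
                                     n_candidates = res$n_candidates,
                                     n_inner_pass = res$n_inner_pass,
                                     n_pass = nrow(res$points)))
    pts <- res$points
    if (nrow(pts) == 0L) next
    if (oc$octave == 0L) pts <- nonmax_suppress(pts)
    if (nrow(pts) == 0L) next
    ref <- subpixel_refine_bulk(oc$dog, pts$x, pts$y)
    # exact per-axis scale: input_dim / octave_dim (telescoped halvings)
    sc <- c(pyr$input_dim[2] / ncol(oc$dog), pyr$input_dim[1] / nrow(oc$dog))
    lifted <- to_input_coords(ref[, 1], ref[, 2], oc$octave, scale = sc)
    out[[i]] <- data.frame(x = lifted[, "x"], y = lifted[, "y"],
                           octave = oc$octave, response = pts$response,
                           beta = pts$beta)
  }
  pts <- do.call(rbind, out)
  if (is.null(pts) || nrow(pts) == 0L) {
    warning("no feature points detected")
    pts <- data.frame(x = numeric(0), y = numeric(0), octave = integer(0),
                      response = numeric(0), beta = numeric(0))
  }
  rownames(pts) <- NULL
  attr(pts, "candidate_stats") <- stats
  pts
}

# Bulk ring tests over every candidate of one octave (compiled core).
# Returns list(points = data.frame(x, y, response, beta),
#              n_candidates, n_inner_pass).
ring_test_bulk <- function(dog, epsilon) {
  res <- ring_test_bulk_cpp(dog, epsilon)
  list(points = data.frame(x = res$x, y = res$y, response = res$response,
                           beta = res$beta),
       n_candidates = res$n_candidates, n_inner_pass = res$n_inner_pass)
}

#' Write detected points to CSV
#'
#' @param points data.frame from [detect_dsaddle()].
#' @param path output path; a header comment states the 1-based pixel-centre
#'   coordinate convention.
#' @export
write_points_csv <- function(points, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# x,y in input-image pixels, 1-based pixel centres", con)
  write.csv(points, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(path) {
  read.csv(path, comment.char = "#")
}
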