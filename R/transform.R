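#' Geometric transformations between image pairs
#'
#' Three model classes map moving-image coordinates to fixed-image
#' coordinates:
#' * `similarity` — 4 parameters `(a, b, tx, ty)`:
#'   `x' = a x - b y + tx`, `y' = b x + a y + ty` (rotation + scale +
#'   translation);
#' * `affine` — 6 parameters (full 2x3 linear map);
#' * `polynomial2` — 12 parameters, the full second-order basis
#'   `{1, x, y, x^2, xy, y^2}` per output coordinate.
#'
#' @param src,dst n x 2 matrices (or data.frames) of corresponding points:
#'   `src` in the moving image, `dst` in the fixed image.
#' @param model one of `"similarity"`, `"affine"`, `"polynomial2"`.
#' @return object of class `dsaddle_transform`: list with `model` and
#'   `params`.
#' @export
fit_transform <- function(src, dst, model = c("similarity", "affine",
                                              "polynomial2")) {
  model <- match.arg(model)
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2L, ncol(dst) == 2L, nrow(src) == nrow(dst))
  n <- nrow(src)
  need <- c(similarity = 2L, affine = 3L, polynomial2 = 6L)[[model]]
  if (n < need) {
    stop(sprintf("%s needs at least %d point pairs, got %d", model, need, n))
  }
  x <- src[, 1]; y <- src[, 2]
  if (model == "similarity") {
    # joint system in (a, b, tx, ty)
    A <- rbind(cbind(x, -y, 1, 0), cbind(y, x, 0, 1))
    b <- c(dst[, 1], dst[, 2])
    qa <- qr(A)
    if (qa$rank < 4L) stop("degenerate geometry: coincident points")
    params <- qr.coef(qa, b)
  } else {
    basis <- if (model == "affine") cbind(x, y, 1) else
      cbind(1, x, y, x^2, x * y, y^2)
    qa <- qr(basis)
    if (qa$rank < ncol(basis)) {
      stop(sprintf("degenerate geometry: %s for a %s fit",
                   if (model == "affine") "collinear points"
                   else "rank-deficient quadratic basis", model))
    }
    params <- c(qr.coef(qa, dst[, 1]), qr.coef(qa, dst[, 2]))
  }
  params <- unname(params)
  if (any(!is.finite(params))) stop("transformation fit produced non-finite parameters")
  structure(list(model = model, params = params),
            class = "dsaddle_transform")
}

#' Build a transformation from explicit parameters
#'
#' @param model model name.
#' @param params parameter vector (4, 6 or 12 values).
#' @export
make_transform <- function(model = c("similarity", "affine", "polynomial2"),
                           params) {
  model <- match.arg(model)
  len <- c(similarity = 4L, affine = 6L, polynomial2 = 12L)[[model]]
  stopifnot(length(params) == len, all(is.finite(params)))
  structure(list(model = model, params = as.numeric(params)),
            class = "dsaddle_transform")
}

#' Identity transformation
#' @param model model class to express the identity in.
#' @export
identity_transform <- function(model = "similarity") {
  switch(model,
    similarity = make_transform("similarity", c(1, 0, 0, 0)),
    affine = make_transform("affine", c(1, 0, 0, 0, 1, 0)),
    polynomial2 = make_transform("polynomial2",
      c(0, 1, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0)))
}

#' Apply a transformation to points
#'
#' @param tf a `dsaddle_transform` (moving to fixed).
#' @param xy n x 2 matrix or data.frame of points.
#' @return n x 2 matrix of mapped points.
#' @export
transform_points <- function(tf, xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop("'xy' must have two columns")
  x <- xy[, 1]; y <- xy[, 2]
  p <- tf$params
  out <- switch(tf$model,
    similarity = cbind(p[1] * x - p[2] * y + p[3],
                       p[2] * x + p[1] * y + p[4]),
    affine = cbind(p[1] * x + p[2] * y + p[3],
                   p[4] * x + p[5] * y + p[6]),
    polynomial2 = {
      B <- cbind(1, x, y, x^2, x * y, y^2)
      cbind(B %*% p[1:6], B %*% p[7:12])
    },
    stop("unknown model"))
  colnames(out) <- c("x", "y")
  out
}

#' Invert a similarity or affine transformation
#'
#' Second-order polynomial maps have no closed-form inverse; use
#' [approximate_inverse()] for those.
#'
#' @param tf a `dsaddle_transform`.
#' @export
invert_transform <- function(tf) {
  p <- tf$params
  if (tf$model == "similarity") {
    det <- p[1]^2 + p[2]^2
    if (det < 1e-15) stop("non-invertible similarity")
    a <- p[1] / det; b <- -p[2] / det
    tx <- -(a * p[3] - b * p[4]); ty <- -(b * p[3] + a * p[4])
    make_transform("similarity", c(a, b, tx, ty))
  } else if (tf$model == "affine") {
    A <- matrix(p[c(1, 4, 2, 5)], 2, 2)
    Ai <- solve(A)
    t2 <- -Ai %*% p[c(3, 6)]
    make_transform("affine", c(Ai[1, 1], Ai[1, 2], t2[1],
                               Ai[2, 1], Ai[2, 2], t2[2]))
  } else {
    stop("polynomial2 has no exact inverse; use approximate_inverse()")
  }
}

#' Approximate inverse of a transformation on a domain
#'
#' Fits a second-order polynomial from fixed to moving coordinates over a
#' grid spanning the stated domain; exact (up to numerics) for similarity
#' and affine inputs, a good local approximation for mild quadratic warps.
#'
#' @param tf a `dsaddle_transform` (moving to fixed).
#' @param domain `c(xmin, xmax, ymin, ymax)` in moving coordinates.
#' @param n_grid grid side (default 15).
#' @export
approximate_inverse <- function(tf, domain, n_grid = 15L) {
  gx <- seq(domain[1], domain[2], length.out = n_grid)
  gy <- seq(domain[3], domain[4], length.out = n_grid)
  src <- cbind(rep(gx, times = n_grid), rep(gy, each = n_grid))
  dst <- transform_points(tf, src)
  fit_transform(dst, src, "polynomial2")
}

#' Select the transformation model from the inlier count
#'
#' Few inliers only support a simple model: up to 8 inliers select
#' similarity, 9 to 30 affine, more than 30 the second-order polynomial.
#' (At the boundary values the simpler model is preferred.)
#'
#' @param n_inliers non-negative integer.
#' @return model name.
#' @export
select_model <- function(n_inliers) {
  stopifnot(n_inliers >= 0)
  if (n_inliers <= 8L) "similarity"
  else if (n_inliers <= 30L) "affine"
  else "polynomial2"
}

#' Warp the moving image into the fixed frame
#'
#' Inverse-mapped bilinear resampling: each output (fixed-frame) pixel is
#' sampled from the moving image at the inverse-transformed position.
#' Pixels falling outside the moving image are filled with 0 and flagged in
#' the `valid_mask` attribute.
#'
#' @param moving gray image matrix.
#' @param tf `dsaddle_transform` mapping moving to fixed coordinates.
#' @param out_dim output `c(nrow, ncol)`; defaults to `dim(moving)`.
#' @return warped matrix with attribute `valid_mask` (logical).
#' @export
warp_image <- function(moving, tf, out_dim = dim(moving)) {
  inv <- if (tf$model == "polynomial2") {
    approximate_inverse(tf, c(1, ncol(moving), 1, nrow(moving)))
  } else {
    invert_transform(tf)
  }
  n1 <- out_dim[1]; m1 <- out_dim[2]
  xx <- matrix(rep(seq_len(m1), each = n1), n1, m1)
  yy <- matrix(rep(seq_len(n1), times = m1), n1, m1)
  src <- transform_points(inv, cbind(as.vector(xx), as.vector(yy)))
  sx <- matrix(src[, 1], n1, m1); sy <- matrix(src[, 2], n1, m1)
  tol <- 1e-6   # keep boundary pixels that rounding pushes just outside
  valid <- sx >= 1 - tol & sx <= ncol(moving) + tol &
           sy >= 1 - tol & sy <= nrow(moving) + tol
  out <- interp_bilinear(unclass(moving), sx, sy)
  out[!valid] <- 0
  attr(out, "valid_mask") <- valid
  out
}

#' @export
print.dsaddle_transform <- function(x, ...) {
  cat(sprintf("%s transformation (moving -> fixed)\n", x$model))
  cat("params:", format(x$params, digits = 6), "\n")
  invisible(x)
}
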