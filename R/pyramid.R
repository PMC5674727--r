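#' Sampled 2D Gaussian kernel
#'
#' The isotropic Gaussian \eqn{G(x, y, \sigma) = \frac{1}{2\pi\sigma^2}
#' e^{-(x^2+y^2)/2\sigma^2}} sampled on the integer grid, truncated at radius
#' `ceiling(trunc_factor * sigma)` and renormalized to sum to one.
#'
#' @param sigma Gaussian width, > 0.
#' @param trunc_factor truncation radius in units of `sigma` (default 4, a
#'   standard negligible-tail cutoff).
#' @param normalize renormalize the discrete kernel to unit sum (default).
#' @return square numeric matrix of odd side `2*ceiling(trunc_factor*sigma)+1`.
#' @export
gaussian_kernel <- function(sigma, trunc_factor = 4, normalize = TRUE) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("'sigma' must be a single positive number")
  }
  r <- ceiling(trunc_factor * sigma)
  x <- seq(-r, r)
  g1 <- exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  k <- outer(g1, g1)
  if (normalize) k <- k / sum(k)
  k
}

# 1D Gaussian taps for separable filtering (unnormalized tails renormalized).
gaussian_taps <- function(sigma, trunc_factor = 4) {
  r <- ceiling(trunc_factor * sigma)
  x <- seq(-r, r)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# Separable Gaussian blur with reflect padding. Reflection avoids spurious
# DoG responses at the frame boundary that would mimic the illumination
# artifact the detector must tolerate.
gaussian_blur <- function(img, sigma, trunc_factor = 4) {
  w <- gaussian_taps(sigma, trunc_factor)
  r <- (length(w) - 1L) %/% 2L
  x <- unclass(img)
  n <- nrow(x); m <- ncol(x)
  # rows (vertical pass)
  out <- matrix(0, n, m)
  for (j in seq_along(w)) {
    off <- j - r - 1L
    out <- out + w[j] * x[reflect_index(seq_len(n) + off, n), , drop = FALSE]
  }
  x <- out
  out <- matrix(0, n, m)
  for (j in seq_along(w)) {
    off <- j - r - 1L
    out <- out + w[j] * x[, reflect_index(seq_len(m) + off, m), drop = FALSE]
  }
  out
}

#' Difference-of-Gaussian image
#'
#' `D(x, y, sigma0) = G(k*sigma0) * I - G(sigma0) * I`: the band-pass
#' residual between two Gaussian blurs, approximating the Laplacian of
#' Gaussian. Defaults `sigma0 = 1.0`, `k = 1.6` give a good Laplacian
#' approximation while emphasizing vessel-scale structure.
#'
#' @param img gray image matrix.
#' @param sigma0 base Gaussian width (> 0).
#' @param k ratio of the two Gaussian widths (> 1).
#' @param trunc_factor kernel truncation, see [gaussian_kernel()].
#' @return numeric matrix of the same dimensions (signed DoG values).
#' @export
dog_image <- function(img, sigma0 = 1.0, k = 1.6, trunc_factor = 4) {
  if (sigma0 <= 0) stop("'sigma0' must be positive")
  if (k <= 1) stop("'k' must exceed 1")
  gaussian_blur(img, k * sigma0, trunc_factor) -
    gaussian_blur(img, sigma0, trunc_factor)
}

#' Downsample an image by half
#'
#' Bilinear resize to `ceiling(dim / 2)`; the ceiling convention keeps the
#' last row/column of odd-sized images (583 is odd at the default working
#' resolution).
#'
#' @param img gray image matrix with both dimensions at least 2.
#' @return matrix of dimensions `ceiling(dim(img) / 2)`.
#' @export
downsample_half <- function(img) {
  if (nrow(img) < 2 || ncol(img) < 2) {
    stop("image too small to downsample: pyramid truncated")
  }
  bilinear_resize(unclass(img), ceiling(dim(img) / 2))
}

# |DoG| min-max normalized to [0, 1]; a constant octave maps to all zeros so
# the epsilon band of the outer-ring labels stays comparable across octaves.
normalize_abs_dog <- function(d) {
  a <- abs(d)
  rng <- range(a)
  # ranges at numerical-noise level (constant input) must not be stretched
  if (rng[2] - rng[1] <= 1e-9) {
    return(matrix(0, nrow(a), ncol(a)))
  }
  (a - rng[1]) / (rng[2] - rng[1])
}

#' Build the multiresolution difference-of-Gaussian pyramid
#'
#' Each octave halves the resolution of the previous one (bilinear,
#' ceiling convention) and is filtered afresh with `sigma0` and `k * sigma0`;
#' the stored detection surface is the absolute DoG min-max normalized to
#' `[0, 1]` per octave. Four octaves cost at most 4/3 of the input pixel
#' count (geometric series 1 + 1/4 + 1/16 + ...).
#'
#' @param img gray image.
#' @param sigma0 base Gaussian width (default 1.0).
#' @param k Gaussian width ratio (default 1.6).
#' @param n_octaves number of octaves (default 4).
#' @param trunc_factor kernel truncation, see [gaussian_kernel()].
#' @return object of class `dog_pyramid`: list with `octaves` (each a list
#'   `dog` (normalized |DoG|), `raw` (signed DoG), `octave` (0-based index),
#'   `scale` (2^octave)), plus `sigma0`, `k`, `input_dim`.
#' @export
build_pyramid <- function(img, sigma0 = 1.0, k = 1.6, n_octaves = 4L,
                          trunc_factor = 4) {
  x <- unclass(img)
  octaves <- vector("list", n_octaves)
  built <- 0L
  for (o in seq_len(n_octaves) - 1L) {
    if (min(dim(x)) < 8L && o > 0L) break
    raw <- dog_image(x, sigma0, k, trunc_factor)
    octaves[[o + 1L]] <- list(dog = normalize_abs_dog(raw), raw = raw,
                              octave = o, scale = 2L^o)
    built <- o + 1L
    if (o < n_octaves - 1L) {
      if (min(dim(x)) < 2L) break
      x <- pmin(pmax(downsample_half(x), 0), 1)
    }
  }
  if (built < n_octaves) {
    warning(sprintf("image too small for %d octaves; built %d",
                    n_octaves, built))
  }
  structure(list(octaves = octaves[seq_len(built)], sigma0 = sigma0, k = k,
                 n_octaves = built, input_dim = dim(img)),
            class = "dog_pyramid")
}

#' @export
print.dog_pyramid <- function(x, ...) {
  cat(sprintf("DoG pyramid: %d octave(s), sigma0 = %g, k = %g\n",
              x$n_octaves, x$sigma0, x$k))
  for (oc in x$octaves) {
    cat(sprintf("  octave %d: %d x %d\n", oc$octave,
                ncol(oc$dog), nrow(oc$dog)))
  }
  invisible(x)
}

#' Dump pyramid octaves as PNG files for inspection
#'
#' @param pyr a `dog_pyramid`.
#' @param dir output directory (created if missing).
#' @return paths written, invisibly.
#' @export
dump_pyramid <- function(pyr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (oc in pyr$octaves) {
    p <- file.path(dir, sprintf("octave_%d.png", oc$octave))
    write_gray_png(oc$dog, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
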