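#' Grayscale image container
#'
#' A gray image is a plain numeric matrix with values in `[0, 1]`, rows
#' indexed by `y` (height `N = nrow`) and columns by `x` (width `M = ncol`),
#' so `img[y, x]` reads the pixel at column `x`, row `y`. All detector maths
#' use 1-based pixel-centre coordinates.
#'
#' @param x numeric matrix, or a 3D array (height x width x channels) from
#'   which a single channel is taken (see `channel`).
#' @param channel for colour input: `"green"` (default; highest vessel
#'   contrast in fundus photography) or `"luminance"`.
#' @return a numeric matrix of class `gray_image` with values in `[0, 1]`.
#' @export
as_gray_image <- function(x, channel = c("green", "luminance")) {
  channel <- match.arg(channel)
  if (is.array(x) && length(dim(x)) == 3L) {
    x <- if (dim(x)[3] >= 3L && channel == "luminance") {
      0.2126 * x[, , 1] + 0.7152 * x[, , 2] + 0.0722 * x[, , 3]
    } else if (dim(x)[3] >= 2L) {
      x[, , 2]  # green channel
    } else {
      x[, , 1]
    }
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("a gray image must be a numeric matrix or a HxWxC array")
  }
  if (anyNA(x) || any(!is.finite(x))) stop("image contains non-finite values")
  if (min(x) < 0 || max(x) > 1) {
    stop("image intensities must lie in [0, 1]; rescale before use")
  }
  structure(x, class = c("gray_image", class(matrix())))
}

#' @rdname as_gray_image
#' @export
is_gray_image <- function(x) is.matrix(x) && is.numeric(x)

#' Read a fundus image from PNG or TIFF
#'
#' Colour images are reduced to the green channel, the standard choice for
#' vessel analysis in fundus photography.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param channel passed to [as_gray_image()].
#' @return a `gray_image` matrix.
#' @export
read_fundus_image <- function(path, channel = "green") {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: '", ext, "' (use PNG or TIFF)")
  )
  as_gray_image(x, channel = channel)
}

#' Write a gray image to PNG
#'
#' @param img gray image matrix.
#' @param path output path.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(pmin(pmax(unclass(img), 0), 1), target = path)
  invisible(path)
}

# Reflect (mirror) out-of-range 1-based indices into [1, n].
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  i <- (i - 1L) %% period
  i <- ifelse(i >= n, period - 1L - i, i)
  i + 1L
}

#' Bilinear resize
#'
#' Pixel-centre aligned bilinear interpolation, used for pyramid
#' downsampling and image warping.
#'
#' @param img numeric matrix.
#' @param new_dim integer `c(nrow, ncol)` of the output.
#' @return resized matrix.
#' @export
bilinear_resize <- function(img, new_dim) {
  n0 <- nrow(img); m0 <- ncol(img)
  n1 <- new_dim[1]; m1 <- new_dim[2]
  if (n1 < 1 || m1 < 1) stop("target dimensions must be positive")
  sy <- n0 / n1; sx <- m0 / m1
  # output pixel centre i maps to input coordinate (i - 0.5) * s + 0.5
  yy <- (seq_len(n1) - 0.5) * sy + 0.5
  xx <- (seq_len(m1) - 0.5) * sx + 0.5
  interp_bilinear(img, matrix(rep(xx, each = n1), n1, m1),
                  matrix(rep(yy, times = m1), n1, m1))
}

# Bilinear sample of img at arbitrary coordinate matrices (x = column,
# y = row, 1-based pixel centres). Out-of-range coordinates are clamped.
interp_bilinear <- function(img, x, y) {
  n <- nrow(img); m <- ncol(img)
  x <- pmin(pmax(x, 1), m)
  y <- pmin(pmax(y, 1), n)
  x0 <- pmin(floor(x), m - 1L); x0[m == 1L] <- 1
  y0 <- pmin(floor(y), n - 1L); y0[n == 1L] <- 1
  if (m == 1L) x0[] <- 1
  if (n == 1L) y0[] <- 1
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, m); y1 <- pmin(y0 + 1, n)
  idx <- function(r, c) img[cbind(as.vector(r), as.vector(c))]
  v <- (1 - fx) * (1 - fy) * idx(y0, x0) +
       fx * (1 - fy) * idx(y0, x1) +
       (1 - fx) * fy * idx(y1, x0) +
       fx * fy * idx(y1, x1)
  matrix(v, nrow(x), ncol(x))
}

#' Circular field-of-view mask
#'
#' @param n_row,n_col image dimensions.
#' @param radius circle radius in pixels (default: 0.48 of the smaller
#'   dimension, the usual fundus framing).
#' @param center `c(x, y)`; default image centre.
#' @return logical matrix, `TRUE` inside the field of view.
#' @export
disk_mask <- function(n_row, n_col, radius = 0.48 * min(n_row, n_col),
                      center = c((n_col + 1) / 2, (n_row + 1) / 2)) {
  xx <- matrix(seq_len(n_col), n_row, n_col, byrow = TRUE)
  yy <- matrix(seq_len(n_row), n_row, n_col)
  (xx - center[1])^2 + (yy - center[2])^2 <= radius^2
}

#' Otsu threshold
#'
#' Two-class intensity threshold maximizing between-class variance, used to
#' separate the dark frame from the illuminated field of view.
#'
#' @param x numeric vector or matrix of intensities in `[0, 1]`.
#' @param n_bins histogram resolution.
#' @return threshold value in `[0, 1]`.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  h <- tabulate(pmin(pmax(floor(as.vector(x) * n_bins) + 1L, 1L), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  centers[which.max(sigma_b)]
}

#' Estimate the circular field-of-view mask of a fundus image
#'
#' Thresholds the image (Otsu) to separate the dark frame from the
#' illuminated disc, then keeps pixels above threshold.
#'
#' @param img gray image.
#' @return logical matrix.
#' @export
estimate_fov_mask <- function(img) {
  unclass(img) > otsu_threshold(img)
}
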