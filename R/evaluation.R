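#' Target registration error
#'
#' Mean Euclidean distance, in pixels, between the fixed-image landmarks
#' and the transformed moving-image landmarks:
#' \eqn{\mathrm{TRE} = \frac{1}{n}\sum_i \lVert T(x_i^{mov}) - x_i^{fix}
#' \rVert}. Ten expert landmarks per pair is the usual ground-truth size.
#'
#' @param landmarks data.frame with columns `x_fixed`, `y_fixed`,
#'   `x_moving`, `y_moving`.
#' @param tf `dsaddle_transform` mapping moving to fixed coordinates, or
#'   `NULL` for the identity.
#' @return non-negative numeric (pixels).
#' @export
tre <- function(landmarks, tf = NULL) {
  if (is.null(landmarks) || nrow(landmarks) == 0L) {
    stop("landmark set is empty")
  }
  mov <- cbind(landmarks$x_moving, landmarks$y_moving)
  mapped <- if (is.null(tf)) mov else transform_points(tf, mov)
  mean(sqrt((mapped[, 1] - landmarks$x_fixed)^2 +
            (mapped[, 2] - landmarks$y_fixed)^2))
}

#' Classify a registration as successful for an application
#'
#' Super-resolution requires sub-pixel accuracy (TRE strictly below 1
#' pixel); mosaicking and longitudinal study accept TRE strictly below 5
#' pixels, the clinically acceptable range.
#'
#' @param tre_value non-negative TRE in pixels (native resolution).
#' @param category `"super_resolution"` (alias `"S"`), `"mosaicking"`
#'   (`"P"`) or `"longitudinal"` (`"A"`).
#' @return logical.
#' @export
classify_success <- function(tre_value,
                             category = c("super_resolution", "mosaicking",
                                          "longitudinal", "S", "P", "A")) {
  stopifnot(tre_value >= 0)
  category <- match.arg(category)
  category <- switch(category, S = "super_resolution", P = "mosaicking",
                     A = "longitudinal", category)
  threshold <- if (category == "super_resolution") 1 else 5
  tre_value < threshold
}

# SSIM map with an 11x11 Gaussian window (sigma 1.5), dynamic range 1.
ssim_map <- function(a, b, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  C1 <- K1^2; C2 <- K2^2
  blur <- function(z) gaussian_blur(z, sigma, trunc_factor = 5 / sigma)
  mu_a <- blur(a); mu_b <- blur(b)
  va <- blur(a * a) - mu_a^2
  vb <- blur(b * b) - mu_b^2
  cab <- blur(a * b) - mu_a * mu_b
  ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
}

#' Image-quality metrics for a fundus pair
#'
#' Computes, within the circular field-of-view region of interest:
#' * `mse` — mean squared intensity difference (0 iff identical);
#' * `ssim` — mean structural similarity (Gaussian-windowed, dynamic range
#'   1; equals 1 iff identical);
#' * `un` — peak deviation nonuniformity per image,
#'   `(I_max + I_min) / (I_max - I_min)` over the ROI, averaged over the
#'   two images. Larger values indicate a more uniform image; a perfectly
#'   uniform ROI has no finite UN and is reported as the sentinel `1e6`
#'   with a warning.
#'
#' @param a,b gray image matrices of equal dimensions.
#' @param roi_mask logical matrix marking the region of interest; when
#'   `NULL` it is estimated from `a` with [estimate_fov_mask()].
#' @return list with `mse`, `ssim`, `un`.
#' @export
image_quality <- function(a, b, roi_mask = NULL) {
  a <- unclass(a); b <- unclass(b)
  stopifnot(all(dim(a) == dim(b)))
  if (is.null(roi_mask)) roi_mask <- estimate_fov_mask(a)
  if (!any(roi_mask)) stop("empty region of interest")
  mse <- mean((a[roi_mask] - b[roi_mask])^2)
  ssim <- mean(ssim_map(a, b)[roi_mask])
  un_one <- function(img) {
    rng <- range(img[roi_mask])
    if (rng[2] - rng[1] < .Machine$double.eps) {
      warning("uniform ROI: UN undefined, returning sentinel 1e6")
      return(1e6)
    }
    (rng[2] + rng[1]) / (rng[2] - rng[1])
  }
  list(mse = mse, ssim = ssim, un = mean(c(un_one(a), un_one(b))))
}

#' Spearman rank correlation
#'
#' Thin wrapper around `stats::cor.test(method = "spearman")` with average
#' ranks for ties and the asymptotic two-sided p-value.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return list with `rho` and `p_value`; both `NA` (with a warning) for
#'   constant input.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Read a landmark correspondence CSV
#'
#' Expected columns: `x_fixed`, `y_fixed`, `x_moving`, `y_moving`
#' (1-based pixel centres). Point-pair files with columns
#' `x1, y1, x2, y2` are accepted and renamed.
#'
#' @param path CSV path.
#' @export
read_landmarks <- function(path) {
  lm <- read.csv(path, comment.char = "#")
  if (all(c("x1", "y1", "x2", "y2") %in% names(lm))) {
    names(lm)[match(c("x1", "y1", "x2", "y2"), names(lm))] <-
      c("x_fixed", "y_fixed", "x_moving", "y_moving")
  }
  stopifnot(all(c("x_fixed", "y_fixed", "x_moving", "y_moving") %in%
                names(lm)))
  lm
}

#' @rdname read_landmarks
#' @param landmarks landmark data.frame.
#' @export
write_landmarks <- function(landmarks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# 1-based pixel-centre coordinates", con)
  write.csv(landmarks, con, row.names = FALSE)
  invisible(path)
}
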