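#' Histogram-of-oriented-gradients descriptor at a feature point
#'
#' A `window`-pixel square window centred at the rounded point position is
#' divided into 8x8-pixel cells; blocks of 2x2 cells with one-cell stride
#' are L2-normalized and concatenated. With the defaults (32-pixel window,
#' 9 unsigned orientation bins) this yields 3x3 blocks x 4 cells x 9 bins =
#' 324 values. Gradients are unsigned (orientation folded into [0, 180)),
#' so the descriptor is invariant to adding a constant intensity offset.
#' Windows extending past the image border are reflect-padded.
#'
#' @param img gray image matrix.
#' @param x,y point position in image coordinates (subpixel accepted;
#'   rounded to the nearest pixel).
#' @param window window side in pixels (default 32; must be a multiple of
#'   `cell`).
#' @param cell cell side in pixels (default 8).
#' @param bins number of unsigned orientation bins (default 9).
#' @return numeric descriptor vector.
#' @export
extract_hog <- function(img, x, y, window = 32L, cell = 8L, bins = 9L) {
  hog_descriptors(img, data.frame(x = x, y = y),
                  window = window, cell = cell, bins = bins)[1, ]
}

#' Descriptors for a set of feature points
#'
#' Vectorized form of [extract_hog()]: gradient orientation/magnitude maps
#' are computed once and per-cell sums are read from integral images, so
#' the cost is almost independent of the number of points.
#'
#' @param points data.frame with columns `x`, `y`.
#' @inheritParams extract_hog
#' @return numeric matrix, one row per point.
#' @export
hog_descriptors <- function(img, points, window = 32L, cell = 8L,
                            bins = 9L) {
  stopifnot(window %% cell == 0L)
  x <- unclass(img)
  n <- nrow(x); m <- ncol(x)
  np <- nrow(points)
  # reflect-pad by a half window so border windows are defined
  pad <- window %/% 2L
  x <- x[reflect_index(seq.int(1L - pad, n + pad), n),
         reflect_index(seq.int(1L - pad, m + pad), m)]
  nn <- nrow(x); mm <- ncol(x)
  gx <- (x[, c(2:mm, mm)] - x[, c(1, 1:(mm - 1))]) / 2
  gy <- (x[c(2:nn, nn), ] - x[c(1, 1:(nn - 1)), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  bin <- pmin(floor((atan2(gy, gx) %% pi) / (pi / bins)) + 1L, bins)

  # one integral image per orientation bin
  integrals <- lapply(seq_len(bins), function(k) {
    B <- mag * (bin == k)
    ii <- matrix(0, nn + 1L, mm + 1L)
    ii[-1L, -1L] <- t(apply(apply(B, 2L, cumsum), 1L, cumsum))
    ii
  })
  box_sum <- function(ii, r0, c0, side) {
    # rows r0..r0+side-1, cols c0..c0+side-1 (padded coords)
    ii[cbind(r0 + side, c0 + side)] - ii[cbind(r0, c0 + side)] -
      ii[cbind(r0 + side, c0)] + ii[cbind(r0, c0)]
  }

  cells_per_side <- window %/% cell
  n_cells <- cells_per_side^2
  cx <- pmin(pmax(round(points$x), 1L), m)
  cy <- pmin(pmax(round(points$y), 1L), n)
  # top-left of the window in padded coordinates
  r_tl <- cy - pad + 1L + pad  # = cy + 1
  c_tl <- cx + 1L
  H <- matrix(0, np, n_cells * bins)
  for (ci in seq_len(n_cells) - 1L) {
    rr <- r_tl + (ci %/% cells_per_side) * cell
    cc <- c_tl + (ci %% cells_per_side) * cell
    for (k in seq_len(bins)) {
      H[, ci * bins + k] <- box_sum(integrals[[k]], rr, cc, cell)
    }
  }

  blocks_per_side <- cells_per_side - 1L
  out <- matrix(0, np, blocks_per_side^2 * 4L * bins)
  b <- 0L
  for (by in seq_len(blocks_per_side) - 1L) {
    for (bx in seq_len(blocks_per_side) - 1L) {
      cells <- c(by * cells_per_side + bx, by * cells_per_side + bx + 1L,
                 (by + 1L) * cells_per_side + bx,
                 (by + 1L) * cells_per_side + bx + 1L)
      cols <- as.vector(vapply(cells, function(ci) ci * bins + seq_len(bins),
                               integer(bins)))
      v <- H[, cols, drop = FALSE]
      nv <- sqrt(rowSums(v^2))
      v <- v / ifelse(nv > 1e-12, nv, 1)
      out[, b * 4L * bins + seq_len(4L * bins)] <- v
      b <- b + 1L
    }
  }
  out
}

#' Match descriptors by nearest-neighbour ratio test
#'
#' For every descriptor of the fixed image, the nearest and second-nearest
#' descriptors of the moving image are found by Euclidean distance; the
#' match is retained when `d1 / d2 <= ratio_threshold` (boundary
#' inclusive). Matching is one-directional and symmetry is not enforced.
#'
#' `method = "approx"` is the approximate nearest-neighbour search of the
#' registration protocol: candidates are shortlisted in a PCA projection of
#' the moving descriptors and re-ranked by exact distance; it approximates
#' the exact semantics at a fraction of the cost on thousands of points.
#'
#' @param desc_fixed,desc_moving descriptor matrices (rows = points) of
#'   equal width.
#' @param ratio_threshold nearest / second-nearest distance ratio cutoff
#'   (default 0.9).
#' @param method `"exact"` (default) or `"approx"`.
#' @param proj_dim projection dimension for the approximate search.
#' @param shortlist number of shortlisted candidates per query.
#' @return data.frame with columns `idx_fixed`, `idx_moving`, `ratio`.
#' @export
match_descriptors <- function(desc_fixed, desc_moving,
                              ratio_threshold = 0.9,
                              method = c("exact", "approx"),
                              proj_dim = 24L, shortlist = 8L) {
  method <- match.arg(method)
  if (!is.matrix(desc_fixed)) desc_fixed <- rbind(desc_fixed)
  if (!is.matrix(desc_moving)) desc_moving <- rbind(desc_moving)
  stopifnot(ncol(desc_fixed) == ncol(desc_moving))
  empty <- data.frame(idx_fixed = integer(0), idx_moving = integer(0),
                      ratio = numeric(0))
  nB <- nrow(desc_moving)
  if (nB < 2L) {
    warning("fewer than 2 moving descriptors: no ratio test possible")
    return(empty)
  }
  ratio_keep <- function(idx, d1, j1, d2) {
    ratio <- ifelse(d2 > 0, d1 / d2, ifelse(d1 == 0, 0, Inf))
    keep <- ratio <= ratio_threshold
    data.frame(idx_fixed = idx[keep], idx_moving = j1[keep],
               ratio = ratio[keep])
  }
  out <- list()
  chunk <- 1024L
  if (method == "exact") {
    nb2 <- rowSums(desc_moving^2)
    for (s in seq.int(1L, nrow(desc_fixed), by = chunk)) {
      idx <- s:min(s + chunk - 1L, nrow(desc_fixed))
      a <- desc_fixed[idx, , drop = FALSE]
      d2 <- outer(rowSums(a^2), nb2, "+") - 2 * tcrossprod(a, desc_moving)
      d2[d2 < 0] <- 0
      nn2 <- row_min_k_cpp(d2, 2L)
      ii <- seq_along(idx)
      d1 <- sqrt(d2[cbind(ii, nn2[, 1])])
      second <- sqrt(d2[cbind(ii, nn2[, 2])])
      out[[length(out) + 1L]] <- ratio_keep(idx, d1, nn2[, 1], second)
    }
  } else {
    k <- min(shortlist, nB)
    q <- min(proj_dim, ncol(desc_moving), nB)
    # deterministic PCA basis from (a subsample of) the moving descriptors
    samp <- desc_moving[seq.int(1L, nB, length.out = min(nB, 2000L)), ,
                        drop = FALSE]
    v <- svd(samp, nu = 0, nv = q)$v
    Ap <- desc_fixed %*% v
    Bp <- desc_moving %*% v
    nbp <- rowSums(Bp^2)
    nb2 <- rowSums(desc_moving^2)
    for (s in seq.int(1L, nrow(desc_fixed), by = chunk)) {
      idx <- s:min(s + chunk - 1L, nrow(desc_fixed))
      ap <- Ap[idx, , drop = FALSE]
      d2p <- outer(rowSums(ap^2), nbp, "+") - 2 * tcrossprod(ap, Bp)
      nc <- length(idx)
      cand <- row_min_k_cpp(d2p, k)
      # exact re-ranking of the shortlist
      a <- desc_fixed[idx, , drop = FALSE]
      na2 <- rowSums(a^2)
      dex <- matrix(0, nc, k)
      for (t in seq_len(k)) {
        bt <- desc_moving[cand[, t], , drop = FALSE]
        dex[, t] <- na2 + nb2[cand[, t]] - 2 * rowSums(a * bt)
      }
      dex[dex < 0] <- 0
      ii <- seq_len(nc)
      nn2 <- row_min_k_cpp(dex, 2L)
      d1 <- sqrt(dex[cbind(ii, nn2[, 1])])
      j1 <- cand[cbind(ii, nn2[, 1])]
      second <- sqrt(dex[cbind(ii, nn2[, 2])])
      out[[length(out) + 1L]] <- ratio_keep(idx, d1, j1, second)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
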