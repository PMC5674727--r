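# Run code with a private, seeded RNG stream; the caller's RNG state is
# untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' MSAC outlier rejection
#'
#' M-estimator sample consensus over similarity hypotheses from two-point
#' minimal samples. Hypotheses are scored by the truncated squared
#' reprojection error `sum(min(r^2, max_distance^2))`; the inliers of the
#' best hypothesis are the matches with residual at most `max_distance`.
#' Sampling stops early (documented optimization) once the standard 99%
#' adaptive-confidence trial bound for the best inlier ratio so far is
#' reached, never exceeding `max_trials`.
#'
#' @param matches data.frame from [match_descriptors()].
#' @param points_fixed,points_moving data.frames of detected points with
#'   columns `x`, `y`, indexed by `idx_fixed` / `idx_moving` of `matches`.
#' @param max_distance inlier residual threshold in pixels.
#' @param max_trials maximum number of random minimal samples (default
#'   8000).
#' @param seed integer seed for the private sampling stream.
#' @return list with `inliers` (sorted row indices into `matches`),
#'   `n_trials`, `cost`, and `status` (`"ok"` or `"failed"`).
#' @export
msac <- function(matches, points_fixed, points_moving, max_distance,
                 max_trials = 8000L, seed = 1L) {
  n <- nrow(matches)
  if (n < 2L) {
    return(list(inliers = integer(0), n_trials = 0L, cost = Inf,
                status = "failed"))
  }
  p <- complex(real = points_moving$x[matches$idx_moving],
               imaginary = points_moving$y[matches$idx_moving])
  q <- complex(real = points_fixed$x[matches$idx_fixed],
               imaginary = points_fixed$y[matches$idx_fixed])
  d2max <- max_distance^2
  best_cost <- Inf
  best_inl <- integer(0)
  trials_done <- 0L
  needed <- max_trials
  chunk <- 64L
  with_seed(seed, {
    while (trials_done < min(needed, max_trials)) {
      t_now <- min(chunk, max_trials - trials_done)
      i1 <- sample.int(n, t_now, replace = TRUE)
      i2 <- sample.int(n, t_now, replace = TRUE)
      ok <- i1 != i2 & p[i1] != p[i2]
      trials_done <- trials_done + t_now
      if (!any(ok)) next
      i1 <- i1[ok]; i2 <- i2[ok]
      m <- (q[i2] - q[i1]) / (p[i2] - p[i1])
      tt <- q[i1] - m * p[i1]
      # residual matrix: trials x matches
      pred <- outer(m, p) + matrix(tt, length(tt), n)
      r2 <- Mod(pred - matrix(q, length(tt), n, byrow = TRUE))^2
      cost <- rowSums(pmin(r2, d2max))
      b <- which.min(cost)
      if (cost[b] < best_cost) {
        best_cost <- cost[b]
        best_inl <- which(r2[b, ] <= d2max)
        w <- length(best_inl) / n
        needed <- if (w >= 1) trials_done else
          ceiling(log(0.01) / log(max(1 - w^2, 1e-12)))
      }
    }
  })
  if (length(best_inl) < 2L) {
    return(list(inliers = integer(0), n_trials = trials_done, cost = Inf,
                status = "failed"))
  }
  list(inliers = sort(best_inl), n_trials = trials_done, cost = best_cost,
       status = "ok")
}
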