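#' Registration configuration
#'
#' @param sigma0,k,n_octaves,epsilon detector settings, see
#'   [detect_dsaddle()].
#' @param ratio_threshold descriptor matching ratio cutoff (default 0.9).
#' @param max_distances MSAC inlier thresholds in pixels, tried in turn
#'   (default `c(1, 20, 60, 80)`).
#' @param repeats_per_distance seeded MSAC + fit rounds per threshold
#'   (default 1000, the full protocol; reduce to desk scale, e.g. 50, for
#'   quick runs).
#' @param max_trials MSAC trial cap per round (default 8000).
#' @param hog_window descriptor window side (default 32).
#' @param match_method `"approx"` (default; the protocol's approximate
#'   nearest-neighbour search) or `"exact"`.
#' @return list of class `dsaddle_config`.
#' @export
register_config <- function(sigma0 = 1.0, k = 1.6, n_octaves = 4L,
                            epsilon = 0.0010, ratio_threshold = 0.9,
                            max_distances = c(1, 20, 60, 80),
                            repeats_per_distance = 1000L,
                            max_trials = 8000L, hog_window = 32L,
                            match_method = c("approx", "exact")) {
  match_method <- match.arg(match_method)
  stopifnot(all(max_distances > 0), !is.unsorted(max_distances),
            repeats_per_distance >= 1L, max_trials >= 1L)
  structure(list(sigma0 = sigma0, k = k, n_octaves = n_octaves,
                 epsilon = epsilon, ratio_threshold = ratio_threshold,
                 max_distances = max_distances,
                 repeats_per_distance = as.integer(repeats_per_distance),
                 max_trials = as.integer(max_trials),
                 hog_window = as.integer(hog_window),
                 match_method = match_method),
            class = "dsaddle_config")
}

#' Register a moving fundus image onto a fixed one
#'
#' Full pipeline: D-Saddle detection on both images, HOG description,
#' ratio-test matching, then for every MSAC distance threshold a series of
#' seeded MSAC + model-selection + least-squares rounds. With landmarks
#' supplied, the round with the smallest target registration error wins
#' (the evaluation protocol); without landmarks the round with the most
#' inliers wins, ties broken by the smallest mean inlier residual (the
#' application protocol).
#'
#' @param fixed,moving gray image matrices.
#' @param cfg a [register_config()].
#' @param landmarks optional data.frame with columns `x_fixed`, `y_fixed`,
#'   `x_moving`, `y_moving` at the working resolution.
#' @param seed integer; every MSAC round derives a child seed from it.
#' @return object of class `dsaddle_registration`: list with `status`
#'   (`"success"` or `"failed"`), `transformation`, `model`,
#'   `inlier_indices`, `n_inliers`, `tre` (when landmarks given),
#'   `selected_distance`, `matches`, `points_fixed`, `points_moving`, and
#'   `rounds` (per-distance best summaries).
#' @export
register_pair <- function(fixed, moving, cfg = register_config(),
                          landmarks = NULL, seed = 1L) {
  failed <- function(reason) {
    structure(list(status = "failed", reason = reason,
                   transformation = NULL, model = NA_character_,
                   inlier_indices = integer(0), n_inliers = 0L,
                   tre = NA_real_, selected_distance = NA_real_,
                   matches = NULL, rounds = NULL),
              class = "dsaddle_registration")
  }
  pf <- detect_dsaddle(fixed, sigma0 = cfg$sigma0, k = cfg$k,
                       n_octaves = cfg$n_octaves, epsilon = cfg$epsilon)
  pm <- detect_dsaddle(moving, sigma0 = cfg$sigma0, k = cfg$k,
                       n_octaves = cfg$n_octaves, epsilon = cfg$epsilon)
  if (nrow(pf) == 0L || nrow(pm) == 0L) return(failed("no feature points"))
  df <- hog_descriptors(fixed, pf, window = cfg$hog_window)
  dm <- hog_descriptors(moving, pm, window = cfg$hog_window)
  matches <- match_descriptors(df, dm, cfg$ratio_threshold,
                               method = cfg$match_method)
  if (is.null(matches) || nrow(matches) < 2L) return(failed("no matches"))

  mov_xy <- cbind(pm$x[matches$idx_moving], pm$y[matches$idx_moving])
  fix_xy <- cbind(pf$x[matches$idx_fixed], pf$y[matches$idx_fixed])
  lm_mov <- if (!is.null(landmarks)) {
    cbind(landmarks$x_moving, landmarks$y_moving)
  }

  best <- NULL
  rounds <- list()
  round_id <- 0L
  for (di in seq_along(cfg$max_distances)) {
    d <- cfg$max_distances[di]
    best_d <- NULL
    for (r in seq_len(cfg$repeats_per_distance)) {
      round_id <- round_id + 1L
      # child stream depends on (distance, repeat) only, so raising the
      # repeat count reruns the same rounds plus new ones
      child <- (as.numeric(seed) * 7919 + di * 1000003 + r * 104729) %%
        2147483647
      res <- msac(matches, pf, pm, max_distance = d,
                  max_trials = cfg$max_trials, seed = as.integer(child))
      if (res$status != "ok") next
      inl <- res$inliers
      model <- select_model(length(inl))
      tf <- tryCatch(
        fit_transform(mov_xy[inl, , drop = FALSE],
                      fix_xy[inl, , drop = FALSE], model),
        error = function(e) NULL)
      if (is.null(tf)) next
      resid <- sqrt(rowSums((transform_points(tf, mov_xy[inl, , drop = FALSE]) -
                             fix_xy[inl, , drop = FALSE])^2))
      cand <- list(tf = tf, model = model, inliers = inl,
                   n_inliers = length(inl), distance = d,
                   mean_residual = mean(resid))
      cand$tre <- if (!is.null(landmarks)) {
        mapped <- transform_points(tf, lm_mov)
        mean(sqrt((mapped[, 1] - landmarks$x_fixed)^2 +
                  (mapped[, 2] - landmarks$y_fixed)^2))
      } else NA_real_
      better <- function(a, b) {
        if (is.null(b)) return(TRUE)
        if (!is.null(landmarks)) return(a$tre < b$tre)
        if (a$n_inliers != b$n_inliers) return(a$n_inliers > b$n_inliers)
        a$mean_residual < b$mean_residual
      }
      if (better(cand, best_d)) best_d <- cand
      if (better(cand, best)) best <- cand
    }
    if (!is.null(best_d)) {
      rounds[[length(rounds) + 1L]] <-
        data.frame(max_distance = d, model = best_d$model,
                   n_inliers = best_d$n_inliers,
                   mean_residual = best_d$mean_residual, tre = best_d$tre)
    }
  }
  if (is.null(best)) return(failed("all MSAC rounds failed"))
  structure(list(status = "success", reason = NA_character_,
                 transformation = best$tf, model = best$model,
                 inlier_indices = best$inliers, n_inliers = best$n_inliers,
                 tre = best$tre, selected_distance = best$distance,
                 matches = matches, points_fixed = pf, points_moving = pm,
                 rounds = if (length(rounds)) do.call(rbind, rounds)),
            class = "dsaddle_registration")
}

#' @export
print.dsaddle_registration <- function(x, ...) {
  cat(sprintf("registration: %s\n", x$status))
  if (x$status == "success") {
    cat(sprintf("  model: %s, inliers: %d, distance: %g px\n",
                x$model, x$n_inliers, x$selected_distance))
    if (!is.na(x$tre)) cat(sprintf("  TRE: %.3f px\n", x$tre))
  } else {
    cat(sprintf("  reason: %s\n", x$reason))
  }
  invisible(x)
}
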