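# Registration batteries shared between test files; computed once per test
# session and cached.
.dsaddle_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .dsaddle_cache)) {
    assign(key, force(expr), envir = .dsaddle_cache)
  }
  get(key, envir = .dsaddle_cache)
}

battery_register <- function(pair, seed, repeats = 50L,
                             with_landmarks = TRUE) {
  cfg <- register_config(repeats_per_distance = repeats)
  res <- register_pair(pair$fixed, pair$moving, cfg,
                       landmarks = if (with_landmarks) pair$landmarks,
                       seed = seed)
  if (res$status != "success") return(Inf)
  if (with_landmarks) res$tre else tre(pair$landmarks, res$transformation)
}

# 20 pairs with >= 75% overlap spanning the three transform models
model_battery_tres <- function() {
  cached("model_battery", {
    specs <- c(
      lapply(101:107, function(s) list(seed = s, spec = list(
        model = "similarity", overlap = c(0.78, 0.95)))),
      lapply(201:207, function(s) list(seed = s, spec = list(
        model = "affine", overlap = c(0.78, 0.95), shear = 0.015))),
      lapply(301:306, function(s) list(seed = s, spec = list(
        model = "polynomial2", overlap = c(0.78, 0.95), quad = 2e-5))))
    vapply(specs, function(b) {
      pair <- generate_pair(phantom_config(seed = b$seed),
                            transform_spec = b$spec, category = "S")
      battery_register(pair, seed = b$seed)
    }, numeric(1))
  })
}

# 10 near-identity pairs (super-resolution regime)
near_identity_tres <- function() {
  cached("near_identity", {
    vapply(601:610, function(s) {
      pair <- generate_pair(phantom_config(seed = s),
                            transform_spec = list(overlap = c(0.97, 1),
                                                  rotation_deg = c(0, 0.5),
                                                  scale = 1),
                            category = "S")
      battery_register(pair, seed = s)
    }, numeric(1))
  })
}

# overlap batteries on low-quality pairs (strong illumination falloff and
# dark spots: the regime in which accuracy depends measurably on overlap)
lowq_config <- function(seed) {
  phantom_config(seed = seed, illumination_gradient = 0.5,
                 dark_spots = list(count = 6L, radius_range = c(10, 40)),
                 noise_sigma = 0.01, n_vessels = 6L)
}

overlap_battery <- function(overlaps = c(0.4, 0.6, 0.8, 0.95)) {
  cached("overlap_battery", {
    do.call(rbind, lapply(overlaps, function(ov) {
      data.frame(overlap = ov, tre = vapply(1:4, function(s) {
        pair <- generate_pair(lowq_config(500 + s),
                              transform_spec = list(overlap = ov),
                              category = "P")
        battery_register(pair, seed = s, repeats = 25L)
      }, numeric(1)))
    }))
  })
}

# mean inner-ring rejection fraction over seeded default phantoms
inner_rejection_pct <- function(seeds = 1:10) {
  cached("inner_rejection", {
    rej <- vapply(seeds, function(s) {
      ph <- generate_fundus(phantom_config(seed = s))
      st <- attr(suppressWarnings(detect_dsaddle(ph$img)), "candidate_stats")
      1 - sum(st$n_inner_pass) / sum(st$n_candidates)
    }, numeric(1))
    100 * mean(rej)
  })
}
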