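# Shared in-code fixtures: tiny photo/deployment tables and simulated worlds.

toy_deployments <- function(n = 1, span = 3600, recovery = 10.35) {
  data.frame(camera_id = sprintf("c%02d", seq_len(n)),
             x = 100 * seq_len(n), y = 0, start = 0, end = span,
             half_angle = 0.37, recovery_s = recovery, burst_size = 6,
             burst_interval_s = 0.49, stringsAsFactors = FALSE)
}

# one photo-table row per tag; dist = NA makes a blank frame
toy_photo_rows <- function(camera_id, timestamp, trigger_id, dist = NA,
                           angle = "0-0.2", reaction = FALSE,
                           animal = "a1", group = "g1") {
  n <- max(length(timestamp), length(dist))
  dist <- rep(dist, length.out = n)
  timestamp <- rep(timestamp, length.out = n)
  blank <- is.na(dist)
  bd <- list(lo = rep(NA_real_, n), hi = rep(NA_real_, n))
  if (any(!blank)) {
    b <- groupdens:::distance_to_band(dist[!blank])
    bd$lo[!blank] <- b$lo; bd$hi[!blank] <- b$hi
  }
  data.frame(camera_id = camera_id, timestamp = timestamp,
             trigger_id = rep(trigger_id, length.out = n),
             animal_id = ifelse(blank, NA_character_,
                                rep(animal, length.out = n)),
             distance_lo = bd$lo, distance_hi = bd$hi,
             angle_band = ifelse(blank, NA_character_,
                                 rep(angle, length.out = n)),
             reaction = ifelse(blank, NA, rep(reaction, length.out = n)),
             rem_contact = ifelse(blank, NA, FALSE),
             group_id = ifelse(blank, NA_character_,
                               rep(group, length.out = n)),
             stringsAsFactors = FALSE)
}

# small always-active solitary world shared across recovery tests
solitary_world <- function(n_animals, arena_km, speed, seed,
                           group_spread = 0) {
  simulation_truth(true_density = n_animals / arena_km^2,
                   n_groups = n_animals,
                   group_sizes = rep(1, n_animals),
                   speed_active = speed,
                   activity = activity_curve("uniform", level = 1),
                   group_spread = group_spread, arena_km = arena_km,
                   turning_sd = 0.1, seed = seed)
}

# inverse-cdf sample of binned point-transect half-normal distances
sample_hn_point_distances <- function(n, sigma, w) {
  r <- seq(0.005, w, by = 0.005)
  cdf <- cumsum(r * exp(-r^2 / (2 * sigma^2)))
  cdf <- cdf / cdf[length(cdf)]
  draws <- stats::approx(cdf, r, stats::runif(n), rule = 2)$y
  b <- groupdens:::distance_to_band(pmin(pmax(draws, 1e-3), 25))
  scheme <- distance_band_scheme()
  idx <- groupdens:::match_distance_band(b$lo, b$hi)
  scheme$n <- tabulate(idx, nbins = nrow(scheme))
  scheme[scheme$hi <= w + 1e-9, ]
}
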