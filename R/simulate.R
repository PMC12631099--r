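#' @title Synthetic camera-trap world
#' @description
#' Simulates clustered groups of animals moving on a torus past
#' sector-viewshed cameras with realistic trigger mechanics (multi-photo
#' bursts, recovery dead time, spurious blank triggers), plus a GPS collar on
#' one individual. Truth (density, speed, activity) is known, so both
#' estimators can be tested by parameter recovery.
#' @name synthetic_data
NULL

wrap_delta <- function(d, L) ((d + L / 2) %% L) - L / 2
wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi

#' Von Mises density
#'
#' @param x Angles in radians.
#' @param mu Mean direction (radians).
#' @param kappa Concentration (>= 0).
#' @return Density values. Computed with exponentially scaled Bessel
#'   functions, so large `kappa` does not overflow.
#' @export
dvonmises <- function(x, mu = 0, kappa = 1) {
  exp(kappa * (cos(x - mu) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler; reduces to uniform when `kappa` is ~0.
#'
#' @param n Number of draws.
#' @inheritParams dvonmises
#' @return Angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-9) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2 * (n - length(out)), 16)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    out <- c(out, th)
  }
  (mu + out[seq_len(n)]) %% (2 * pi)
}

#' Daily activity curve specification
#'
#' Describes the probability that an animal is active (and moving) as a
#' function of time of day. The curve is peak-normalized: at the daily peak
#' animals are certainly active, so the analytic activity level equals
#' `1 / (2*pi * max f)` for the underlying circular density `f` -- the same
#' quantity the circular-kernel estimator targets.
#'
#' @param type `"uniform"` (constant activity probability `level`),
#'   `"vonmises"` (single mode) or `"vonmises_mixture"`.
#' @param level Constant activity probability for `type = "uniform"`.
#' @param mu Mode location(s), radians of time-of-day.
#' @param kappa Concentration(s).
#' @param weights Mixture weights (normalized internally).
#' @return An object of class `activity_curve`.
#' @export
activity_curve <- function(type = c("uniform", "vonmises", "vonmises_mixture"),
                           level = 1, mu = 0, kappa = 1, weights = NULL) {
  type <- match.arg(type)
  if (type == "uniform" && (level < 0 || level > 1))
    stop("uniform activity 'level' must lie in [0, 1]")
  if (is.null(weights)) weights <- rep(1, length(mu))
  weights <- weights / sum(weights)
  structure(list(type = type, level = level, mu = mu, kappa = kappa,
                 weights = weights), class = "activity_curve")
}

# circular density of active time (only meaningful for von Mises types)
activity_density <- function(curve, x) {
  stopifnot(inherits(curve, "activity_curve"))
  if (curve$type == "uniform") return(rep(1 / (2 * pi), length(x)))
  f <- 0
  for (i in seq_along(curve$mu))
    f <- f + curve$weights[i] * dvonmises(x, curve$mu[i], curve$kappa[i])
  f
}

# P(active | time-of-day radians), peak-normalized to 1 for von Mises types
activity_prob <- function(curve, x) {
  if (curve$type == "uniform") return(rep(curve$level, length(x)))
  grid <- seq(0, 2 * pi, length.out = 2048)
  fmax <- max(activity_density(curve, grid))
  pmin(activity_density(curve, x) / fmax, 1)
}

#' Canonical diurnal activity curve
#'
#' A two-mode (morning / late-afternoon) von Mises mixture typical of a
#' diurnal forager: peaks at 08:00 and 16:00 with moderate concentration,
#' giving an analytic activity level of about 0.5. Used as the default
#' non-trivial curve in simulations and tests.
#'
#' @return An [activity_curve()].
#' @export
activity_curve_diurnal <- function() {
  activity_curve("vonmises_mixture",
                 mu = 2 * pi * c(8, 16) / 24,
                 kappa = c(1.5, 1.5), weights = c(0.5, 0.5))
}

#' Analytic activity level of a curve
#'
#' The proportion of the day active: the mean of the activity probability,
#' equal to `1/(2*pi*max f)` for peak-normalized von Mises curves.
#'
#' @param curve An [activity_curve()].
#' @return Scalar in (0, 1].
#' @export
activity_level_true <- function(curve) {
  if (curve$type == "uniform") return(curve$level)
  grid <- seq(0, 2 * pi, length.out = 8192)
  1 / (2 * pi * max(activity_density(curve, grid)))
}

#' Simulation truth
#'
#' The known world against which estimates are judged. Group sizes are drawn
#' (multinomially) so that they sum exactly to `round(density * area)`,
#' keeping the arena-density invariant.
#'
#' @param true_density Individuals per km^2.
#' @param n_groups Number of social groups. Solitary animals are groups of
#'   size one (set `n_groups = round(true_density * arena_km^2)`).
#' @param speed_active Travel speed while active, m/s. The default (0.22)
#'   gives a day range of ~4.9 km at an activity level of 0.26, matching a
#'   large terrestrial primate; crossing speeds in recovery tests are passed
#'   explicitly.
#' @param activity An [activity_curve()]; default uniform, always active.
#' @param group_spread SD (meters) of the bivariate-normal scatter of
#'   members about their group centroid, refreshed each second.
#' @param arena_km Side of the square torus arena, km.
#' @param turning_sd SD of the per-second heading increment (radians); small
#'   values approximate the straight-line movement of the ideal-gas model.
#' @param group_sizes Optional explicit vector of group sizes (overrides the
#'   multinomial draw; must be consistent with density within 20%).
#' @param seed Integer seed controlling the size draw and downstream
#'   simulation defaults.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(true_density = 3, n_groups = 2,
                             speed_active = 0.22,
                             activity = activity_curve("uniform", level = 1),
                             group_spread = 30, arena_km = 4,
                             turning_sd = 0.1, group_sizes = NULL,
                             seed = 1L) {
  if (true_density <= 0) stop("'true_density' must be > 0")
  if (speed_active <= 0) stop("'speed_active' must be > 0")
  area <- arena_km^2
  total <- max(1L, round(true_density * area))
  if (is.null(group_sizes)) {
    set.seed(seed)
    group_sizes <- as.vector(stats::rmultinom(1, total, rep(1, n_groups)))
    group_sizes[group_sizes == 0] <- 1L
  } else {
    n_groups <- length(group_sizes)
    if (abs(sum(group_sizes) - true_density * area) > 0.2 * true_density * area)
      stop("group sizes inconsistent with 'true_density' and arena area")
  }
  structure(list(true_density = true_density, n_groups = n_groups,
                 group_sizes = group_sizes, speed_active = speed_active,
                 activity = activity, group_spread = group_spread,
                 arena_km = arena_km, turning_sd = turning_sd, seed = seed),
            class = "simulation_truth")
}

#' Simulate group movement
#'
#' Group centroids perform correlated random walks at `speed_active` during
#' seconds the activity curve marks active (per-second Bernoulli, matched to
#' the curve's marginal probability); members scatter about the centroid with
#' SD `group_spread`, refreshed each second. Positions are stored unwrapped
#' (the torus wrap is applied at detection time), so GPS path lengths obey
#' the triangle inequality exactly.
#'
#' @param truth A [simulation_truth()].
#' @param duration Simulation length in seconds (1 s resolution).
#' @param seed Integer seed; defaults to the truth's seed.
#' @param start_tod Time of day (seconds past midnight) of the first step.
#' @return A `track_set`: list of tracks (`id`, `group_id`, `x`, `y`,
#'   `moving`), with the arena size and duration as attributes.
#' @export
simulate_movement <- function(truth, duration = 86400, seed = truth$seed,
                              start_tod = 0) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (truth$speed_active <= 0) stop("'speed_active' must be > 0")
  set.seed(seed)
  L <- truth$arena_km * 1000
  Tn <- as.integer(duration)
  tod <- ((start_tod + 0:(Tn - 1)) %% 86400) / 86400 * 2 * pi
  p_active <- activity_prob(truth$activity, tod)
  tracks <- list()
  aid <- 0L
  for (g in seq_along(truth$group_sizes)) {
    x0 <- stats::runif(1, 0, L); y0 <- stats::runif(1, 0, L)
    heading <- cumsum(c(stats::runif(1, 0, 2 * pi),
                        stats::rnorm(Tn - 1, 0, truth$turning_sd)))
    active <- stats::runif(Tn) < p_active
    step <- truth$speed_active * active
    cx <- x0 + cumsum(c(0, (step * cos(heading))[-Tn]))
    cy <- y0 + cumsum(c(0, (step * sin(heading))[-Tn]))
    for (m in seq_len(truth$group_sizes[g])) {
      aid <- aid + 1L
      if (truth$group_spread > 0) {
        mx <- cx + stats::rnorm(Tn, 0, truth$group_spread)
        my <- cy + stats::rnorm(Tn, 0, truth$group_spread)
      } else {
        mx <- cx; my <- cy
      }
      tracks[[aid]] <- structure(
        list(id = sprintf("a%03d", aid), group_id = sprintf("g%02d", g),
             x = mx, y = my, moving = active),
        class = "track")
    }
  }
  structure(tracks, class = "track_set", arena_m = L, duration = Tn,
            start_tod = start_tod, truth = truth)
}

#' Detection specification for the simulator
#'
#' Distance and angle detection-probability curves plus nuisance trigger
#' behavior. `false_trigger_rate` is the per-second probability of a spurious
#' trigger (vegetation, heat shimmer); these produce the blank frames real
#' surveys rely on to delimit contacts.
#'
#' @param g_distance Function of distance (m) returning detection probability.
#' @param g_angle Function of angle as a fraction of the half field-of-view
#'   (0 center, 1 edge) returning a multiplicative detection factor.
#' @param false_trigger_rate Per-second spurious trigger probability.
#' @param reaction_prob Probability a tagged animal is flagged as reacting.
#' @param g_trigger Optional separate trigger-sensitivity curve (function of
#'   distance). The default `NULL` uses the tagging curve for the trigger
#'   draw as well, so detectability acts on both the trigger and the tag;
#'   passing `function(r) rep(1, length(r))` models an ideal motion sensor,
#'   leaving the tagged distances distributed exactly as `r*g(r)` (the
#'   point-transect observation model).
#' @return A `detection_spec` object.
#' @export
detection_spec <- function(g_distance = function(r) rep(1, length(r)),
                           g_angle = function(u) rep(1, length(u)),
                           false_trigger_rate = 5e-4,
                           reaction_prob = 0, g_trigger = NULL) {
  structure(list(g_distance = g_distance, g_angle = g_angle,
                 false_trigger_rate = false_trigger_rate,
                 reaction_prob = reaction_prob, g_trigger = g_trigger),
            class = "detection_spec")
}

#' Half-normal detection specification
#'
#' @param sigma Half-normal scale of the distance falloff (m).
#' @param angle_sigma Optional half-normal scale of the angular falloff, as a
#'   fraction of the half field-of-view; `NULL` means no angular falloff.
#' @inheritParams detection_spec
#' @return A `detection_spec`.
#' @export
detection_halfnormal <- function(sigma, angle_sigma = NULL,
                                 false_trigger_rate = 5e-4,
                                 reaction_prob = 0, g_trigger = NULL) {
  ga <- if (is.null(angle_sigma)) function(u) rep(1, length(u))
        else function(u) exp(-u^2 / (2 * angle_sigma^2))
  detection_spec(g_distance = function(r) exp(-r^2 / (2 * sigma^2)),
                 g_angle = ga, false_trigger_rate = false_trigger_rate,
                 reaction_prob = reaction_prob, g_trigger = g_trigger)
}

#' Lay out a camera deployment grid
#'
#' Cameras are placed on a jittered square grid inside the arena with random
#' orientations, mirroring a grid-based field design.
#'
#' @param n_cameras Number of cameras.
#' @param arena_km Arena side, km (must match the movement simulation).
#' @param duration Operating window length, seconds (start = 0).
#' @param half_angle Nominal half field-of-view, radians.
#' @param max_tag_distance Sector radius within which animals can be tagged, m.
#' @param recovery_s,burst_size,burst_interval_s Trigger mechanics; defaults
#'   are the measured performance of a fast-recovery trail camera
#'   (6-photo bursts 0.49 s apart, 10.35 s recovery dead time).
#' @param seed Integer seed for jitter and orientation.
#' @return Deployment data frame (schema of [observation_set()], plus
#'   `orientation` and `max_tag_distance`).
#' @export
make_deployments <- function(n_cameras, arena_km, duration,
                             half_angle = 0.37, max_tag_distance = 25,
                             recovery_s = 10.35, burst_size = 6,
                             burst_interval_s = 0.49, seed = 1L) {
  set.seed(seed)
  L <- arena_km * 1000
  ncol <- ceiling(sqrt(n_cameras))
  cell <- L / ncol
  gx <- (seq_len(ncol) - 0.5) * cell
  grid <- expand.grid(x = gx, y = gx)[seq_len(n_cameras), ]
  data.frame(camera_id = sprintf("c%02d", seq_len(n_cameras)),
             x = grid$x + stats::runif(n_cameras, -cell / 4, cell / 4),
             y = grid$y + stats::runif(n_cameras, -cell / 4, cell / 4),
             start = 0, end = duration, half_angle = half_angle,
             recovery_s = recovery_s, burst_size = burst_size,
             burst_interval_s = burst_interval_s,
             orientation = stats::runif(n_cameras, 0, 2 * pi),
             max_tag_distance = max_tag_distance,
             stringsAsFactors = FALSE)
}

#' Simulate camera-trap detections from tracks
#'
#' Each second a camera that is not in recovery triggers if at least one
#' individual inside its sector passes a Bernoulli detection draw (or a
#' spurious trigger fires). A trigger emits `burst_size` frames spaced
#' `burst_interval_s` apart; the camera is then dead for `recovery_s` after
#' the burst's nominal coverage (`burst_size * burst_interval_s`). Animals in
#' view at a frame are tagged independently with their detection probability;
#' frames with no tags are recorded as blank.
#'
#' @param tracks A `track_set` from [simulate_movement()].
#' @param deployments Deployment data frame (see [make_deployments()]).
#' @param spec A [detection_spec()].
#' @param seed Integer seed.
#' @return An [observation_set()].
#' @export
simulate_detections <- function(tracks, deployments, spec = detection_spec(),
                                seed = 1L) {
  stopifnot(inherits(tracks, "track_set"), inherits(spec, "detection_spec"))
  set.seed(seed)
  L <- attr(tracks, "arena_m")
  dur <- attr(tracks, "duration")
  if (any(deployments$x < 0 | deployments$x > L |
          deployments$y < 0 | deployments$y > L))
    stop("cameras must lie inside the arena")
  animal_ids <- vapply(tracks, function(tr) tr$id, "")
  group_ids <- vapply(tracks, function(tr) tr$group_id, "")
  fld <- list(cam = list(), ts = list(), trig = list(), an = list(),
              dlo = list(), dhi = list(), ab = list(), re = list(),
              gid = list())
  ri <- 0L
  for (ci in seq_len(nrow(deployments))) {
    cam <- deployments[ci, ]
    r_max <- if ("max_tag_distance" %in% names(cam)) cam$max_tag_distance else 25
    orient <- if ("orientation" %in% names(cam)) cam$orientation else 0
    t0 <- cam$start
    Tn <- as.integer(floor(cam$end - cam$start))
    idx <- pmin(as.integer(t0) + seq_len(Tn), dur)
    # coarse proximity pre-screen: an animal can reach the sector inside a
    # coarse block only if the block's sample point is within
    # r_max + block-length * (speed + scatter allowance) of the camera
    coarse <- 20L
    truth <- attr(tracks, "truth")
    vmax <- truth$speed_active + 4 * truth$group_spread / coarse
    thr <- r_max + coarse * max(vmax, 1)
    ci_idx <- idx[seq(1L, Tn, by = coarse)]
    sec <- integer(0); an <- integer(0); dist <- numeric(0); rel <- numeric(0)
    for (a in seq_along(tracks)) {
      dxc <- abs(wrap_delta(tracks[[a]]$x[ci_idx] - cam$x, L))
      dyc <- abs(wrap_delta(tracks[[a]]$y[ci_idx] - cam$y, L))
      blocks <- which(dxc <= thr & dyc <= thr)
      if (!length(blocks)) next
      loc <- unique(unlist(lapply(blocks, function(b)
        seq(max(1L, (b - 2L) * coarse + 1L), min(Tn, (b + 1L) * coarse)))))
      loc <- sort(loc)
      dx <- wrap_delta(tracks[[a]]$x[idx[loc]] - cam$x, L)
      dy <- wrap_delta(tracks[[a]]$y[idx[loc]] - cam$y, L)
      near <- which(abs(dx) <= r_max & abs(dy) <= r_max)
      if (!length(near)) next
      d <- sqrt(dx[near]^2 + dy[near]^2)
      keep <- d <= r_max & d > 0
      near <- near[keep]; d <- d[keep]
      if (!length(near)) next
      ra <- abs(wrap_angle(atan2(dy[near], dx[near]) - orient))
      inf <- ra <= cam$half_angle
      if (!any(inf)) next
      sec <- c(sec, loc[near[inf]]); an <- c(an, rep(a, sum(inf)))
      dist <- c(dist, d[inf]); rel <- c(rel, ra[inf] / cam$half_angle)
    }
    p <- if (length(sec))
      pmin(pmax(spec$g_distance(dist) * spec$g_angle(rel), 0), 1)
    else numeric(0)
    p_trig <- if (is.null(spec$g_trigger)) p else
      pmin(pmax(spec$g_trigger(dist) * spec$g_angle(rel), 0), 1)
    draw <- stats::runif(length(p_trig)) < p_trig
    succ <- rep(FALSE, Tn)
    if (length(sec)) {
      s_any <- tapply(draw, sec, any)
      succ[as.integer(names(s_any))] <- as.logical(s_any)
    }
    false_sec <- which(stats::runif(Tn) < spec$false_trigger_rate)
    is_false <- rep(FALSE, Tn); is_false[false_sec] <- TRUE
    lookup <- if (length(sec)) split(seq_along(sec), sec) else list()
    cand <- sort(unique(c(sec, false_sec)))
    avail <- -Inf
    trig <- 0L
    bs <- cam$burst_size; ib <- cam$burst_interval_s
    for (s in cand) {
      tt <- t0 + s - 1
      # re-trigger at the exact end of recovery when occupancy persists:
      # integer-second quantization would otherwise stretch the cycle and
      # desynchronize frames from the trigger-adjusted effort
      if (tt < avail) {
        if (avail <= tt + 1) tt <- avail else next
      }
      if (!(succ[s] || is_false[s])) next
      trig <- trig + 1L
      ftimes <- tt + (seq_len(bs) - 1) * ib
      ftimes <- ftimes[ftimes <= cam$end]
      avail <- tt + bs * ib + cam$recovery_s
      trig_lab <- sprintf("%s_t%05d", cam$camera_id, trig)
      for (ft in ftimes) {
        fsec <- min(as.integer(floor(ft - t0)) + 1L, Tn)
        at <- lookup[[as.character(fsec)]]
        tagged <- integer(0)
        if (length(at)) tagged <- at[stats::runif(length(at)) < p[at]]
        ri <- ri + 1L
        k <- length(tagged)
        if (k) {
          bd <- distance_to_band(dist[tagged])
          fld$cam[[ri]] <- rep(cam$camera_id, k)
          fld$ts[[ri]] <- rep(ft, k)
          fld$trig[[ri]] <- rep(trig_lab, k)
          fld$an[[ri]] <- animal_ids[an[tagged]]
          fld$dlo[[ri]] <- bd$lo
          fld$dhi[[ri]] <- bd$hi
          fld$ab[[ri]] <- fraction_to_angle_band(pmin(rel[tagged], 1))
          fld$re[[ri]] <- stats::runif(k) < spec$reaction_prob
          fld$gid[[ri]] <- group_ids[an[tagged]]
        } else {
          fld$cam[[ri]] <- cam$camera_id
          fld$ts[[ri]] <- ft
          fld$trig[[ri]] <- trig_lab
          fld$an[[ri]] <- NA_character_
          fld$dlo[[ri]] <- NA_real_
          fld$dhi[[ri]] <- NA_real_
          fld$ab[[ri]] <- NA_character_
          fld$re[[ri]] <- NA
          fld$gid[[ri]] <- NA_character_
        }
      }
    }
  }
  photos <- data.frame(
    camera_id = as.character(unlist(fld$cam)),
    timestamp = as.numeric(unlist(fld$ts)),
    trigger_id = as.character(unlist(fld$trig)),
    animal_id = as.character(unlist(fld$an)),
    distance_lo = as.numeric(unlist(fld$dlo)),
    distance_hi = as.numeric(unlist(fld$dhi)),
    angle_band = as.character(unlist(fld$ab)),
    reaction = as.logical(unlist(fld$re)),
    rem_contact = as.logical(unlist(fld$an) == "__never__"),
    group_id = as.character(unlist(fld$gid)),
    stringsAsFactors = FALSE)
  photos$rem_contact <- ifelse(is.na(photos$animal_id), NA, FALSE)
  observation_set(photos, deployments, validate = FALSE)
}

#' Sample a GPS collar track
#'
#' Samples an individual's positions at a fixed interval inside a daily fix
#' window (collars commonly fix only during daylight, with all fixes
#' successful).
#'
#' @param track A single `track` from [simulate_movement()].
#' @param fix_interval Seconds between fixes (>= 1, integer).
#' @param window Daily fix window, seconds past midnight `c(from, to)`.
#' @return A `gps_track` data frame (`timestamp`, `x`, `y`) with the fix
#'   interval as an attribute.
#' @export
simulate_gps_track <- function(track, fix_interval = 3600,
                               window = c(5, 19) * 3600) {
  stopifnot(inherits(track, "track"))
  if (fix_interval < 1) stop("'fix_interval' must be >= 1 s (track resolution)")
  fix_interval <- as.integer(fix_interval)
  Tn <- length(track$x)
  t_all <- 0:(Tn - 1)
  tod <- t_all %% 86400
  sel <- tod >= window[1] & tod <= window[2] &
    ((tod - window[1]) %% fix_interval) == 0
  out <- data.frame(timestamp = t_all[sel], x = track$x[sel],
                    y = track$y[sel])
  structure(out, class = c("gps_track", "data.frame"),
            fix_interval = fix_interval)
}

#' Expected contact rate under the ideal-gas encounter model
#'
#' The analytic expectation inverted by the REM: a population at density `D`
#' moving `v` km/day past a sector of radius `r` and full angle `theta`
#' generates `D * v * r * (2 + theta) / pi` contacts per camera-day.
#'
#' @param density Individuals per km^2.
#' @param day_range km traveled per day.
#' @param r Detection radius, km.
#' @param theta Full detection angle, radians.
#' @return Expected contacts per camera per day.
#' @export
expected_trapping_rate <- function(density, day_range, r, theta) {
  density * day_range * r * (2 + theta) / pi
}
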