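#' @title Random encounter model (REM) density estimation
#' @description
#' Density from the rate of first contacts between moving animals and static
#' cameras under an ideal-gas movement model:
#' `D = (y/t) * pi / (v * r * (2 + theta))`, with the trapping rate `y/t` in
#' contacts per camera-day, day range `v` in km/day, effective detection
#' radius `r` in km and effective detection angle `theta` in radians.
#' Variance combines independent component CVs by the delta method; travel
#' speed comes from GPS collar fixes, with fix-interval rarefaction to probe
#' the sensitivity of straight-line speeds to fix frequency.
#' @name rem_estimator
NULL

#' Identify first contacts in a camera's photo stream
#'
#' Identities are unknown, so contacts are bookkept by counts of
#' individuals within the gating distance: an increase of the in-view count
#' by `m` adds `m` contacts, departures decrement, and a unit with no
#' animals at all resets the in-view set (an animal that leaves and
#' re-enters counts anew). The gate is applied at the first qualifying
#' appearance.
#'
#' The default counting unit is the burst (all frames sharing a
#' `trigger_id`), whose in-view count is the maximum over its frames: a
#' tagger scanning a sequence recognizes the same animal across its
#' frames, and per-frame counting would convert every missed detection
#' within a burst into a spurious new contact when per-frame detection is
#' imperfect. `by = "frame"` applies the strict per-frame rule.
#'
#' @param photos Time-sorted, reaction-filtered photo rows for one camera.
#' @param max_distance Gating distance, m (an animal beyond it could not
#'   credibly have triggered the camera).
#' @param gap_reset_s Optional frameless-gap reset (seconds): when the
#'   camera stays silent for longer than this the viewshed is inferred to
#'   have emptied, and the in-view set is reset. Only valid when detection
#'   inside the zone is near-certain (a live camera facing a present animal
#'   would have triggered); the default `Inf` applies the strict rule that
#'   only an animal-free unit resets.
#' @param by Counting unit: `"burst"` (default) or `"frame"`.
#' @return List: `y` (number of contacts), `times` (contact timestamps),
#'   `distances` (data frame `lo`, `hi` of the contributing tags' bands),
#'   `angle_bands` (their angle bands).
#' @export
identify_contacts <- function(photos, max_distance = 25, gap_reset_s = Inf,
                              by = c("burst", "frame")) {
  by <- match.arg(by)
  if (length(unique(photos$camera_id)) > 1)
    stop("'photos' must contain a single camera's stream")
  out <- list(y = 0L, times = numeric(0),
              distances = data.frame(lo = numeric(0), hi = numeric(0)),
              angle_bands = character(0))
  if (!nrow(photos)) return(out)
  if (is.unsorted(photos$timestamp)) stop("photo stream is not time-sorted")
  fr_id <- if (by == "burst" && !all(is.na(photos$trigger_id))) {
    match(photos$trigger_id, unique(photos$trigger_id))
  } else {
    match(photos$timestamp, unique(photos$timestamp))
  }
  tagged <- !is.na(photos$animal_id)
  mid <- rep(NA_real_, nrow(photos))
  if (any(tagged))
    mid[tagged] <- band_midpoint(photos$distance_lo[tagged],
                                 photos$distance_hi[tagged])
  qual <- tagged & !is.na(mid) & mid <= max_distance
  rows_by_frame <- split(seq_len(nrow(photos)), fr_id)
  prev <- 0L
  ci <- 0L
  keep_rows <- integer(0)
  times <- numeric(0)
  last_t <- -Inf
  for (fr in rows_by_frame) {
    tt <- photos$timestamp[fr[1]]
    if (tt - last_t > gap_reset_s) prev <- 0L
    last_t <- max(photos$timestamp[fr])
    if (!any(tagged[fr])) { prev <- 0L; next }
    qr <- fr[qual[fr]]
    if (length(qr) > 1) {
      # in-view count of the unit = the best-populated frame within it
      per_frame <- split(qr, photos$timestamp[qr])
      best <- per_frame[[which.max(lengths(per_frame))]]
      qr <- c(best, setdiff(qr, best))[seq_along(best)]
    }
    q <- length(qr)
    inc <- max(0L, q - prev)
    if (inc > 0) {
      keep_rows <- c(keep_rows, qr[seq_len(inc)])
      times <- c(times, rep(photos$timestamp[fr[1]], inc))
      ci <- ci + inc
    }
    prev <- q
  }
  out$y <- ci
  out$times <- times
  out$distances <- data.frame(lo = photos$distance_lo[keep_rows],
                              hi = photos$distance_hi[keep_rows])
  out$angle_bands <- photos$angle_band[keep_rows]
  out
}

#' Trapping rate with camera-level bootstrap variance
#'
#' `rate = sum(y) / sum(T_days)` with trigger-adjusted effort in days
#' (matched to the CTDS effort). Variance by resampling camera locations
#' with replacement.
#'
#' @param y Contacts per camera.
#' @param T_days Trigger-adjusted operating time per camera, days.
#' @param B Bootstrap resamples.
#' @param seed Integer seed.
#' @return List: `rate` (contacts per camera-day), `se`, `cv` (`NA` and
#'   flagged when all counts are zero), `boot`.
#' @export
trapping_rate <- function(y, T_days, B = 1000, seed = NULL) {
  if (length(y) != length(T_days)) stop("'y' and 'T_days' lengths differ")
  if (sum(T_days) <= 0) stop("total effort must be positive")
  if (!is.null(seed)) set.seed(seed)
  rate <- sum(y) / sum(T_days)
  K <- length(y)
  boot <- replicate(B, {
    pick <- sample.int(K, K, replace = TRUE)
    if (sum(T_days[pick]) > 0) sum(y[pick]) / sum(T_days[pick]) else 0
  })
  se <- stats::sd(boot)
  cv <- if (rate > 0) se / rate else NA_real_
  list(rate = rate, se = se, cv = cv, boot = boot,
       all_zero = sum(y) == 0)
}

#' Straight-line travel speed from GPS fixes
#'
#' Speeds are Euclidean displacements between consecutive fixes divided by
#' the elapsed time; the speed while active averages segments above an
#' activity threshold. Daily path length (DPL) is the mean over days of the
#' summed displacements.
#'
#' @param gps A `gps_track` data frame (`timestamp`, `x`, `y`).
#' @param active_threshold Segments faster than this (m/s) count as active.
#' @return A `speed_estimate`: `speed_active` (m/s), `se`, `n_segments`,
#'   `fix_interval` (s), `dpl` (m/day).
#' @export
linear_speed <- function(gps, active_threshold = 0.05) {
  if (nrow(gps) < 2) stop("at least 2 fixes required")
  dt <- diff(gps$timestamp)
  if (any(dt <= 0)) stop("duplicate or non-increasing fix timestamps")
  ds <- sqrt(diff(gps$x)^2 + diff(gps$y)^2)
  sp <- ds / dt
  active <- sp > active_threshold
  n_act <- sum(active)
  speed <- if (n_act) mean(sp[active]) else 0
  se <- if (n_act > 1) stats::sd(sp[active]) / sqrt(n_act) else NA_real_
  day <- floor(gps$timestamp[-nrow(gps)] / 86400)
  dpl <- mean(tapply(ds, day, sum))
  structure(list(speed_active = speed, se = se, n_segments = n_act,
                 fix_interval = stats::median(dt), dpl = dpl),
            class = "speed_estimate")
}

#' Rarefy a GPS track to a coarser fix interval
#'
#' Keeps every `(new_interval / native_interval)`-th fix from the first,
#' emulating a collar programmed at a coarser schedule. Straight-line path
#' length can only shrink under rarefaction (triangle inequality).
#'
#' @param gps A `gps_track`.
#' @param new_interval Target fix interval, seconds; must be a multiple of
#'   the native interval.
#' @return The rarefied `gps_track`.
#' @export
rarefy_track <- function(gps, new_interval) {
  native <- attr(gps, "fix_interval")
  if (is.null(native)) native <- min(diff(gps$timestamp))
  ratio <- new_interval / native
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("'new_interval' must be a multiple of the native fix interval")
  ratio <- as.integer(round(ratio))
  out <- gps[seq(1, nrow(gps), by = ratio), , drop = FALSE]
  attr(out, "fix_interval") <- new_interval
  out
}

#' Percent change in daily path length
#'
#' @param dpl Daily path length, m.
#' @param dpl_reference Reference DPL, m (> 0).
#' @return `100 * (dpl - dpl_reference) / dpl_reference`.
#' @export
dpl_percent_change <- function(dpl, dpl_reference) {
  if (any(dpl_reference <= 0)) stop("'dpl_reference' must be > 0")
  100 * (dpl - dpl_reference) / dpl_reference
}

#' Day range from speed while active
#'
#' `v = speed_active * moving_proportion * active_seconds_per_day / 1000`
#' km/day: the product of travel speed while active, the fraction of active
#' time spent moving, and the seconds of activity per day.
#'
#' @param speed_active Travel speed while active, m/s.
#' @param moving_proportion Fraction of active time spent in travel.
#' @param active_seconds_per_day Seconds of activity per day (e.g. activity
#'   level times 86400).
#' @return Day range, km/day.
#' @export
day_range <- function(speed_active, moving_proportion = 1,
                      active_seconds_per_day) {
  if (speed_active < 0 || moving_proportion < 0 || active_seconds_per_day < 0)
    stop("day range inputs must be non-negative")
  speed_active * moving_proportion * active_seconds_per_day / 1000
}

#' REM parameter bundle
#'
#' @param trapping_rate Contacts per camera-day.
#' @param day_range km/day.
#' @param r Effective detection radius, km.
#' @param theta Effective detection angle, radians, in (0, 2*pi].
#' @param cv_trapping_rate,cv_speed,cv_r,cv_activity Component CVs.
#' @param se_theta SE of the effective angle, radians.
#' @return A `rem_parameters` object.
#' @export
rem_parameters <- function(trapping_rate, day_range, r, theta,
                           cv_trapping_rate = 0, cv_speed = 0, cv_r = 0,
                           se_theta = 0, cv_activity = 0) {
  if (day_range <= 0 || r <= 0) stop("'day_range' and 'r' must be > 0")
  if (theta <= 0 || theta > 2 * pi) stop("'theta' must lie in (0, 2*pi]")
  if (trapping_rate < 0) stop("'trapping_rate' must be >= 0")
  structure(list(trapping_rate = trapping_rate, day_range = day_range,
                 r = r, theta = theta, cv_trapping_rate = cv_trapping_rate,
                 cv_speed = cv_speed, cv_r = cv_r, se_theta = se_theta,
                 cv_activity = cv_activity), class = "rem_parameters")
}

#' REM point density
#'
#' `D = (y/t) * pi / (v * r * (2 + theta))`, individuals per km^2.
#'
#' @param params A [rem_parameters()] object.
#' @return Density, individuals per km^2.
#' @export
rem_density <- function(params) {
  stopifnot(inherits(params, "rem_parameters"))
  params$trapping_rate * pi /
    (params$day_range * params$r * (2 + params$theta))
}

#' Delta-method variance and lognormal CI for REM
#'
#' `CV(D)^2 = CV(y/t)^2 + CV(v)^2 + CV(r)^2 + (SE(theta)/(2+theta))^2 +
#' CV(activity)^2` (activity enters through the day range when used). The
#' 95% CI is the lognormal interval with this CV.
#'
#' @param params A [rem_parameters()] with component CVs filled in.
#' @return A [density_estimate()].
#' @export
rem_variance <- function(params) {
  stopifnot(inherits(params, "rem_parameters"))
  d <- rem_density(params)
  comp <- c(trapping_rate = params$cv_trapping_rate,
            speed = params$cv_speed, r = params$cv_r,
            theta = params$se_theta / (2 + params$theta),
            activity = params$cv_activity)
  cv <- sqrt(sum(comp^2))
  cfac <- exp(1.96 * sqrt(log(1 + cv^2)))
  density_estimate(method = "REM", density = d, ci_low = d / cfac,
                   ci_high = d * cfac, cv = cv, components = comp,
                   estimate = params)
}

#' Rescale a REM density to other speed estimates
#'
#' Density is inversely proportional to speed with all other REM terms
#' fixed: `D(s) = baseline_density * baseline_speed / s`. Used to propagate
#' GPS fix-interval sensitivity of the speed estimate into density.
#'
#' @param baseline_density Baseline density, per km^2.
#' @param baseline_speed Speed that produced the baseline, m/s.
#' @param speeds Speeds to rescale to, m/s.
#' @param dpl,dpl_reference Optional DPLs (m) matching `speeds`, to include
#'   the percent change column.
#' @return Data frame with `speed`, `density` and optionally `dpl`,
#'   `dpl_pct_change`.
#' @export
speed_sensitivity <- function(baseline_density, baseline_speed, speeds,
                              dpl = NULL, dpl_reference = NULL) {
  if (baseline_speed <= 0) stop("'baseline_speed' must be > 0")
  out <- data.frame(speed = speeds,
                    density = baseline_density * baseline_speed / speeds)
  if (!is.null(dpl)) {
    out$dpl <- dpl
    if (!is.null(dpl_reference))
      out$dpl_pct_change <- dpl_percent_change(dpl, dpl_reference)
  }
  out
}

#' Full REM analysis of an observation set
#'
#' Contacts are identified per camera with the count-bookkeeping rule; the
#' detection zone (`r`, `theta`) is fitted by distance sampling on the
#' contact positions; effort is trigger-adjusted and matched to CTDS; speed
#' comes from the GPS track and the day range from speed times active time.
#'
#' @param obs An [observation_set()].
#' @param gps A `gps_track` for one individual (or a precomputed
#'   `speed_estimate` via `speed`).
#' @param activity_level Activity level used for the day range (and its CV).
#' @param cv_activity CV of the activity level.
#' @param moving_proportion Fraction of active time spent traveling.
#' @param max_distance Contact gating distance, m.
#' @param gap_reset_s Frameless-gap reset passed to [identify_contacts()].
#' @param contact_by Counting unit passed to [identify_contacts()].
#' @param speed Optional `speed_estimate` overriding `gps`.
#' @param r,theta Optional fixed detection-zone parameters (km, radians);
#'   when `NULL` they are fitted from the contact positions.
#' @param B Bootstrap resamples for the trapping rate.
#' @param seed Integer seed.
#' @return A `density_estimate` with the fitted components attached.
#' @export
rem_estimate <- function(obs, gps = NULL, activity_level = 1,
                         cv_activity = 0, moving_proportion = 1,
                         max_distance = 25, speed = NULL, r = NULL,
                         theta = NULL, B = 1000, seed = NULL,
                         gap_reset_s = Inf, contact_by = "burst") {
  stopifnot(inherits(obs, "observation_set"))
  obs <- filter_reactions(obs)
  ph_by_cam <- split(obs$photos, obs$photos$camera_id)
  dep <- obs$deployments
  contacts <- lapply(dep$camera_id, function(cid) {
    ph <- ph_by_cam[[cid]]
    if (is.null(ph)) ph <- obs$photos[0, , drop = FALSE]
    identify_contacts(ph, max_distance = max_distance,
                      gap_reset_s = gap_reset_s, by = contact_by)
  })
  y <- vapply(contacts, function(ct) as.numeric(ct$y), 0)
  T_days <- vapply(seq_len(nrow(dep)), function(i)
    trigger_adjusted_effort(dep[i, ], obs$photos)$T_k / 86400, 0)
  tr <- trapping_rate(y, T_days, B = B, seed = seed)
  cdist <- do.call(rbind, lapply(contacts, function(ct) ct$distances))
  half <- max(dep$half_angle)
  fit <- NULL
  if (is.null(r)) {
    counts <- distance_band_scheme()
    idx <- match_distance_band(cdist$lo, cdist$hi)
    counts$n <- tabulate(idx, nbins = nrow(counts))
    fit <- tryCatch(
      fit_detection_function(counts, detection_model("half-normal", 0),
                             w_left = 0, w = max_distance),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("too few contacts to fit the detection zone; ",
              "using the full gating radius for r")
      r <- max_distance / 1000
      cv_r <- 0
    } else {
      r <- fit$edr / 1000
      cv_r <- if (is.finite(fit$se_edr)) fit$se_edr / fit$edr else 0
    }
  } else cv_r <- 0
  angle <- NULL
  if (is.null(theta)) {
    bands <- unlist(lapply(contacts, function(ct) ct$angle_bands))
    angle <- if (length(bands) >= 10)
      fit_effective_angle(angle_band_to_radians(bands, half), half)
    else NULL
    if (is.null(angle)) {
      warning("fewer than 10 contact angles; ",
              "using the nominal field of view for theta")
      theta <- 2 * half
      se_theta <- 0
    } else {
      theta <- angle$effective_angle
      se_theta <- if (is.finite(angle$se)) angle$se else 0
    }
  } else se_theta <- 0
  if (is.null(speed) && !is.null(gps)) speed <- linear_speed(gps)
  if (is.null(speed)) stop("REM requires 'gps' fixes or a 'speed' estimate")
  v <- day_range(speed$speed_active, moving_proportion,
                 activity_level * 86400)
  cv_speed <- if (is.finite(speed$se) && speed$speed_active > 0)
    speed$se / speed$speed_active else 0
  params <- rem_parameters(tr$rate, v, r, theta,
                           cv_trapping_rate = ifelse(is.na(tr$cv), 0, tr$cv),
                           cv_speed = cv_speed, cv_r = cv_r,
                           se_theta = se_theta, cv_activity = cv_activity)
  est <- rem_variance(params)
  est$trapping <- tr
  est$speed <- speed
  est$detection_fit <- fit
  est$angle_fit <- angle
  est$y <- y
  est$T_days <- T_days
  est
}
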