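#' @title Camera-trap distance sampling (CTDS) density estimation
#' @description
#' Point-transect distance sampling adapted to camera frames: camera
#' operating time is trigger-adjusted (recovery dead time removed),
#' discretized into snapshot moments of length `t`, and the density of
#' individuals follows from the snapshot encounter rate, the average
#' detection probability inside the truncation annulus, and an availability
#' (activity-level) correction.
#' @name ctds_estimator
NULL

#' Trigger-adjusted operating effort
#'
#' Removes the recovery dead time accumulated after each trigger from the
#' deployment span: `T_k = span - n_triggers * recovery_s`, floored at zero.
#'
#' @param deployment One row of the deployment table.
#' @param photos Photo-table rows (the deployment's camera is selected by
#'   `camera_id`; blank-frame triggers count, they also cost recovery).
#' @return A list: `camera_id`, `T_k` (seconds), `n_triggers`.
#' @export
trigger_adjusted_effort <- function(deployment, photos) {
  span <- deployment$end - deployment$start
  if (span < 0) stop("negative deployment span")
  ph <- photos[photos$camera_id == deployment$camera_id, , drop = FALSE]
  n_trig <- length(unique(ph$trigger_id[!is.na(ph$trigger_id)]))
  T_k <- span - n_trig * deployment$recovery_s
  if (T_k < 0) {
    warning("recovery time exceeds deployment span; effort floored at 0")
    T_k <- 0
  }
  list(camera_id = deployment$camera_id, T_k = T_k, n_triggers = n_trig)
}

#' Snapshot-moment effort
#'
#' `e_k = theta * T_k / (2 * pi * t)`: operating seconds scaled by the
#' angular fraction of the circle covered and divided into snapshot moments
#' of length `t`.
#'
#' @param T_k Trigger-adjusted operating time, seconds.
#' @param theta Effective detection angle (full), radians, in `(0, 2*pi]`.
#' @param t Snapshot interval, seconds (0.5 by default, set by measured
#'   burst spacing).
#' @return Number of snapshot moments (dimensionless).
#' @export
snapshot_effort <- function(T_k, theta, t = 0.5) {
  if (t <= 0) stop("'t' must be > 0")
  if (any(theta < 0 | theta > 2 * pi)) stop("'theta' must lie in [0, 2*pi]")
  theta * T_k / (2 * pi * t)
}

#' Count snapshot observations
#'
#' Total individual tags whose band midpoint lies inside the truncation
#' annulus, summed over frames (each frame is one snapshot moment). Expects
#' a reaction-filtered stream.
#'
#' @param photos Photo-table rows for one camera (or any subset).
#' @param w_left,w Truncation annulus bounds, meters.
#' @return Integer count `n_k`.
#' @export
count_snapshot_observations <- function(photos, w_left = 0, w = 25) {
  tagged <- photos[!is.na(photos$animal_id), , drop = FALSE]
  if (!nrow(tagged)) return(0L)
  mid <- band_midpoint(tagged$distance_lo, tagged$distance_hi)
  sum(mid > w_left & mid <= w)
}

#' CTDS point density
#'
#' `D = [sum n_k / (pi * (w^2 - w_left^2) * sum e_k * P_hat)] / activity`,
#' reported per km^2. The annulus area replaces `pi * w^2` under left
#' truncation; dividing by the activity level corrects for animals being
#' unavailable to the cameras while inactive.
#'
#' @param n_k Snapshot observation counts per camera (vector or total).
#' @param e_k Snapshot-moment efforts per camera (vector or total).
#' @param P_hat Average detection probability inside the annulus, in (0, 1].
#' @param w_left,w Truncation annulus, meters.
#' @param activity_level Activity level, in (0, 1].
#' @return Density, individuals per km^2.
#' @export
ctds_density <- function(n_k, e_k, P_hat, w_left = 0, w,
                         activity_level = 1) {
  if (sum(e_k) <= 0) stop("zero snapshot effort")
  if (P_hat <= 0 || P_hat > 1) stop("'P_hat' must lie in (0, 1]")
  if (activity_level <= 0 || activity_level > 1)
    stop("'activity_level' must lie in (0, 1]")
  if (w <= w_left) stop("'w' must exceed 'w_left'")
  d_m2 <- sum(n_k) / (pi * (w^2 - w_left^2) * sum(e_k) * P_hat)
  d_m2 / activity_level * 1e6
}

#' Full CTDS analysis of an observation set
#'
#' Pipeline: reaction filtering, distance binning, truncation, detection-
#' function fitting with QAIC selection, effective-angle fitting, activity
#' estimation from group contacts, trigger-adjusted snapshot effort, and the
#' point density.
#'
#' @param obs An [observation_set()].
#' @param t Snapshot interval, seconds.
#' @param left Left truncation, m.
#' @param right_rule Right truncation: numeric distance or
#'   `"detection-prob-0.15"`.
#' @param models Candidate [detection_model()] list; a single model fixes
#'   the family (used by the bootstrap).
#' @param activity_level Optional fixed activity level (skips the kernel
#'   fit; e.g. 1 for an always-active simulation).
#' @param activity_adjust Kernel bandwidth multiplier for the activity fit.
#' @param theta Optional fixed effective angle (radians); when `NULL` it is
#'   fitted from the tagged angle bands.
#' @return A list of class `ctds_estimate` with the density, the component
#'   fits and the per-camera effort table.
#' @export
ctds_estimate <- function(obs, t = 0.5, left = 0,
                          right_rule = "detection-prob-0.15",
                          models = candidate_detection_models(),
                          activity_level = NULL, activity_adjust = 1.5,
                          theta = NULL) {
  stopifnot(inherits(obs, "observation_set"))
  obs <- filter_reactions(obs)
  bins <- bin_distances(obs$photos)
  trunc <- truncate_distances(bins, left = left, right_rule = right_rule)
  if (inherits(models, "detection_model")) models <- list(models)
  fits <- lapply(models, function(m)
    tryCatch(fit_detection_function(trunc$bins, m, w_left = trunc$w_left,
                                    w = trunc$w),
             error = function(e) NULL))
  ok <- Filter(Negate(is.null), fits)
  if (!length(ok)) stop("no detection model converged")
  most <- ok[[which.max(vapply(ok, function(f) f$npar, 0))]]
  c_hat <- tryCatch(estimate_overdispersion(most), error = function(e) 1)
  fit <- select_model(ok, c_hat)
  angle <- NULL
  if (is.null(theta)) {
    tagged <- obs$photos[!is.na(obs$photos$animal_id), , drop = FALSE]
    half <- obs$deployments$half_angle[
      match(tagged$camera_id, obs$deployments$camera_id)]
    abs_ang <- angle_band_to_radians(tagged$angle_band, half)
    angle <- fit_effective_angle(abs_ang, max(half))
    theta <- angle$effective_angle
  }
  act <- NULL
  if (is.null(activity_level)) {
    events <- times_to_radians(group_contact_times(obs))
    act <- fit_activity(events, adjust = activity_adjust)
    activity_level <- act$level
  }
  effort <- do.call(rbind, lapply(seq_len(nrow(obs$deployments)), function(i) {
    eff <- trigger_adjusted_effort(obs$deployments[i, ], obs$photos)
    ph <- obs$photos[obs$photos$camera_id == eff$camera_id, , drop = FALSE]
    data.frame(camera_id = eff$camera_id, T_k = eff$T_k,
               n_triggers = eff$n_triggers,
               e_k = snapshot_effort(eff$T_k, theta, t),
               n_k = count_snapshot_observations(ph, trunc$w_left, trunc$w),
               stringsAsFactors = FALSE)
  }))
  density <- ctds_density(effort$n_k, effort$e_k, fit$P_hat,
                          trunc$w_left, trunc$w, activity_level)
  structure(list(density = density, fit = fit, angle = angle,
                 theta = theta, activity = act,
                 activity_level = activity_level, effort = effort,
                 encounter_rate = sum(effort$n_k) / sum(effort$e_k),
                 c_hat = c_hat, t = t, w_left = trunc$w_left, w = trunc$w),
            class = "ctds_estimate")
}

#' @export
print.ctds_estimate <- function(x, ...) {
  cat("<ctds_estimate>\n")
  cat(sprintf("  D = %.3f /km^2   encounter rate = %.3g /snapshot\n",
              x$density, x$encounter_rate))
  cat(sprintf("  P_hat = %.3f  EDR = %.2f m  theta = %.3f rad  activity = %.3f\n",
              x$fit$P_hat, x$fit$edr, x$theta, x$activity_level))
  invisible(x)
}

#' Camera-level bootstrap for CTDS
#'
#' Resamples camera locations with replacement `B` times; each resample
#' refits the detection function (family fixed at the full-data winner),
#' recomputes the encounter rate and the activity level, and recomputes the
#' density. The CI is the 2.5/97.5 percentile interval; CV is SD/mean of the
#' resampled densities. Resamples with zero observations contribute a
#' density of zero (they are not dropped).
#'
#' @inheritParams ctds_estimate
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return A `density_estimate` (see [density_estimate()]).
#' @export
bootstrap_ctds <- function(obs, B = 1000, seed = NULL, t = 0.5, left = 0,
                           right_rule = "detection-prob-0.15",
                           models = candidate_detection_models(),
                           activity_level = NULL, activity_adjust = 1.5,
                           theta = NULL) {
  stopifnot(inherits(obs, "observation_set"))
  if (nrow(obs$deployments) < 2) stop("bootstrap needs at least 2 cameras")
  if (!is.null(seed)) set.seed(seed)
  full <- ctds_estimate(obs, t = t, left = left, right_rule = right_rule,
                        models = models, activity_level = activity_level,
                        activity_adjust = activity_adjust, theta = theta)
  obs_f <- filter_reactions(obs)
  cams <- obs_f$deployments$camera_id
  K <- length(cams)
  ph_by_cam <- split(obs_f$photos, obs_f$photos$camera_id)
  scheme <- distance_band_scheme()
  # per-camera summaries computed once; a resample is then sums over picks
  cam_e <- cam_n <- numeric(K)
  cam_bins <- matrix(0, nrow(scheme), K)
  cam_events <- vector("list", K)
  for (i in seq_len(K)) {
    ph <- ph_by_cam[[cams[i]]]
    if (is.null(ph)) ph <- obs_f$photos[0, , drop = FALSE]
    dep <- obs_f$deployments[obs_f$deployments$camera_id == cams[i], ]
    eff <- trigger_adjusted_effort(dep, ph)
    cam_e[i] <- snapshot_effort(eff$T_k, full$theta, t)
    cam_n[i] <- count_snapshot_observations(ph, full$w_left, full$w)
    cam_bins[, i] <- bin_distances(ph)$n
    cam_events[[i]] <- segment_group_contacts(ph)
  }
  fixed_act <- !is.null(activity_level)
  boot_d <- boot_p <- boot_er <- boot_act <- numeric(B)
  for (b in seq_len(B)) {
    pick <- sample.int(K, K, replace = TRUE)
    n_k <- cam_n[pick]
    e_k <- cam_e[pick]
    counts <- scheme
    counts$n <- rowSums(cam_bins[, pick, drop = FALSE])
    p_b <- full$fit$P_hat
    refit <- tryCatch(
      fit_detection_function(counts, full$fit$model, w_left = full$w_left,
                             w = full$w, n_starts = 2),
      error = function(e) NULL)
    if (!is.null(refit)) p_b <- refit$P_hat
    act_b <- if (fixed_act) activity_level else {
      ev <- unlist(cam_events[pick], use.names = FALSE)
      if (length(ev) >= 10)
        fit_activity(times_to_radians(ev), adjust = activity_adjust)$level
      else full$activity_level
    }
    boot_p[b] <- p_b
    boot_act[b] <- act_b
    boot_er[b] <- if (sum(e_k) > 0) sum(n_k) / sum(e_k) else 0
    boot_d[b] <- if (sum(n_k) == 0 || sum(e_k) == 0) 0 else
      ctds_density(n_k, e_k, p_b, full$w_left, full$w, act_b)
  }
  ci <- stats::quantile(boot_d, c(0.025, 0.975), names = FALSE)
  cv <- if (mean(boot_d) > 0) stats::sd(boot_d) / mean(boot_d) else NA_real_
  components <- c(
    detection = stats::sd(boot_p) / mean(boot_p),
    encounter = if (mean(boot_er) > 0)
      stats::sd(boot_er) / mean(boot_er) else NA_real_,
    activity = stats::sd(boot_act) / mean(boot_act))
  density_estimate(method = "CTDS", density = full$density,
                   ci_low = ci[1], ci_high = ci[2], cv = cv,
                   components = components, boot = boot_d, B = B,
                   estimate = full)
}

#' Density estimate container
#'
#' @param method `"CTDS"` or `"REM"`.
#' @param density Point estimate, individuals per km^2.
#' @param ci_low,ci_high 95% interval bounds.
#' @param cv Coefficient of variation of the estimate.
#' @param components Named vector of component CVs.
#' @param boot Optional vector of bootstrap densities.
#' @param B Number of bootstrap resamples used.
#' @param estimate Underlying full estimate object.
#' @return An object of class `density_estimate`.
#' @export
density_estimate <- function(method, density, ci_low = NA_real_,
                             ci_high = NA_real_, cv = NA_real_,
                             components = NULL, boot = NULL, B = NA_integer_,
                             estimate = NULL) {
  structure(list(method = method, density = density, ci_low = ci_low,
                 ci_high = ci_high, cv = cv, components = components,
                 boot = boot, B = B, estimate = estimate),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("<density_estimate> %s\n", x$method))
  cat(sprintf("  D = %.3f /km^2  95%% CI [%.3f, %.3f]  CV = %.3f\n",
              x$density, x$ci_low, x$ci_high, x$cv))
  if (!is.null(x$components))
    cat("  component CVs:",
        paste(names(x$components), signif(x$components, 3),
              sep = "=", collapse = "  "), "\n")
  invisible(x)
}
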