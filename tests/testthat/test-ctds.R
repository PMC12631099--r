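test_that("trigger-adjusted effort removes recovery dead time", {
  dep <- toy_deployments(1, span = 3600)
  ph <- do.call(rbind, lapply(1:10, function(i)
    toy_photo_rows("c01", 10 * i, sprintf("t%02d", i), dist = 3)))
  eff <- trigger_adjusted_effort(dep[1, ], ph)
  expect_equal(eff$T_k, 3600 - 10 * 10.35)
  expect_equal(eff$n_triggers, 10)
  # no triggers: full span
  expect_equal(trigger_adjusted_effort(dep[1, ], ph[0, ])$T_k, 3600)
  # pathological: deduction exceeds span, floored with a warning
  dep2 <- toy_deployments(1, span = 50)
  ph2 <- ph; ph2$timestamp <- seq_len(nrow(ph2))
  expect_warning(e2 <- trigger_adjusted_effort(dep2[1, ], ph2), "floored")
  expect_equal(e2$T_k, 0)
})

test_that("snapshot effort is the angular fraction of lattice moments", {
  expect_equal(snapshot_effort(10, 2 * pi, 0.5), 20)
  expect_equal(snapshot_effort(3600, 0.7, 0.5), 0.7 * 3600 / pi,
               tolerance = 1e-12)
  expect_equal(snapshot_effort(3600, 0.7, 0.5), 802.14, tolerance = 1e-4)
  expect_equal(snapshot_effort(3600, 0, 0.5), 0)
  expect_error(snapshot_effort(10, 0.7, 0), "'t'")
})

test_that("snapshot observation counts respect the truncation annulus", {
  ph <- rbind(toy_photo_rows("c01", 1 + (0:2) * 0.49, "t1",
                             dist = c(3, 4, 5), animal = paste0("a", 1:3)),
              toy_photo_rows("c01", 20 + (0:2) * 0.49, "t2",
                             dist = c(3, 4, 5), animal = paste0("a", 1:3)))
  expect_equal(count_snapshot_observations(ph, 0, 25), 6)
  expect_equal(count_snapshot_observations(ph, 10, 25), 0)
  mixed <- toy_photo_rows("c01", 1 + (0:2) * 0.49, "t1",
                          dist = c(1.7, 12.4, 24.4),
                          animal = paste0("a", 1:3))
  # band midpoints 1.75, 12.5, 24.5; annulus (2, 24] keeps only 12.5
  expect_equal(count_snapshot_observations(mixed, 2, 24), 1)
})

test_that("the point density reconstructs printed survey parameters", {
  # survey area 1: encounter rate 0.00032, w 24, P 0.24, activity 0.26
  d1 <- ctds_density(0.00032, 1, 0.24, 0, 24, 0.26)
  expect_lt(abs(d1 / 2.82 - 1), 0.015)
  # survey area 2 printed inputs are 2-significant-figure rounded; the
  # reconstruction lands within the implied rounding envelope
  d2 <- ctds_density(0.00019, 1, 0.11, 0, 24, 0.33)
  expect_lt(abs(d2 / 2.97 - 1), 0.05)
  # degenerate and inverse checks
  expect_equal(ctds_density(0, 10, 0.5, 0, 24, 0.5), 0)
  expect_equal(ctds_density(pi * 24^2 * 1e-6, 1, 1, 0, 24, 1), 1)
  expect_error(ctds_density(1, 0, 0.5, 0, 24, 1), "zero snapshot effort")
  expect_error(ctds_density(1, 1, 1.5, 0, 24, 1), "P_hat")
})

test_that("density is invariant to splitting a camera in two", {
  set.seed(41)
  truth <- solitary_world(32, 2, 0.22, seed = 41)
  tk <- simulate_movement(truth, 86400, seed = 41)
  deps <- make_deployments(12, 2, 86400, recovery_s = 0,
                           burst_interval_s = 0.5, seed = 41)
  obs <- simulate_detections(tk, deps, detection_halfnormal(
    8, g_trigger = function(r) rep(1, length(r))), seed = 42)
  est <- ctds_estimate(obs, models = detection_model("half-normal", 0),
                       activity_level = 1, theta = 0.74, right_rule = 24)
  # split camera c01 at mid-span into two co-located deployments
  dep2 <- obs$deployments
  first <- dep2[dep2$camera_id == "c01", ]
  first$end <- 43200
  second <- first; second$camera_id <- "c01b"
  second$start <- 43200; second$end <- 86400
  dep2 <- rbind(dep2[dep2$camera_id != "c01", ], first, second)
  ph2 <- obs$photos
  move <- ph2$camera_id == "c01" & ph2$timestamp >= 43200
  ph2$camera_id[move] <- "c01b"
  obs2 <- observation_set(ph2, dep2, validate = FALSE)
  est2 <- ctds_estimate(obs2, models = detection_model("half-normal", 0),
                        activity_level = 1, theta = 0.74, right_rule = 24)
  expect_equal(est2$density, est$density, tolerance = 1e-9)
})

test_that("halving t doubles effort and halves density at fixed counts", {
  e1 <- snapshot_effort(1000, 0.7, 0.5)
  e2 <- snapshot_effort(1000, 0.7, 0.25)
  expect_equal(e2, 2 * e1)
  expect_equal(ctds_density(50, e2, 0.3, 0, 24, 1),
               ctds_density(50, e1, 0.3, 0, 24, 1) / 2)
})

test_that("camera bootstrap is seeded and registers zero resamples", {
  set.seed(43)
  truth <- solitary_world(16, 2, 0.22, seed = 43)
  tk <- simulate_movement(truth, 43200, seed = 43)
  deps <- make_deployments(5, 2, 43200, seed = 43)
  obs <- simulate_detections(tk, deps, detection_halfnormal(8), seed = 44)
  b1 <- bootstrap_ctds(obs, B = 60, seed = 9,
                       models = detection_model("half-normal", 0),
                       activity_level = 1, theta = 0.74, right_rule = 24)
  b2 <- bootstrap_ctds(obs, B = 60, seed = 9,
                       models = detection_model("half-normal", 0),
                       activity_level = 1, theta = 0.74, right_rule = 24)
  expect_identical(b1$boot, b2$boot)
  expect_identical(c(b1$ci_low, b1$ci_high), c(b2$ci_low, b2$ci_high))
  expect_true(b1$ci_low <= b1$density && b1$density <= b1$ci_high)
  # cameras with no observations exist, so some resamples must hit all-empty
  # camera sets and be recorded as zero densities, not dropped
  if (any(tapply(!is.na(obs$photos$animal_id), obs$photos$camera_id,
                 sum) == 0))
    expect_true(min(b1$boot) == 0)
  expect_error(bootstrap_ctds(
    observation_set(obs$photos[obs$photos$camera_id == "c01", ],
                    obs$deployments[1, ], validate = FALSE), B = 10),
    "at least 2 cameras")
})
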