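test_that("contact bookkeeping follows the count rules", {
  mk <- function(counts, dists, times) {
    do.call(rbind, lapply(seq_along(counts), function(i) {
      if (counts[i] == 0)
        toy_photo_rows("c01", times[i], sprintf("t%d", i), dist = NA)
      else
        toy_photo_rows("c01", times[i], sprintf("t%d", i),
                       dist = rep(dists[i], counts[i]),
                       animal = paste0("a", seq_len(counts[i])))
    }))
  }
  # counts [1,1,0,1]: leave-and-re-enter after an empty frame -> 2
  expect_equal(identify_contacts(mk(c(1, 1, 0, 1), c(3, 3, NA, 3), 1:4))$y, 2)
  # counts [1,2,2]: increment bookkeeping, 1 then +1 -> 2
  expect_equal(identify_contacts(mk(c(1, 2, 2), c(3, 3, 3), 1:3))$y, 2)
  # a tag beyond the gate does not open a contact; the first qualifying
  # frame does (gate 10 m: 12.4 m band then 8 m band -> one contact at t2)
  far_near <- mk(c(1, 1), c(12.4, 8), 1:2)
  got <- identify_contacts(far_near, max_distance = 10)
  expect_equal(got$y, 1)
  expect_equal(got$times, 2)
  # unsorted stream errors
  bad <- mk(c(1, 1), c(3, 3), c(5, 1))
  bad <- bad[order(bad$trigger_id), ]
  expect_error(identify_contacts(bad), "not time-sorted")
  # frameless-gap reset: same counts, long silence in between
  gap <- mk(c(1, 1), c(3, 3), c(1, 500))
  expect_equal(identify_contacts(gap)$y, 1)
  expect_equal(identify_contacts(gap, gap_reset_s = 60)$y, 2)
})

test_that("trapping rate pools trigger-matched effort", {
  tr <- trapping_rate(c(3, 1), c(2, 2), B = 200, seed = 1)
  expect_equal(tr$rate, 1)
  expect_false(tr$all_zero)
  z <- trapping_rate(c(0, 0), c(2, 2), B = 50, seed = 1)
  expect_true(z$all_zero)
  expect_true(is.na(z$cv))
  t2 <- trapping_rate(c(3, 1), c(2, 2), B = 200, seed = 1)
  expect_identical(tr$boot, t2$boot)
})

test_that("linear speed and DPL follow straight-line geometry", {
  g <- structure(data.frame(timestamp = c(0, 60), x = c(0, 60), y = c(0, 0)),
                 class = c("gps_track", "data.frame"), fix_interval = 60)
  sp <- linear_speed(g)
  expect_equal(sp$speed_active, 1)
  expect_equal(sp$dpl, 60)
  # stationary
  gs <- structure(data.frame(timestamp = c(0, 60, 120), x = 0, y = 0),
                  class = c("gps_track", "data.frame"), fix_interval = 60)
  expect_equal(linear_speed(gs)$speed_active, 0)
  # right-angle path at coarser fixes: 1.0 m/s becomes 1/sqrt(2)
  g1 <- structure(data.frame(timestamp = c(0, 3600, 7200),
                             x = c(0, 3600, 3600), y = c(0, 0, 3600)),
                  class = c("gps_track", "data.frame"), fix_interval = 3600)
  expect_equal(linear_speed(g1)$speed_active, 1)
  g2 <- rarefy_track(g1, 7200)
  expect_equal(linear_speed(g2)$speed_active, sqrt(2) / 2, tolerance = 1e-9)
  # duplicate timestamps error
  gd <- data.frame(timestamp = c(0, 0), x = c(0, 1), y = 0)
  expect_error(linear_speed(gd), "non-increasing")
})

test_that("rarefaction keeps every k-th fix and never lengthens the path", {
  g <- structure(data.frame(timestamp = seq(0, 13 * 3600, by = 3600),
                            x = stats::rnorm(14), y = stats::rnorm(14)),
                 class = c("gps_track", "data.frame"), fix_interval = 3600)
  expect_equal(nrow(rarefy_track(g, 3600)), 14)
  expect_equal(nrow(rarefy_track(g, 7200)), 7)
  expect_error(rarefy_track(g, 5400), "multiple")
  # DPL non-increasing across a chain of coarser intervals, every track
  set.seed(51)
  for (rep in 1:5) {
    tr <- solitary_world(1, 2, 0.5, seed = 60 + rep)
    tk <- simulate_movement(tr, 14400, seed = 60 + rep)
    gg <- simulate_gps_track(tk[[1]], 60, window = c(0, 86400))
    dpls <- vapply(c(60, 300, 900, 3600), function(iv)
      linear_speed(rarefy_track(gg, iv))$dpl, 0)
    expect_true(all(diff(dpls) <= 1e-9))
  }
})

test_that("DPL percent change reproduces the published fix-time table", {
  expect_equal(round(dpl_percent_change(10860, 3588), 1), 202.7)
  expect_equal(round(dpl_percent_change(7303, 3588), 1), 103.5)
  expect_equal(round(dpl_percent_change(2713, 3588), 1), -24.4)
  expect_equal(dpl_percent_change(3588, 3588), 0)
  expect_error(dpl_percent_change(1, 0), "dpl_reference")
})

test_that("day range composes speed, movement share and active time", {
  expect_equal(day_range(1.38, 1, 3551), 4.9, tolerance = 1e-3)
  expect_equal(day_range(1.38, 0, 3551), 0)
  expect_equal(day_range(2.76, 0.5, 3551), day_range(1.38, 1, 3551))
})

test_that("REM density and variance follow the formula", {
  p <- rem_parameters(1, 1, 0.01, 1e-9)
  expect_equal(rem_density(p), pi / 0.02, tolerance = 1e-6)  # 157.08
  expect_equal(rem_density(rem_parameters(0, 1, 0.01, 0.5)), 0)
  d1 <- rem_density(rem_parameters(1, 1, 0.01, 0.5))
  expect_equal(rem_density(rem_parameters(1, 2, 0.01, 0.5)), d1 / 2)
  expect_error(rem_parameters(1, 0, 0.01, 0.5), "day_range")
  expect_error(rem_parameters(1, 1, 0.01, 7), "theta")

  v1 <- rem_variance(rem_parameters(1, 4.9, 0.012, 0.74,
                                    cv_trapping_rate = 0.3))
  expect_equal(v1$cv, 0.3)
  v2 <- rem_variance(rem_parameters(1, 4.9, 0.012, 0.74,
                                    cv_trapping_rate = 0.3, cv_speed = 0.4))
  expect_equal(v2$cv, 0.5)
  expect_true(v2$ci_low < v2$density && v2$density < v2$ci_high)

  # feeding the analytic expected rate back through the model returns the
  # input density exactly
  D <- 3.7; v <- 4.9; r <- 0.012; th <- 0.74
  rate <- expected_trapping_rate(D, v, r, th)
  expect_equal(rem_density(rem_parameters(rate, v, r, th)), D,
               tolerance = 1e-12)
})

test_that("speed rescaling reproduces the published sensitivity table", {
  speeds <- c(4.170, 3.770, 2.800, 2.530, 2.020, 1.670, 1.380, 1.040)
  s1_printed <- c(0.422, 0.467, 0.629, 0.696, 0.872, 1.050, 1.280, 1.690)
  s2_printed <- c(0.309, 0.342, 0.461, 0.510, 0.639, 0.772, 0.940, 1.240)
  s1 <- speed_sensitivity(1.28, 1.38, speeds)
  s2 <- speed_sensitivity(0.94, 1.38, speeds)
  expect_true(all(abs(s1$density / s1_printed - 1) < 0.01))
  expect_true(all(abs(s2$density / s2_printed - 1) < 0.01))
  # identity at the baseline speed
  expect_equal(speed_sensitivity(1.28, 1.38, 1.38)$density, 1.28)
  # DPL columns propagate
  tab <- speed_sensitivity(1.28, 1.38, c(2.8, 1.04),
                           dpl = c(7303, 2713), dpl_reference = 3588)
  expect_equal(round(tab$dpl_pct_change, 1), c(103.5, -24.4))
})

test_that("the full REM pipeline wires its components together", {
  set.seed(52)
  truth <- solitary_world(16, 2, 0.5, seed = 52)
  tk <- simulate_movement(truth, 86400, seed = 52)
  deps <- make_deployments(8, 2, 86400, max_tag_distance = 15, seed = 52)
  obs <- simulate_detections(tk, deps, detection_spec(), seed = 53)
  gps <- simulate_gps_track(tk[[1]], 10, window = c(0, 86400))
  est <- rem_estimate(obs, gps = gps, activity_level = 1, B = 100, seed = 7)
  expect_s3_class(est, "density_estimate")
  expect_gt(est$density, 0)
  expect_true(est$ci_low <= est$density && est$density <= est$ci_high)
  expect_equal(length(est$y), nrow(deps))
  # short-interval straight-line speed sits just under the step speed
  # (mild tortuosity over 10 s segments)
  expect_equal(est$speed$speed_active, 0.5, tolerance = 0.05)
  expect_error(rem_estimate(obs, activity_level = 1), "requires 'gps'")
})
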