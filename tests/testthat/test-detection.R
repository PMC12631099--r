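test_that("uniform detection is the degenerate closed form", {
  bins <- data.frame(lo = c(0, 10), hi = c(10, 20), n = c(25, 75))
  fit <- fit_detection_function(bins, detection_model("uniform", 0), w = 20)
  expect_equal(fit$P_hat, 1)
  expect_equal(fit$edr, 20)
})

test_that("half-normal P and EDR match the closed form", {
  m <- detection_model("half-normal", 0)
  dp <- detection_probability(m, c(sigma = 5), w_left = 0, w = 24)
  expect_equal(dp$P, (2 * 25 / 576) * (1 - exp(-576 / 50)), tolerance = 1e-6)
  expect_equal(dp$P, 0.0868, tolerance = 5e-4)
  expect_equal(dp$edr, sqrt(50), tolerance = 1e-5)
})

test_that("binned MLE recovers the generating scale at large n", {
  set.seed(21)
  bins <- sample_hn_point_distances(20000, sigma = 8, w = 24)
  fit <- fit_detection_function(bins, detection_model("half-normal", 0),
                                w = 24)
  expect_lt(abs(fit$params[["sigma"]] / 8 - 1), 0.03)
  # SE machinery produces a finite, sane EDR standard error
  expect_true(is.finite(fit$se_edr))
  expect_lt(fit$se_edr / fit$edr, 0.05)
})

test_that("adjustment series improve or match the base likelihood", {
  set.seed(22)
  bins <- sample_hn_point_distances(3000, sigma = 7, w = 24)
  base <- fit_detection_function(bins, detection_model("half-normal", 0),
                                 w = 24)
  adj <- fit_detection_function(bins, detection_model("half-normal", 1),
                                w = 24)
  expect_gte(adj$loglik, base$loglik - 1e-6)
  u2 <- fit_detection_function(bins, detection_model("uniform", 2), w = 24)
  expect_true(is.finite(u2$loglik))
})

test_that("truncation rules follow the detection-probability floor", {
  set.seed(23)
  bins <- sample_hn_point_distances(4000, sigma = 8, w = 25)
  # fixed truncation window
  tf <- truncate_distances(bins, left = 2, right_rule = 24)
  expect_true(all(tf$bins$lo >= 2 & tf$bins$hi <= 24))
  expect_equal(tf$w, 24)
  # identity
  ti <- truncate_distances(bins, left = 0, right_rule = 25)
  expect_equal(sum(ti$bins$n), sum(bins$n))
  # iterative rule: final g(w) >= 0.15 while one bin further would fail
  tr <- truncate_distances(bins, left = 0)
  expect_gte(predict_g(tr$fit, tr$w), 0.15)
  expect_lt(tr$w, 25)
  expect_lt(predict_g(tr$fit, tr$w + 1), 0.15)
  # everything truncated -> error
  empty <- bins; empty$n[] <- 0
  expect_error(truncate_distances(empty, left = 0, right_rule = 24),
               "all data truncated")
})

test_that("overdispersion and QAIC compose correctly", {
  set.seed(24)
  bins <- sample_hn_point_distances(2000, sigma = 8, w = 24)
  fit <- fit_detection_function(bins, detection_model("half-normal", 0),
                                w = 24)
  c1 <- estimate_overdispersion(fit)
  expect_gte(c1, 1)
  # duplicating every observation doubles chi-square exactly
  bins2 <- bins; bins2$n <- bins2$n * 2L
  fit2 <- fit_detection_function(bins2, detection_model("half-normal", 0),
                                 w = 24)
  c2 <- estimate_overdispersion(fit2)
  if (c1 > 1) expect_equal(c2 / c1, 2, tolerance = 0.05)
  # independent multinomial data stay near c = 1 over replicates
  cs <- replicate(10, {
    b <- sample_hn_point_distances(1500, sigma = 8, w = 24)
    estimate_overdispersion(
      fit_detection_function(b, detection_model("half-normal", 0), w = 24))
  })
  expect_lt(mean(cs), 1.5)

  # QAIC arithmetic on stub fits
  stub <- structure(list(loglik = -100, npar = 2), class = "detection_fit")
  expect_equal(qaic(stub, 1), 200 + 2 * 3)
  expect_equal(qaic(stub, 4), 50 + 6)
  stub3 <- structure(list(loglik = -100, npar = 3), class = "detection_fit")
  expect_equal(qaic(stub3, 1) - qaic(stub, 1), 2)
  expect_error(qaic(stub, 0.5), "c_hat")
})

test_that("QAIC selection prefers the generating family", {
  # single candidate comes straight back
  set.seed(25)
  bins <- sample_hn_point_distances(2000, sigma = 8, w = 24)
  only <- fit_detection_function(bins, detection_model("half-normal", 0),
                                 w = 24)
  expect_identical(select_model(list(only))$model$family, "half-normal")

  # equal QAIC resolves to fewer parameters
  a <- structure(list(loglik = -100, npar = 2L,
                      model = detection_model("hazard-rate", 0)),
                 class = "detection_fit")
  b <- structure(list(loglik = -99, npar = 3L,
                      model = detection_model("hazard-rate", 1)),
                 class = "detection_fit")
  expect_equal(select_model(list(b, a))$npar, 2)

  # hazard-rate-generated distances: hazard-rate family usually wins
  r_grid <- seq(0.005, 24, by = 0.005)
  g_hr <- 1 - exp(-(r_grid / 7)^(-3))
  cdf <- cumsum(r_grid * g_hr); cdf <- cdf / max(cdf)
  scheme <- distance_band_scheme()
  set.seed(26)
  wins <- 0L
  reps <- 20
  for (i in seq_len(reps)) {
    draws <- stats::approx(cdf, r_grid, stats::runif(1500), rule = 2)$y
    b <- groupdens:::distance_to_band(pmax(draws, 1e-3))
    counts <- scheme
    counts$n <- tabulate(groupdens:::match_distance_band(b$lo, b$hi),
                         nbins = nrow(scheme))
    counts <- counts[counts$hi <= 24, ]
    fits <- lapply(candidate_detection_models(), function(m)
      tryCatch(fit_detection_function(counts, m, w = 24),
               error = function(e) NULL))
    ok <- Filter(Negate(is.null), fits)
    most <- ok[[which.max(vapply(ok, function(f) f$npar, 0))]]
    ch <- tryCatch(estimate_overdispersion(most), error = function(e) 1)
    best <- select_model(ok, ch)
    if (best$model$family == "hazard-rate") wins <- wins + 1L
  }
  expect_gte(wins / reps, 0.8)
})

test_that("effective angle fits recover the closed form", {
  h <- 0.4
  # uniform angles, no angular falloff: theta approaches the full FOV
  set.seed(27)
  af <- fit_effective_angle(stats::runif(4000, 0, h), h)
  expect_equal(af$effective_angle, 2 * h, tolerance = 0.02)
  # concentrated angles: theta collapses
  af0 <- fit_effective_angle(abs(stats::rnorm(400, 0, 0.01)), h)
  expect_lt(af0$effective_angle, 0.1)
  # half-normal falloff sigma_a = 0.25: closed-form recovery within 5%
  sa <- 0.25
  cand <- stats::runif(60000, 0, h)
  ang <- cand[stats::runif(60000) < exp(-cand^2 / (2 * sa^2))][1:4000]
  af1 <- fit_effective_angle(ang, h)
  th_true <- 2 * sqrt(2 * sa^2 * (1 - exp(-h^2 / (2 * sa^2))))
  expect_lt(abs(af1$effective_angle / th_true - 1), 0.05)
  expect_true(is.finite(af1$se))
  expect_error(fit_effective_angle(stats::runif(5, 0, h), h), "at least 10")
})

test_that("detection probability is monotone in w with the analytic limit", {
  m <- detection_model("half-normal", 0)
  ws <- seq(6, 60, by = 2)
  P <- vapply(ws, function(w)
    detection_probability(m, c(sigma = 5), w = w)$P, 0)
  expect_true(all(diff(P) < 0))
  # EDR tends to sigma * sqrt(2) as w grows
  edr_inf <- detection_probability(m, c(sigma = 5), w = 200)$edr
  expect_equal(edr_inf, 5 * sqrt(2), tolerance = 1e-4)
})
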