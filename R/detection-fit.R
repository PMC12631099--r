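#' @title Point-transect detection functions for binned camera distances
#' @description
#' Maximum-likelihood fitting of detection functions to binned distances
#' under point-transect geometry (availability proportional to distance), a
#' detection-probability right-truncation rule, chi-square overdispersion,
#' QAIC model selection and an effective detection angle fitted to absolute
#' angles. All inputs are banded, so the likelihood is the multinomial
#' interval likelihood with bin probabilities proportional to the integral
#' of `r*g(r)` over each bin.
#' @name detection_fitting
NULL

#' Detection model specification
#'
#' @param family `"half-normal"` (Hermite adjustments), `"hazard-rate"` or
#'   `"uniform"` (cosine adjustments).
#' @param n_adjust Number of adjustment terms.
#' @return A `detection_model` object.
#' @export
detection_model <- function(family = c("half-normal", "hazard-rate", "uniform"),
                            n_adjust = 0) {
  family <- match.arg(family)
  limits <- c("half-normal" = 1, "hazard-rate" = 2, "uniform" = 2)
  if (n_adjust < 0 || n_adjust > limits[family])
    stop(sprintf("'%s' supports at most %d adjustment terms", family,
                 limits[family]))
  structure(list(family = family, n_adjust = as.integer(n_adjust)),
            class = "detection_model")
}

#' The candidate model set
#'
#' Half-normal with 0/1 Hermite terms, uniform with 1/2 cosine terms and
#' hazard-rate with 0/1/2 cosine terms.
#'
#' @return List of [detection_model()] objects.
#' @export
candidate_detection_models <- function() {
  list(detection_model("half-normal", 0), detection_model("half-normal", 1),
       detection_model("uniform", 1), detection_model("uniform", 2),
       detection_model("hazard-rate", 0), detection_model("hazard-rate", 1),
       detection_model("hazard-rate", 2))
}

n_model_params <- function(model) {
  base <- switch(model$family, "half-normal" = 1L, "hazard-rate" = 2L,
                 "uniform" = 0L)
  base + model$n_adjust
}

# par: optimizer scale -- log(sigma), log(b) (hazard), adjustment coefs
# returns g(r) standardized to g(0) = 1 and clipped to [0, 1]
eval_g <- function(model, par, r, w) {
  fam <- model$family
  na <- model$n_adjust
  if (fam == "half-normal") {
    sigma <- exp(par[1])
    key <- function(x) exp(-x^2 / (2 * sigma^2))
    adj <- if (na >= 1) function(x) {
      z <- x / sigma
      cbind(z^4 - 6 * z^2 + 3)  # Hermite H4
    } else NULL
    a <- if (na >= 1) par[2] else numeric(0)
  } else if (fam == "hazard-rate") {
    sigma <- exp(par[1]); b <- exp(par[2])
    key <- function(x) 1 - exp(-pmax(x / sigma, 1e-12)^(-b))
    adj <- if (na >= 1) function(x) {
      xs <- x / w
      m <- sapply(2:(1 + na), function(j) cos(j * pi * xs))
      if (is.null(dim(m))) m <- matrix(m, ncol = na)
      m
    } else NULL
    a <- if (na >= 1) par[3:(2 + na)] else numeric(0)
  } else {
    key <- function(x) rep(1, length(x))
    adj <- if (na >= 1) function(x) {
      xs <- x / w
      m <- sapply(seq_len(na), function(j) cos(j * pi * xs))
      if (is.null(dim(m))) m <- matrix(m, ncol = na)
      m
    } else NULL
    a <- if (na >= 1) par[seq_len(na)] else numeric(0)
  }
  series <- function(x) {
    s <- rep(1, length(x))
    if (length(a)) s <- s + drop(adj(x) %*% a)
    s
  }
  norm0 <- key(0) * series(0)
  if (!is.finite(norm0) || norm0 <= 0) return(rep(NaN, length(r)))
  g <- key(r) * series(r) / norm0
  pmin(pmax(g, 0), 1)
}

# integral of r*g(r) over each bin, composite Simpson with `nodes` points
bin_rg_integrals <- function(model, par, bins, w, nodes = 33) {
  stopifnot(nodes %% 2 == 1)
  nb <- nrow(bins)
  u <- seq(0, 1, length.out = nodes)
  xs <- outer(bins$hi - bins$lo, u) + bins$lo        # nb x nodes
  gv <- eval_g(model, par, as.vector(xs), w)
  if (anyNA(gv)) return(rep(NaN, nb))
  fv <- matrix(as.vector(xs) * gv, nb, nodes)
  wts <- c(1, rep(c(4, 2), (nodes - 3) / 2), 4, 1)
  h <- (bins$hi - bins$lo) / (nodes - 1)
  (fv %*% wts) * h / 3
}

# average detection probability over the annulus (w_left, w]
integral_P <- function(model, par, w_left, w, nodes = 513) {
  seg <- data.frame(lo = w_left, hi = w)
  int <- bin_rg_integrals(model, par, seg, w, nodes = nodes)
  2 * int / (w^2 - w_left^2)
}

#' Fit a point-transect detection function to binned distances
#'
#' Maximizes the multinomial interval likelihood with bin probabilities
#' proportional to the integral of `r*g(r)` over each bin inside the
#' truncation annulus `(w_left, w]`. The average detection probability is
#' `P = 2 * int r g(r) dr / (w^2 - w_left^2)` and the effective detection
#' radius is `rho = sqrt(P * (w^2 - w_left^2) + w_left^2)`.
#'
#' @param bins Data frame with columns `lo`, `hi` (meters) and `n` (tag
#'   counts per band); zero-count bands inside the annulus should be present.
#' @param model A [detection_model()].
#' @param w_left,w Left and right truncation distances (m). `w` defaults to
#'   the largest band edge.
#' @param n_starts Multistart points for the scale parameter (log grid).
#' @return A `detection_fit` object: model, fitted parameters (`sigma`, `b`,
#'   adjustment coefficients), `loglik`, `n_obs`, `P_hat`, `edr`, `se_edr`,
#'   per-bin expected counts, convergence and monotonicity flags.
#' @export
fit_detection_function <- function(bins, model, w_left = 0, w = NULL,
                                   n_starts = 5) {
  stopifnot(inherits(model, "detection_model"))
  if (is.null(w)) w <- max(bins$hi)
  bins <- bins[bins$lo >= w_left - 1e-9 & bins$hi <= w + 1e-9, , drop = FALSE]
  bins <- bins[order(bins$lo), , drop = FALSE]
  npar <- n_model_params(model)
  if (sum(bins$n > 0) < npar + 1)
    stop("too few non-empty bins for the number of parameters")
  n_obs <- sum(bins$n)
  negll <- function(par) {
    ints <- bin_rg_integrals(model, par, bins, w)
    if (anyNA(ints) || any(!is.finite(ints)) || sum(ints) <= 0) return(1e10)
    p <- ints / sum(ints)
    if (any(p <= 0 & bins$n > 0)) return(1e10)
    -sum(bins$n[bins$n > 0] * log(p[bins$n > 0]))
  }
  if (npar == 0) {
    par <- numeric(0)
    ll <- -negll(par)
    conv <- 0L
    hess <- matrix(numeric(0), 0, 0)
  } else {
    mid <- (bins$lo + bins$hi) / 2
    s0 <- sqrt(sum(bins$n * mid^2) / max(n_obs, 1)) / sqrt(2)
    s_grid <- exp(seq(log(0.3 * s0), log(3 * s0), length.out = n_starts))
    best <- NULL
    for (s in s_grid) {
      start <- switch(model$family,
        "half-normal" = c(log(s), rep(0, model$n_adjust)),
        "hazard-rate" = c(log(s), log(2), rep(0, model$n_adjust)),
        "uniform" = rep(0, model$n_adjust))
      if (model$family == "uniform" && s != s_grid[1]) next
      opt <- tryCatch(
        if (length(start) == 1)
          stats::optim(start, negll, method = "Brent",
                       lower = start - 8, upper = start + 8,
                       control = list(maxit = 3000))
        else
          stats::optim(start, negll, method = "Nelder-Mead",
                       control = list(maxit = 3000, reltol = 1e-10)),
        error = function(e) NULL)
      if (is.null(opt)) next
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (is.null(best) || best$value >= 1e10)
      stop("detection function optimization failed to converge (",
           model$family, ", ", model$n_adjust, " adjustments)")
    par <- best$par
    ll <- -best$value
    conv <- best$convergence
    hess <- tryCatch(stats::optimHess(par, negll), error = function(e) NULL)
  }
  P_hat <- as.numeric(integral_P(model, par, w_left, w))
  edr <- sqrt(P_hat * (w^2 - w_left^2) + w_left^2)
  se_edr <- NA_real_
  if (npar > 0 && !is.null(hess)) {
    vc <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(vc)) && all(diag(vc) >= 0)) {
      grad <- numeric(npar)
      for (i in seq_len(npar)) {
        dp <- par; dm <- par
        h <- max(1e-5, abs(par[i]) * 1e-5)
        dp[i] <- dp[i] + h; dm[i] <- dm[i] - h
        fp <- sqrt(integral_P(model, dp, w_left, w) * (w^2 - w_left^2) + w_left^2)
        fm <- sqrt(integral_P(model, dm, w_left, w) * (w^2 - w_left^2) + w_left^2)
        grad[i] <- (fp - fm) / (2 * h)
      }
      v <- drop(t(grad) %*% vc %*% grad)
      if (is.finite(v) && v >= 0) se_edr <- sqrt(v)
    }
  }
  ints <- bin_rg_integrals(model, par, bins, w)
  bins$expected <- n_obs * ints / sum(ints)
  grid <- seq(max(w_left, 1e-6), w, length.out = 200)
  gg <- eval_g(model, par, grid, w)
  monotone_warn <- any(diff(gg) > 1e-6)
  params <- switch(model$family,
    "half-normal" = c(sigma = exp(par[1]),
                      if (model$n_adjust) stats::setNames(par[-1],
                        paste0("adj", seq_len(model$n_adjust)))),
    "hazard-rate" = c(sigma = exp(par[1]), b = exp(par[2]),
                      if (model$n_adjust) stats::setNames(par[-(1:2)],
                        paste0("adj", seq_len(model$n_adjust)))),
    "uniform" = if (model$n_adjust) stats::setNames(par,
                  paste0("adj", seq_len(model$n_adjust))) else numeric(0))
  structure(list(model = model, par = par, params = params, loglik = ll,
                 n_obs = n_obs, P_hat = P_hat, edr = edr, se_edr = se_edr,
                 w_left = w_left, w = w, bins = bins, npar = npar,
                 convergence = conv, monotone_warning = monotone_warn),
            class = "detection_fit")
}

#' @export
print.detection_fit <- function(x, ...) {
  cat(sprintf("<detection_fit> %s, %d adjustment(s)\n", x$model$family,
              x$model$n_adjust))
  cat(sprintf("  truncation (%g, %g] m   n = %d\n", x$w_left, x$w, x$n_obs))
  if (length(x$params))
    cat("  params:", paste(names(x$params),
                           signif(x$params, 4), sep = "=", collapse = "  "), "\n")
  cat(sprintf("  P_hat = %.4f   EDR = %.3f m (SE %.3f)   logLik = %.2f\n",
              x$P_hat, x$edr, x$se_edr, x$loglik))
  if (x$monotone_warning)
    cat("  warning: fitted g(r) is non-monotone on the annulus\n")
  invisible(x)
}

#' Evaluate a fitted detection function
#'
#' @param fit A `detection_fit`.
#' @param r Distances (m).
#' @return Detection probabilities `g(r)`, standardized to `g(0) = 1`.
#' @export
predict_g <- function(fit, r) {
  stopifnot(inherits(fit, "detection_fit"))
  eval_g(fit$model, fit$par, r, fit$w)
}

#' Average detection probability for given parameters
#'
#' Evaluates `P = 2 * int r g(r) dr / (w^2 - w_left^2)` over the truncation
#' annulus for a detection model with natural-scale parameters, together
#' with the implied effective detection radius. Closed-form half-normal
#' check: `P = (2*sigma^2/w^2) * (1 - exp(-w^2/(2*sigma^2)))` at
#' `w_left = 0`.
#'
#' @param model A [detection_model()].
#' @param params Named numeric vector on the natural scale: `sigma` (m),
#'   `b` (hazard-rate shape), `adj1`, `adj2` (adjustment coefficients).
#' @param w_left,w Truncation annulus, m.
#' @return List with `P` and `edr` (m).
#' @export
detection_probability <- function(model, params, w_left = 0, w) {
  stopifnot(inherits(model, "detection_model"))
  par <- switch(model$family,
    "half-normal" = c(log(params[["sigma"]]),
                      if (model$n_adjust) params[paste0("adj", seq_len(model$n_adjust))]),
    "hazard-rate" = c(log(params[["sigma"]]), log(params[["b"]]),
                      if (model$n_adjust) params[paste0("adj", seq_len(model$n_adjust))]),
    "uniform" = if (model$n_adjust)
      params[paste0("adj", seq_len(model$n_adjust))] else numeric(0))
  P <- as.numeric(integral_P(model, unname(par), w_left, w))
  list(P = P, edr = sqrt(P * (w^2 - w_left^2) + w_left^2))
}

#' Truncate binned distances
#'
#' Left truncation drops bands at or below `left`; right truncation is either
#' a fixed distance or the detection-probability rule: iteratively shrink `w`
#' to the next lower band edge until the fitted `g(w) >= 0.15`.
#'
#' @param bins Binned distance counts (`lo`, `hi`, `n`).
#' @param left Left truncation distance, m.
#' @param right_rule Either a numeric right-truncation distance or
#'   `"detection-prob-0.15"`.
#' @param model Model used to evaluate the rule (default half-normal, no
#'   adjustments).
#' @param threshold Detection probability floor for the rule.
#' @return List with `bins` (truncated), `w_left`, `w`, and (for the
#'   iterative rule) the final `fit`.
#' @export
truncate_distances <- function(bins, left = 0,
                               right_rule = "detection-prob-0.15",
                               model = detection_model("half-normal", 0),
                               threshold = 0.15) {
  bins <- bins[order(bins$lo), , drop = FALSE]
  keep <- bins$lo >= left - 1e-9
  bins <- bins[keep, , drop = FALSE]
  if (!nrow(bins) || sum(bins$n) == 0) stop("all data truncated")
  if (is.numeric(right_rule)) {
    w <- right_rule
    bins <- bins[bins$hi <= w + 1e-9, , drop = FALSE]
    if (!nrow(bins) || sum(bins$n) == 0) stop("all data truncated")
    return(list(bins = bins, w_left = left, w = w, fit = NULL))
  }
  if (!identical(right_rule, "detection-prob-0.15"))
    stop("unknown right truncation rule: ", right_rule)
  repeat {
    w <- max(bins$hi)
    fit <- fit_detection_function(bins, model, w_left = left, w = w)
    if (predict_g(fit, w) >= threshold)
      return(list(bins = bins, w_left = left, w = w, fit = fit))
    bins <- bins[-nrow(bins), , drop = FALSE]
    if (sum(bins$n > 0) < n_model_params(model) + 1)
      stop("all data truncated by the detection-probability rule")
  }
}

#' Chi-square overdispersion factor
#'
#' Computed from the observed vs expected bin counts of the
#' most-parameterized candidate model: `c_hat = max(1, chi2 / df)` with
#' `df = bins - params - 1`. Used to penalize non-independent observations
#' (bursts of the same animals) in QAIC model selection.
#'
#' @param fit A converged `detection_fit` (normally the most-parameterized
#'   candidate).
#' @return `c_hat` (>= 1).
#' @export
estimate_overdispersion <- function(fit) {
  stopifnot(inherits(fit, "detection_fit"))
  b <- fit$bins[fit$bins$expected > 0, , drop = FALSE]
  df <- nrow(b) - fit$npar - 1
  if (df <= 0) stop("non-positive degrees of freedom for overdispersion")
  chi2 <- sum((b$n - b$expected)^2 / b$expected)
  max(1, chi2 / df)
}

#' Quasi-AIC
#'
#' `-2 * loglik / c_hat + 2 * (n_params + 1)`; the `+1` counts `c_hat`
#' itself. Equals AIC when `c_hat = 1`.
#'
#' @param fit A `detection_fit`.
#' @param c_hat Overdispersion factor (>= 1).
#' @return QAIC value.
#' @export
qaic <- function(fit, c_hat = 1) {
  if (c_hat < 1) stop("'c_hat' must be >= 1")
  -2 * fit$loglik / c_hat + 2 * (fit$npar + 1)
}

#' Select the detection model by QAIC
#'
#' Ties are broken by fewer parameters, then by family order half-normal <
#' hazard-rate < uniform.
#'
#' @param fits List of `detection_fit` objects (failed fits may be `NULL`).
#' @param c_hat Shared overdispersion factor.
#' @return The winning `detection_fit`, with the QAIC table attached as
#'   attribute `"qaic_table"`.
#' @export
select_model <- function(fits, c_hat = 1) {
  fits <- Filter(function(f) !is.null(f) && inherits(f, "detection_fit"), fits)
  if (!length(fits)) stop("no converged detection fits to select from")
  fam_rank <- c("half-normal" = 1, "hazard-rate" = 2, "uniform" = 3)
  tab <- data.frame(
    family = vapply(fits, function(f) f$model$family, ""),
    n_adjust = vapply(fits, function(f) f$model$n_adjust, 0L),
    npar = vapply(fits, function(f) f$npar, 0L),
    loglik = vapply(fits, function(f) f$loglik, 0),
    qaic = vapply(fits, function(f) qaic(f, c_hat), 0))
  ord <- order(round(tab$qaic, 8), tab$npar, fam_rank[tab$family])
  best <- fits[[ord[1]]]
  attr(best, "qaic_table") <- tab[ord, ]
  best
}

#' Effective detection angle from absolute angles
#'
#' Fits a half-normal falloff to the absolute angles of detections (assuming
#' uniform availability across the viewshed) and converts it to an effective
#' full detection angle `theta = 2 * sqrt(2*sigma^2*(1 - exp(-h^2 /
#' (2*sigma^2))))`, truncated at the nominal half-angle `h`. SE by the
#' observed information and the delta method.
#'
#' @param angles Absolute angles from the viewshed center line, radians, in
#'   `[0, half_angle]`; at least 10 required.
#' @param half_angle Nominal half field-of-view, radians.
#' @return An `angle_fit`: `effective_angle` (full angle, radians), `se`,
#'   `sigma`, `n`.
#' @export
fit_effective_angle <- function(angles, half_angle) {
  if (length(angles) < 10) stop("at least 10 angles required")
  if (any(angles < 0 | angles > half_angle + 1e-9))
    stop("angles must lie in [0, half_angle]")
  h <- half_angle
  negll <- function(logs) {
    s <- exp(logs)
    denom <- stats::integrate(function(a) exp(-a^2 / (2 * s^2)), 0, h,
                              rel.tol = 1e-10)$value
    -(sum(-angles^2 / (2 * s^2)) - length(angles) * log(denom))
  }
  opt <- stats::optimize(negll, c(log(h / 100), log(h * 100)))
  logs <- opt$minimum
  sigma <- exp(logs)
  theta_of <- function(ls) {
    s <- exp(ls)
    min(2 * sqrt(2 * s^2 * (1 - exp(-h^2 / (2 * s^2)))), 2 * h)
  }
  theta <- theta_of(logs)
  eps <- 1e-4
  hess <- (negll(logs + eps) - 2 * negll(logs) + negll(logs - eps)) / eps^2
  se <- NA_real_
  if (is.finite(hess) && hess > 0) {
    dtheta <- (theta_of(logs + eps) - theta_of(logs - eps)) / (2 * eps)
    se <- abs(dtheta) / sqrt(hess)
  }
  structure(list(effective_angle = theta, se = se, sigma = sigma,
                 n = length(angles), half_angle = h), class = "angle_fit")
}

#' Tally tagged distances into band counts
#'
#' @param photos Photo-table rows (tagged rows are used).
#' @param scheme Band scheme to tally over (default the legal scheme).
#' @return Data frame `lo`, `hi`, `n` covering every scheme band.
#' @export
bin_distances <- function(photos, scheme = distance_band_scheme()) {
  tagged <- photos[!is.na(photos$animal_id), , drop = FALSE]
  idx <- match_distance_band(tagged$distance_lo, tagged$distance_hi)
  scheme$n <- tabulate(idx, nbins = nrow(scheme))
  scheme
}
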