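#' Distance banding scheme
#'
#' Camera-trap images are tagged with binned (not exact) distances: 0.5 m
#' bands on (0, 10] and 1 m bands on (10, 25]. Bands are lower-open,
#' upper-closed intervals.
#'
#' @return A data frame with columns `lo` and `hi` (meters), one row per
#'   legal band, ordered by distance.
#' @export
distance_band_scheme <- function() {
  lo <- c(seq(0, 9.5, by = 0.5), 10:24)
  hi <- c(seq(0.5, 10, by = 0.5), 11:25)
  data.frame(lo = lo, hi = hi)
}

#' Angle band labels
#'
#' Angles are tagged as fractions of the half field-of-view, in five bands:
#' 0 is the viewshed center, 1 the edge.
#'
#' @return Character vector of the five band labels.
#' @export
angle_band_labels <- function() {
  c("0-0.2", "0.2-0.4", "0.4-0.6", "0.6-0.8", "0.8-1.0")
}

# index of each (lo, hi) pair in the legal scheme, NA when not legal
match_distance_band <- function(lo, hi, tol = 1e-6) {
  scheme <- distance_band_scheme()
  idx <- rep(NA_integer_, length(lo))
  for (i in seq_len(nrow(scheme))) {
    ok <- abs(lo - scheme$lo[i]) < tol & abs(hi - scheme$hi[i]) < tol
    idx[ok & !is.na(ok)] <- i
  }
  idx
}

#' Midpoint of a legal distance band
#'
#' @param lo,hi Numeric vectors of band bounds in meters; each (lo, hi] pair
#'   must belong to the legal scheme (see [distance_band_scheme()]).
#' @return Numeric vector of arithmetic band midpoints (meters).
#' @export
#' @examples
#' band_midpoint(2, 2.5)   # 2.25
#' band_midpoint(10, 11)   # 10.5
band_midpoint <- function(lo, hi) {
  if (length(lo) != length(hi)) stop("'lo' and 'hi' must have equal length")
  idx <- match_distance_band(lo, hi)
  if (anyNA(idx) && any(!is.na(lo) & is.na(idx))) {
    bad <- which(!is.na(lo) & is.na(idx))[1]
    stop(sprintf("distance band (%s, %s] is not in the legal scheme",
                 format(lo[bad]), format(hi[bad])))
  }
  (lo + hi) / 2
}

#' Convert an angle band to an absolute angle
#'
#' Tagged angle bands are fractions of the half field-of-view. The band's
#' midpoint fraction is multiplied by the camera's nominal half-angle to give
#' an absolute angle from the viewshed center line.
#'
#' @param band Character vector of band labels (see [angle_band_labels()]) or
#'   integer band indices 1-5.
#' @param half_angle Camera half field-of-view in radians (> 0).
#' @return Absolute angles in radians.
#' @export
#' @examples
#' angle_band_to_radians("0-0.2", 0.4)  # 0.04
angle_band_to_radians <- function(band, half_angle) {
  if (!is.numeric(half_angle) || any(half_angle <= 0))
    stop("'half_angle' must be > 0")
  labels <- angle_band_labels()
  if (is.numeric(band)) {
    idx <- as.integer(band)
  } else {
    idx <- match(as.character(band), labels)
  }
  if (anyNA(idx) || any(idx < 1L | idx > 5L))
    stop("unknown angle band; legal bands are: ",
         paste(labels, collapse = ", "))
  mid <- c(0.1, 0.3, 0.5, 0.7, 0.9)[idx]
  mid * half_angle
}

# bin exact distances (0, 25] into the tagging scheme; returns list(lo, hi)
distance_to_band <- function(r) {
  if (any(r <= 0 | r > 25, na.rm = TRUE))
    stop("distances must lie in (0, 25] to be binned")
  near <- r <= 10
  lo <- ifelse(near, (ceiling(r / 0.5) - 1) * 0.5, ceiling(r) - 1)
  hi <- ifelse(near, ceiling(r / 0.5) * 0.5, ceiling(r))
  list(lo = lo, hi = hi)
}

# bin a fraction of the half field-of-view in [0, 1] into the 5 angle bands
fraction_to_angle_band <- function(frac) {
  if (any(frac < 0 | frac > 1, na.rm = TRUE))
    stop("angle fractions must lie in [0, 1]")
  idx <- pmin(pmax(ceiling(frac * 5), 1L), 5L)
  angle_band_labels()[idx]
}
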