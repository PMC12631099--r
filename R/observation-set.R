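#' @title Observation sets
#' @description
#' The central data container: a photo table (one row per tagged animal, with
#' blank frames as rows whose animal columns are `NA`) plus a deployment
#' table (camera geometry, operating window, trigger mechanics). All
#' timestamps are numeric seconds since the survey epoch, which is taken to
#' be a site-local midnight so that time-of-day is `timestamp %% 86400`.
#' @name observation_set
NULL

photo_columns <- function() {
  c("camera_id", "timestamp", "trigger_id", "animal_id",
    "distance_lo", "distance_hi", "angle_band", "reaction",
    "rem_contact", "group_id")
}

deployment_columns <- function() {
  c("camera_id", "x", "y", "start", "end", "half_angle",
    "recovery_s", "burst_size", "burst_interval_s")
}

#' Construct and validate an observation set
#'
#' @param photos Data frame with columns `camera_id`, `timestamp` (seconds
#'   since survey epoch), `trigger_id`, `animal_id`, `distance_lo`,
#'   `distance_hi`, `angle_band`, `reaction`, `rem_contact`, `group_id`.
#'   Blank frames are rows with `animal_id = NA`.
#' @param deployments Data frame with columns `camera_id`, `x`, `y` (site
#'   meters), `start`, `end` (seconds since epoch), `half_angle` (radians),
#'   `recovery_s`, `burst_size`, `burst_interval_s`. Optional extra columns
#'   (e.g. `orientation`, `max_tag_distance`) are preserved.
#' @param validate Check invariants (camera ids known, timestamps inside
#'   deployment windows, legal bands)?
#' @return An object of class `observation_set`: a list with elements
#'   `photos` and `deployments`, photos sorted by camera then time.
#' @export
observation_set <- function(photos, deployments, validate = TRUE) {
  for (col in photo_columns())
    if (!col %in% names(photos))
      stop(sprintf("photo table is missing column '%s'", col))
  for (col in deployment_columns())
    if (!col %in% names(deployments))
      stop(sprintf("deployment table is missing column '%s'", col))
  photos <- photos[order(photos$camera_id, photos$timestamp), , drop = FALSE]
  rownames(photos) <- NULL
  obs <- structure(list(photos = photos, deployments = deployments),
                   class = "observation_set")
  if (validate) validate_observation_set(obs)
  obs
}

validate_observation_set <- function(obs) {
  ph <- obs$photos
  dep <- obs$deployments
  if (any(dep$end <= dep$start))
    stop("deployment 'end' must be after 'start'")
  if (any(dep$half_angle <= 0 | dep$half_angle > pi))
    stop("'half_angle' must lie in (0, pi]")
  if (any(dep$recovery_s < 0) || any(dep$burst_size < 1))
    stop("'recovery_s' must be >= 0 and 'burst_size' >= 1")
  unknown <- !ph$camera_id %in% dep$camera_id
  if (any(unknown))
    stop("photo rows reference unknown camera_id: ",
         paste(utils::head(unique(ph$camera_id[unknown]), 5), collapse = ", "))
  idx <- match(ph$camera_id, dep$camera_id)
  off <- ph$timestamp < dep$start[idx] - 1e-6 |
    ph$timestamp > dep$end[idx] + 1e-6
  if (any(off))
    stop("photo timestamps outside deployment window at rows: ",
         paste(utils::head(which(off), 10), collapse = ", "))
  tagged <- !is.na(ph$animal_id)
  if (any(tagged)) {
    bad <- is.na(match_distance_band(ph$distance_lo[tagged],
                                     ph$distance_hi[tagged]))
    if (any(bad))
      stop("illegal distance band in photo rows: ",
           paste(utils::head(which(tagged)[bad], 10), collapse = ", "))
    if (any(!ph$angle_band[tagged] %in% angle_band_labels()))
      stop("illegal angle band in photo table")
  }
  invisible(obs)
}

#' @export
print.observation_set <- function(x, ...) {
  ph <- x$photos
  tagged <- sum(!is.na(ph$animal_id))
  frames <- nrow(unique(ph[, c("camera_id", "timestamp")]))
  cat("<observation_set>\n")
  cat(sprintf("  cameras: %d   frames: %d   tags: %d (blank frames: %d)\n",
              nrow(x$deployments), frames, tagged,
              frames - nrow(unique(ph[!is.na(ph$animal_id),
                                      c("camera_id", "timestamp")]))))
  invisible(x)
}

parse_time_column <- function(x, epoch) {
  if (is.numeric(x)) return(as.numeric(x))
  suppressWarnings(num <- as.numeric(x))
  if (!anyNA(num)) return(num)
  t <- as.POSIXct(x, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(t)) stop("unparseable timestamps in input table")
  as.numeric(t) - epoch
}

iso_epoch <- function(x) {
  # midnight (site-local clock, stored as UTC) on the first deployment day
  t <- as.POSIXct(x, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  as.numeric(trunc(min(t), units = "days"))
}

#' Read camera-trap observation tables
#'
#' Reads the delimited photo and deployment tables into a validated
#' [observation_set()]. Timestamps may be numeric (seconds since the survey
#' epoch) or ISO 8601 site-local strings; in the latter case the epoch is
#' midnight of the earliest deployment day, so clock time survives for the
#' activity analysis.
#'
#' @param photo_table_path,deployment_table_path Paths to CSV files following
#'   the documented schemas.
#' @return An `observation_set`.
#' @export
read_observations <- function(photo_table_path, deployment_table_path) {
  if (!file.exists(photo_table_path))
    stop("photo table not found: ", photo_table_path)
  if (!file.exists(deployment_table_path))
    stop("deployment table not found: ", deployment_table_path)
  ph <- utils::read.csv(photo_table_path, stringsAsFactors = FALSE)
  dep <- utils::read.csv(deployment_table_path, stringsAsFactors = FALSE)
  for (col in photo_columns())
    if (!col %in% names(ph))
      stop(sprintf("photo table is missing column '%s'", col))
  for (col in deployment_columns())
    if (!col %in% names(dep))
      stop(sprintf("deployment table is missing column '%s'", col))
  epoch <- if (is.numeric(dep$start) ||
               !anyNA(suppressWarnings(as.numeric(dep$start)))) 0
           else iso_epoch(dep$start)
  dep$start <- parse_time_column(dep$start, epoch)
  dep$end <- parse_time_column(dep$end, epoch)
  ph$timestamp <- parse_time_column(ph$timestamp, epoch)
  ph$reaction <- as.logical(ph$reaction)
  ph$rem_contact <- as.logical(ph$rem_contact)
  ph$camera_id <- as.character(ph$camera_id)
  dep$camera_id <- as.character(dep$camera_id)
  # blank frames round-trip as empty strings in character columns
  for (col in c("animal_id", "trigger_id", "angle_band", "group_id")) {
    ph[[col]] <- as.character(ph[[col]])
    ph[[col]][!nzchar(ph[[col]])] <- NA_character_
  }
  observation_set(ph, dep)
}

#' Write observation tables
#'
#' Inverse of [read_observations()]: emits the photo and deployment tables
#' with numeric timestamps (seconds since the survey epoch), so a
#' write-then-read round trip is exact.
#'
#' @param obs An `observation_set`.
#' @param photo_table_path,deployment_table_path Output CSV paths.
#' @return `obs`, invisibly.
#' @export
write_observations <- function(obs, photo_table_path, deployment_table_path) {
  stopifnot(inherits(obs, "observation_set"))
  utils::write.csv(obs$photos, photo_table_path, row.names = FALSE, na = "")
  utils::write.csv(obs$deployments, deployment_table_path,
                   row.names = FALSE, na = "")
  invisible(obs)
}

frame_key <- function(photos) {
  paste(photos$camera_id, sprintf("%.6f", photos$timestamp), sep = "\r")
}

#' Remove animals that reacted to the camera
#'
#' Tags flagged as reactions (the animal visibly responded to the camera) are
#' excluded so that they do not bias encounter rates. A frame whose only tags
#' were reactions is retained as a blank frame, because blank frames delimit
#' group contacts.
#'
#' @param obs An `observation_set`.
#' @return The filtered `observation_set`. Idempotent.
#' @export
filter_reactions <- function(obs) {
  stopifnot(inherits(obs, "observation_set"))
  ph <- obs$photos
  flagged <- !is.na(ph$animal_id) & ph$reaction %in% TRUE
  if (!any(flagged)) return(obs)
  key <- frame_key(ph)
  keep <- ph[!flagged, , drop = FALSE]
  lost <- setdiff(unique(key[flagged]), unique(key[!flagged]))
  if (length(lost)) {
    blanks <- ph[match(lost, key), , drop = FALSE]
    blank_cols <- c("animal_id", "distance_lo", "distance_hi",
                    "angle_band", "reaction", "rem_contact", "group_id")
    blanks[blank_cols] <- NA
    keep <- rbind(keep, blanks)
  }
  observation_set(keep, obs$deployments, validate = FALSE)
}

#' Segment a camera's photo stream into group contacts
#'
#' A new contact for a group begins a maximal run of non-empty frames; runs
#' are separated by at least one frame in which no animals were present. The
#' contact time is the first frame of the run. Used to build the "contacts
#' only" event series for the activity analysis.
#'
#' @param photos Photo-table rows for a single camera, time-sorted.
#' @return Numeric vector of contact timestamps (possibly empty).
#' @export
segment_group_contacts <- function(photos) {
  if (length(unique(photos$camera_id)) > 1)
    stop("'photos' must contain a single camera's stream")
  if (nrow(photos) == 0) return(numeric(0))
  if (is.unsorted(photos$timestamp)) stop("photo stream is not time-sorted")
  ts <- unique(photos$timestamp)
  occ_ts <- unique(photos$timestamp[!is.na(photos$animal_id)])
  occupied <- ts %in% occ_ts
  if (!any(occupied)) return(numeric(0))
  runs <- rle(occupied)
  starts <- cumsum(c(1L, runs$lengths))[seq_along(runs$lengths)]
  ts[starts[runs$values]]
}

#' Group-contact times across all cameras
#'
#' @param obs An `observation_set` (reaction-filtered as appropriate).
#' @return Numeric vector of contact timestamps pooled over cameras.
#' @export
group_contact_times <- function(obs) {
  stopifnot(inherits(obs, "observation_set"))
  ph <- obs$photos
  unlist(lapply(split(ph, ph$camera_id), segment_group_contacts),
         use.names = FALSE)
}
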