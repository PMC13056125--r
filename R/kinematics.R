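#' Tracked platelet centroid/orientation time series
#'
#' @param t strictly increasing time stamps (s), length >= 3.
#' @param x,y centroid coordinates (um).
#' @param orientation wrapped orientation series (deg, in `[-180, 180)`).
#' @param radius platelet radius (um); default 1.25 um when the track
#'   metadata omits it.
#' @param group shape group label, `"discoid"` or `"spherical"`.
#' @param id track identifier.
#' @return an object of class `tracked_platelet`.
#' @export
tracked_platelet <- function(t, x, y, orientation, radius = 1.25,
                             group = c("discoid", "spherical"), id = "track1") {
  group <- match.arg(group)
  n <- length(t)
  if (n < 3L) stop_bad("a track needs at least 3 frames")
  if (length(x) != n || length(y) != n || length(orientation) != n)
    stop_bad("track series lengths differ")
  if (any(diff(t) <= 0)) stop_bad("`t` must be strictly increasing")
  check_number(radius, "radius", lower = 0, strict_lower = TRUE)
  structure(list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                 orientation = as.numeric(orientation), radius = radius,
                 group = group, id = as.character(id)),
            class = "tracked_platelet")
}

#' @export
print.tracked_platelet <- function(x, ...) {
  cat(sprintf("<tracked_platelet> %s (%s): %d frames over %.1f s, radius %.2f um\n",
              x$id, x$group, length(x$t), diff(range(x$t)), x$radius))
  invisible(x)
}

#' Cumulative path length of a track
#'
#' Cumulative sum of Euclidean frame-to-frame steps, starting at 0.
#'
#' @param track a [tracked_platelet()].
#' @return numeric series (um), same length as the track.
#' @export
displacement_series <- function(track) {
  stopifnot(inherits(track, "tracked_platelet"))
  if (length(track$t) < 2L) stop_bad("need at least 2 frames")
  c(0, cumsum(sqrt(diff(track$x)^2 + diff(track$y)^2)))
}

#' Unwrapped cumulative rotation of a track
#'
#' Resolves +/-180 deg wrap jumps by the minimal-angular-change rule (an
#' exact 180 deg step is taken as positive rotation), converts to radians and
#' accumulates the signed rotation starting at 0.
#'
#' @param track a [tracked_platelet()].
#' @return numeric series (rad), same length as the track.
#' @export
rotation_series <- function(track) {
  stopifnot(inherits(track, "tracked_platelet"))
  if (length(track$t) < 2L) stop_bad("need at least 2 frames")
  d <- diff(track$orientation)
  d <- ((d + 180) %% 360) - 180      # minimal-change branch, in [-180, 180)
  d[d == -180] <- 180                # tie toward positive rotation
  c(0, cumsum(d)) * pi / 180
}

#' Rolling index of a track
#'
#' `radius x |total unwrapped rotation| / total path length`: 1 for perfect
#' no-slip rolling, 0 for pure sliding. Undefined (NA with attribute
#' `undefined`) when the track does not move.
#'
#' @param track a [tracked_platelet()].
#' @return dimensionless rolling index, or NA when displacement is zero.
#' @export
rolling_index <- function(track) {
  disp <- displacement_series(track)
  total <- disp[length(disp)]
  if (total <= 0) return(structure(NA_real_, undefined = TRUE))
  rot <- rotation_series(track)
  track$radius * abs(rot[length(rot)]) / total
}

#' Classify wall motion as rolling or sliding
#'
#' Rolling iff the rolling index is at least `threshold` (boundary counts as
#' rolling). The default threshold 0.5 is the midpoint of the ideal rolling
#' (1) and sliding (0) signatures.
#'
#' @param track a [tracked_platelet()].
#' @param threshold rolling-index threshold.
#' @return `"rolling"`, `"sliding"`, or `"unclassified"` when the index is
#'   undefined.
#' @export
classify_motion <- function(track, threshold = 0.5) {
  check_number(threshold, "threshold", lower = 0)
  ri <- rolling_index(track)
  if (is.na(ri)) return("unclassified")
  if (ri >= threshold) "rolling" else "sliding"
}

#' Trend of the frame speed over time
#'
#' Least-squares slope of frame speed versus time: `"accelerating"` when the
#' slope exceeds `tolerance`, `"decelerating"` below `-tolerance`, otherwise
#' `"steady"`.
#'
#' @param track a [tracked_platelet()] with at least 5 frames.
#' @param tolerance absolute slope (um/s^2) below which the speed counts as
#'   steady.
#' @return `"accelerating"`, `"decelerating"` or `"steady"`.
#' @export
velocity_trend <- function(track, tolerance = 0.01) {
  stopifnot(inherits(track, "tracked_platelet"))
  if (length(track$t) < 5L) stop_bad("need at least 5 frames for a trend")
  steps <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  dt <- diff(track$t)
  speed <- steps / dt
  tm <- (track$t[-1] + track$t[-length(track$t)]) / 2
  slope <- stats::cov(tm, speed) / stats::var(tm)
  if (slope > tolerance) "accelerating"
  else if (slope < -tolerance) "decelerating"
  else "steady"
}

#' Motion summary of a single track
#'
#' Convenience bundle of [displacement_series()], [rotation_series()],
#' [rolling_index()], [classify_motion()] and [velocity_trend()].
#'
#' @param track a [tracked_platelet()].
#' @param threshold rolling-index classification threshold.
#' @return an object of class `motion_summary`.
#' @export
summarize_motion <- function(track, threshold = 0.5) {
  disp <- displacement_series(track)
  rot <- rotation_series(track)
  structure(list(id = track$id, group = track$group,
                 total_displacement = disp[length(disp)],
                 total_rotation = abs(rot[length(rot)]),
                 rolling_index = rolling_index(track),
                 classification = classify_motion(track, threshold),
                 velocity_trend = velocity_trend(track)),
            class = "motion_summary")
}

#' @export
print.motion_summary <- function(x, ...) {
  cat(sprintf("<motion_summary> %s (%s): %s, index %.3f, %.1f um, %.2f rad, %s\n",
              x$id, x$group, x$classification, x$rolling_index,
              x$total_displacement, x$total_rotation, x$velocity_trend))
  invisible(x)
}

#' Per-group rolling statistics
#'
#' @param tracks list of [tracked_platelet()]s belonging to one group.
#' @param group group label.
#' @param threshold rolling-index threshold passed to [classify_motion()].
#' @return an object of class `group_motion_stats` with `group`, `n`,
#'   `n_rolling` and `rolling_fraction`.
#' @export
group_motion_stats <- function(tracks, group = "group", threshold = 0.5) {
  if (!length(tracks)) stop_bad("no tracks in group")
  cls <- vapply(tracks, classify_motion, character(1), threshold = threshold)
  n_roll <- sum(cls == "rolling")
  structure(list(group = as.character(group), n = length(tracks),
                 n_rolling = n_roll, rolling_fraction = n_roll / length(tracks)),
            class = "group_motion_stats")
}

#' Fold ratio of rolling probabilities between two groups
#'
#' Ratio of rolling fractions `a / b` with the Katz log-method confidence
#' interval for a risk ratio. Undefined (flagged) when the denominator
#' fraction is zero.
#'
#' @param a,b [group_motion_stats()] objects (numerator, denominator).
#' @param conf_level confidence level for the interval.
#' @return list with `ratio`, `ci_lower`, `ci_upper`, `undefined`.
#' @export
group_rolling_ratio <- function(a, b, conf_level = 0.95) {
  stopifnot(inherits(a, "group_motion_stats"), inherits(b, "group_motion_stats"))
  if (b$rolling_fraction == 0)
    return(list(ratio = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                undefined = TRUE))
  ratio <- a$rolling_fraction / b$rolling_fraction
  if (a$n_rolling == 0L)
    return(list(ratio = ratio, ci_lower = NA_real_, ci_upper = NA_real_,
                undefined = TRUE))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / a$n_rolling - 1 / a$n + 1 / b$n_rolling - 1 / b$n)
  list(ratio = ratio,
       ci_lower = exp(log(ratio) - z * se),
       ci_upper = exp(log(ratio) + z * se),
       undefined = FALSE)
}

#' Discoid-fraction time series from per-frame shape counts
#'
#' @param counts data frame with columns `t_min`, `n_discoid`, `n_total`
#'   (e.g. from [sample_shape_labels()]); frames with `n_total = 0` are
#'   flagged missing (NA fraction).
#' @param switch_times increasing phase boundaries (min) assigning
#'   `treatment` / `circulation` / `recovery` phases.
#' @return a data frame of class `shape_series` with `t_min`,
#'   `discoid_fraction`, `phase`.
#' @export
discoid_fraction_series <- function(counts, switch_times = c(30, 60)) {
  stopifnot(is.data.frame(counts),
            all(c("t_min", "n_discoid", "n_total") %in% names(counts)))
  frac <- ifelse(counts$n_total > 0, counts$n_discoid / counts$n_total, NA_real_)
  bounds <- c(0, switch_times, Inf)
  labels <- c("treatment", "circulation", "recovery")[seq_len(length(bounds) - 1L)]
  phase <- labels[findInterval(counts$t_min, bounds, rightmost.closed = FALSE)]
  structure(data.frame(t_min = counts$t_min, discoid_fraction = frac,
                       phase = phase),
            class = c("shape_series", "data.frame"))
}

#' Classify platelet shape from its projected aspect ratio
#'
#' Discoid iff the major/minor axis ratio is at least `cutoff` (boundary
#' counts as discoid); ratios below 1 violate the major/minor convention.
#'
#' @param aspect_ratio major/minor axis ratio (>= 1).
#' @param cutoff classification cutoff.
#' @return `"discoid"` or `"spherical"`.
#' @export
classify_shape <- function(aspect_ratio, cutoff = 1.3) {
  check_number(aspect_ratio, "aspect_ratio", lower = 1)
  check_number(cutoff, "cutoff", lower = 1)
  if (aspect_ratio >= cutoff) "discoid" else "spherical"
}

#' Time for a conformational extension at a given pulling speed
#'
#' `time = extension / speed`, reported in milliseconds: a 15-nm integrin
#' extension at the 0.8 um/s wall speed takes 18.75 ms, well within the
#' ~50 ms physiological switching time of integrin unbending.
#'
#' @param extension_nm conformational extension (nm).
#' @param speed_um_s pulling/translation speed (um/s), positive.
#' @return duration (ms).
#' @export
conformational_switch_time <- function(extension_nm = 15, speed_um_s = 0.8) {
  check_number(extension_nm, "extension_nm", lower = 0)
  check_number(speed_um_s, "speed_um_s", lower = 0, strict_lower = TRUE)
  extension_nm / speed_um_s
}
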