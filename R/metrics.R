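# Per-trial trajectory measures.
#
# Departing direction (DD) and perimeter-crossing direction (PCD) are the
# positional angles at which the trajectory first crosses, from inside to
# outside, the departure circle and the perimeter boundary respectively;
# crossing points are linearly interpolated in Cartesian space between the
# bracketing samples. Deviations are unsigned circular differences from the
# high-value zone centre.

# all inside->outside crossings of the circle of radius r, with linear
# interpolation of the crossing point along each bracketing segment
crossings_outward <- function(samples, r) {
  x <- samples$x; y <- samples$y; t <- samples$t
  n <- length(x)
  empty <- data.frame(index = integer(0), s = numeric(0), x = numeric(0),
                      y = numeric(0), angle = numeric(0), t = numeric(0))
  if (n < 2) return(empty)
  rad <- sqrt(x^2 + y^2)
  idx <- which(rad[-n] < r & rad[-1] >= r)
  if (!length(idx)) return(empty)
  dx <- x[idx + 1] - x[idx]; dy <- y[idx + 1] - y[idx]
  a <- dx^2 + dy^2
  b <- 2 * (x[idx] * dx + y[idx] * dy)
  cc <- x[idx]^2 + y[idx]^2 - r^2
  s <- (-b + sqrt(pmax(0, b^2 - 4 * a * cc))) / (2 * a)
  s <- pmin(1, pmax(0, s))
  cx <- x[idx] + s * dx; cy <- y[idx] + s * dy
  data.frame(index = idx, s = s, x = cx, y = cy,
             angle = arena_angle_from_xy(cx, cy),
             t = t[idx] + s * (t[idx + 1] - t[idx]))
}

#' Departing direction (DD) of a trial
#'
#' Arena-frame angle of the point where the trajectory first crosses the
#' departure circle from inside to outside, linearly interpolated between
#' the bracketing samples.
#'
#' @param trial a `vr_trial` (or any list with a `samples` data.frame).
#' @param config an `arena_config`.
#' @return angle in degrees in `[0, 360)`.
#' @export
departing_direction <- function(trial, config) {
  cr <- crossings_outward(trial$samples, config$departure_circle_radius)
  if (!nrow(cr))
    stop("departing direction undefined: trajectory never leaves the departure circle")
  cr$angle[1]
}

#' DD-deviation angle
#'
#' Unsigned circular difference between the departing direction and the
#' high-value zone centre (180 deg by default).
#'
#' @inheritParams departing_direction
#' @return deviation in degrees, in `[0, 180]`.
#' @export
dd_deviation <- function(trial, config) {
  circular_deviation(departing_direction(trial, config),
                     config$zones$high$center_angle)
}

#' Perimeter crossings of a trial
#'
#' Inside-to-outside crossings of the unmarked perimeter boundary (the
#' circle sharing the reward zones' inner edge). Outside-to-inside
#' transitions are not counted, so a completed trial always has at least
#' one crossing and wandering trials accumulate more.
#'
#' @inheritParams departing_direction
#' @return data.frame with one row per crossing: `index` (bracketing
#'   sample), `angle` (degrees) and `t` (seconds); zero rows if the
#'   trajectory never leaves the perimeter.
#' @export
perimeter_crossings <- function(trial, config) {
  cr <- crossings_outward(trial$samples, config$perimeter_radius)
  cr[, c("index", "angle", "t")]
}

#' Perimeter-crossing direction (PCD) of a trial
#'
#' Angle at which the trajectory first touches the perimeter boundary
#' (first inside-to-outside crossing).
#'
#' @inheritParams departing_direction
#' @return angle in degrees in `[0, 360)`.
#' @export
perimeter_crossing_direction <- function(trial, config) {
  cr <- perimeter_crossings(trial, config)
  if (!nrow(cr))
    stop("PCD undefined: trajectory never crosses the perimeter boundary")
  cr$angle[1]
}

#' PCD-deviation angle
#'
#' @inheritParams departing_direction
#' @return deviation of the PCD from the high-value zone centre, degrees.
#' @export
pcd_deviation <- function(trial, config) {
  circular_deviation(perimeter_crossing_direction(trial, config),
                     config$zones$high$center_angle)
}

unwrap_deg <- function(a) {
  if (length(a) <= 1) return(a)
  a[1] + c(0, cumsum(signed180(diff(a))))
}

#' Scene-rotation trace of a trial
#'
#' Unwrapped scene direction (minimal-jump unwrapping, clockwise rotation
#' positive) against the cumulative path length from the trial start to the
#' departure-circle exit, normalized to `[0, 1]`. In-place rotations before
#' departure therefore appear as vertical excursions at distance 0.
#'
#' @inheritParams departing_direction
#' @return object of class `scene_rotation_trace`: data.frame with columns
#'   `normalized_distance` and `scene_direction` (unwrapped degrees).
#' @export
scene_rotation_trace <- function(trial, config) {
  cr <- crossings_outward(trial$samples, config$departure_circle_radius)
  if (!nrow(cr))
    stop("scene rotation trace undefined: trajectory never leaves the departure circle")
  i <- cr$index[1]; s <- cr$s[1]
  sm <- trial$samples
  xs <- c(sm$x[seq_len(i)], cr$x[1])
  ys <- c(sm$y[seq_len(i)], cr$y[1])
  sd_end <- sm$scene_dir[i] + s * signed_diff(sm$scene_dir[i + 1], sm$scene_dir[i])
  scn <- c(sm$scene_dir[seq_len(i)], wrap360(sd_end))
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  nd <- if (total > 0) cum / total else cum
  structure(data.frame(normalized_distance = nd,
                       scene_direction = unwrap_deg(scn)),
            class = c("scene_rotation_trace", "data.frame"))
}

#' Direction of the first body turn in a trial
#'
#' Sign of the first unwrapped scene-direction excursion from its initial
#' value that exceeds `threshold`. Positive excursions are clockwise in the
#' arena convention.
#'
#' @inheritParams departing_direction
#' @param threshold excursion threshold in degrees (default 10).
#' @return `"cw"`, `"ccw"` or `"none"`.
#' @export
first_turn_direction <- function(trial, threshold = 10) {
  u <- unwrap_deg(trial$samples$scene_dir)
  exc <- u - u[1]
  i <- which(abs(exc) > threshold)[1]
  if (is.na(i)) return("none")
  if (exc[i] > 0) "cw" else "ccw"
}

#' Travel distance, excess distance, latency and mean speed of a trial
#'
#' Travel distance is the summed segment length from the trial start to the
#' trial end (reward-zone entry, or the last sample for timeouts). Excess
#' travel distance subtracts the shortest possible path: the perimeter
#' radius for the main task (both zones share the same inner boundary), or
#' the start-to-zone-edge distance for the probe task; it is `NA` for
#' timeout trials. Mean speed covers the full start-to-end interval,
#' including any post-bump recovery pauses.
#'
#' @inheritParams departing_direction
#' @return list with `travel_distance` (m), `excess_travel_distance` (m or
#'   `NA`), `latency` (s) and `mean_speed` (cm/s).
#' @export
path_lengths <- function(trial, config) {
  sm <- trial$samples
  travel <- sum(sqrt(diff(sm$x)^2 + diff(sm$y)^2))
  latency <- sm$t[nrow(sm)] - sm$t[1]
  shortest <- if (identical(config$task, "probe")) {
    b <- trial$beacon %||% config$beacon_positions$right
    max(0, sqrt(sum((b - config$start_position)^2)) - config$reward_zone_radius)
  } else {
    config$perimeter_radius
  }
  excess <- if (trial$outcome == "timeout") NA_real_ else travel - shortest
  list(travel_distance = travel,
       excess_travel_distance = excess,
       latency = latency,
       mean_speed = if (latency > 0) 100 * travel / latency else NA_real_)
}

#' Classify a probe-task trial as direct hit or failed
#'
#' A direct hit is a trial that reaches the beacon reward zone without any
#' wall contact; trials with wall bumps or timeouts are failed.
#'
#' @param trial a probe-task `vr_trial`.
#' @param config a probe-task `arena_config`.
#' @return `"direct_hit"` or `"failed"`.
#' @export
classify_probe_trial <- function(trial, config) {
  if (!identical(config$task, "probe"))
    stop("classify_probe_trial() expects a probe-task config")
  if (trial$outcome != "timeout" && length(trial$bumps) == 0) "direct_hit"
  else "failed"
}

#' Full metric record for one trial
#'
#' Computes every per-trial measure as a one-row data.frame. DD/PCD fields
#' are `NA` when undefined (e.g. timeout inside the departure circle).
#'
#' @inheritParams departing_direction
#' @param first_turn_threshold degrees, see [first_turn_direction()].
#' @return one-row data.frame (class `trial_metrics`).
#' @export
trial_metrics <- function(trial, config, first_turn_threshold = 10) {
  dd <- tryCatch(departing_direction(trial, config), error = function(e) NA_real_)
  crs <- if (identical(config$task, "probe")) {
    data.frame(index = integer(0), angle = numeric(0), t = numeric(0))
  } else {
    perimeter_crossings(trial, config)
  }
  pcd <- if (nrow(crs)) crs$angle[1] else NA_real_
  hv <- if (identical(config$task, "probe")) NA_real_ else config$zones$high$center_angle
  pl <- path_lengths(trial, config)
  structure(data.frame(
    trial_id = trial$trial_id %||% NA_integer_,
    session_id = trial$session_id %||% NA_character_,
    subject_id = trial$subject_id %||% NA_character_,
    condition = trial$condition %||% NA_character_,
    start_direction = trial$start_direction,
    outcome = trial$outcome,
    departing_direction = dd,
    dd_deviation = if (is.na(dd)) NA_real_ else circular_deviation(dd, hv),
    perimeter_crossing_direction = pcd,
    pcd_deviation = if (is.na(pcd) || is.na(hv)) NA_real_ else circular_deviation(pcd, hv),
    n_perimeter_crossings = nrow(crs),
    n_bumps = length(trial$bumps),
    travel_distance = pl$travel_distance,
    excess_travel_distance = pl$excess_travel_distance,
    latency = pl$latency,
    mean_speed = pl$mean_speed,
    first_turn = first_turn_direction(trial, first_turn_threshold),
    reward_drops = trial$reward_drops,
    stringsAsFactors = FALSE
  ), class = c("trial_metrics", "data.frame"))
}

#' Metric table for a whole session
#'
#' @param session a `vr_session`.
#' @param config the matching `arena_config`.
#' @param first_turn_threshold degrees, see [first_turn_direction()].
#' @return data.frame with one row per trial.
#' @export
session_metrics <- function(session, config, first_turn_threshold = 10) {
  do.call(rbind, lapply(session$trials, trial_metrics, config = config,
                        first_turn_threshold = first_turn_threshold))
}
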