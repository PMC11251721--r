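# Arena geometry and task constants.
#
# The main place-preference task: a circular arena of 1.6 m diameter with a
# fixed start at the centre, six possible start directions, a small
# "departure circle" around the start, an unmarked perimeter boundary that
# shares the inner edge of the two reward zones, and annular-sector reward
# zones at 180 deg (high value, 12 drops) and 0 deg (low value, 2 drops).
#
# The probe (object-guided) task: same arena with no peripheral landmarks, a
# fixed start near the south periphery, a flickering beacon spawned left or
# right of the start heading, and a 0.4 m-radius disc reward zone around it.

new_reward_zone <- function(label, center_angle, angular_halfwidth = 30,
                            inner_radius = 0.62, outer_radius = 0.78,
                            reward_drops, drop_volume = 12) {
  list(label = label,
       center_angle = wrap360(center_angle),
       angular_halfwidth = angular_halfwidth,
       inner_radius = inner_radius,
       outer_radius = outer_radius,
       reward_drops = reward_drops,
       drop_volume = drop_volume)
}

main_arena_defaults <- function() {
  list(
    task = "main",
    arena_radius = 0.8,
    start_position = c(0, 0),
    departure_circle_radius = 0.10,
    perimeter_radius = 0.62,
    zones = list(
      high = new_reward_zone("high", 180, reward_drops = 12),
      low  = new_reward_zone("low", 0, reward_drops = 2)
    ),
    start_directions = c(270, 315, 45, 90, 135, 225), # N NE SE S SW NW
    iti_still_duration = 5,     # s of stillness required to start a trial
    iti_speed_threshold = 5,    # cm/s
    reward_duration = 8,        # s, scene frozen while reward is consumed
    trial_timeout = 120,        # s (not stated for the main task; default)
    sample_rate = 60            # Hz
  )
}

validate_main_arena <- function(cfg) {
  if (!(cfg$departure_circle_radius < cfg$perimeter_radius &&
        cfg$perimeter_radius < cfg$arena_radius))
    stop("invalid geometry: need departure_circle_radius < perimeter_radius < arena_radius")
  sd <- cfg$start_directions
  if (any(sd < 0 | sd >= 360)) stop("start_directions must lie in [0, 360)")
  if (length(sd) != 6) stop("the main task uses exactly 6 start directions")
  if (anyDuplicated(sd)) stop("start_directions must be distinct")
  for (z in cfg$zones) {
    if (any(abs(signed_diff(sd, z$center_angle)) < 1e-9))
      stop("a start direction coincides with a reward-zone centre")
    if (z$outer_radius >= cfg$arena_radius)
      stop("reward zones must sit at a slight distance from the arena wall")
    if (abs(z$inner_radius - cfg$perimeter_radius) > 1e-9)
      stop("perimeter_radius must equal the inner boundary of every reward zone")
  }
  if (!isTRUE(all.equal(cfg$zones$high$reward_drops / cfg$zones$low$reward_drops, 6)))
    stop("high:low reward must keep the 6:1 drop ratio")
  invisible(cfg)
}

#' Build the main place-preference arena configuration
#'
#' Returns the default task geometry: a circular arena of radius 0.8 m
#' (1.6 m diameter) with the start at the centre, a departure circle of
#' radius 0.10 m, an unmarked perimeter boundary at 0.62 m (the shortest
#' start-to-zone path), a high-value zone centred at 180 deg rewarding 12
#' drops and a low-value zone at 0 deg rewarding 2 drops (6:1 value ratio),
#' and six start directions (N, NE, SE, S, SW, NW).
#'
#' @param overrides named list of fields to override; unknown names are an
#'   error, and geometric invariants are re-checked after overriding.
#' @return an object of class `arena_config`.
#' @examples
#' cfg <- build_main_arena()
#' cfg$arena_radius            # 0.8
#' cfg$zones$high$center_angle # 180
#' @export
build_main_arena <- function(overrides = list()) {
  cfg <- main_arena_defaults()
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("overrides must be a named list")
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  validate_main_arena(cfg)
  structure(cfg, class = "arena_config")
}

#' Build the object-guided (probe) task arena configuration
#'
#' The probe task keeps the circular arena but removes all peripheral
#' landmarks. The rat starts from a fixed point near the south periphery,
#' facing north; a flickering beacon appears left or right of the start
#' heading, and the reward zone is a 0.4 m-radius disc around the beacon.
#' Trials time out after 60 s.
#'
#' @return an object of class `arena_config` with `task = "probe"`.
#' @examples
#' build_probe_arena()$reward_zone_radius # 0.4
#' @export
build_probe_arena <- function() {
  cfg <- list(
    task = "probe",
    landmarks = FALSE,
    arena_radius = 0.8,
    start_position = c(0, -0.7),       # south periphery, facing north
    start_directions = 270,
    departure_circle_radius = 0.10,
    perimeter_radius = 0.62,
    zones = list(),
    reward_zone_radius = 0.4,
    # beacon positions symmetric about the start heading (left/right)
    beacon_positions = list(left = c(-0.35, 0.25), right = c(0.35, 0.25)),
    iti_still_duration = 5,
    iti_speed_threshold = 5,
    reward_duration = 8,
    trial_timeout = 60,
    sample_rate = 60
  )
  structure(cfg, class = "arena_config")
}

#' Arena-frame angle of a point
#'
#' Angular position of a point about the arena centre, measured clockwise
#' from East in degrees (so North maps to 270, NE to 315, NW to 225).
#'
#' @param point numeric length-2 Cartesian coordinates in meters.
#' @param config an `arena_config` (used only to reject degenerate input).
#' @return angle in degrees in `[0, 360)`.
#' @export
angle_of <- function(point, config) {
  stopifnot(length(point) == 2)
  if (sqrt(sum(point^2)) < 1e-12)
    stop("angle undefined at the arena centre")
  arena_angle_from_xy(point[1], point[2])
}

#' Reward-zone membership of a point
#'
#' Tests whether a point lies inside the high- or low-value annular sector.
#'
#' @param point numeric length-2 Cartesian coordinates in meters.
#' @param config an `arena_config`.
#' @return `"high"`, `"low"` or `"none"`.
#' @export
zone_membership <- function(point, config) {
  stopifnot(length(point) == 2)
  r <- sqrt(sum(point^2))
  if (r > config$arena_radius + 1e-9) stop("point outside the arena")
  if (r < 1e-12) return("none")
  a <- arena_angle_from_xy(point[1], point[2])
  for (z in config$zones) {
    if (r >= z$inner_radius && r <= z$outer_radius &&
        circular_deviation(a, z$center_angle) <= z$angular_halfwidth)
      return(z$label)
  }
  "none"
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf("<arena_config: %s task>\n", x$task))
  cat(sprintf("  arena radius %.2f m, perimeter %.2f m, departure circle %.2f m\n",
              x$arena_radius, x$perimeter_radius, x$departure_circle_radius))
  if (x$task == "main") {
    cat(sprintf("  zones: high @ %g deg (%d drops), low @ %g deg (%d drops)\n",
                x$zones$high$center_angle, x$zones$high$reward_drops,
                x$zones$low$center_angle, x$zones$low$reward_drops))
    cat("  start directions:", paste(x$start_directions, collapse = ", "), "\n")
  } else {
    cat(sprintf("  beacon reward disc radius %.2f m, timeout %g s\n",
                x$reward_zone_radius, x$trial_timeout))
  }
  invisible(x)
}
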