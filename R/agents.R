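# Synthetic navigation agents.
#
# The generator reproduces the qualitative behavioural regimes of the task:
#   novice  - runs straight along the imposed start direction without
#             rotating the scene first, so it usually misses the zones;
#   expert  - rotates the treadmill counterclockwise at the start until the
#             scene is aligned with the high-value zone, then runs straight;
#   dMUS    - (dorsal inactivation) still targets the high-value zone but
#             with degraded alignment precision and poorer recovery after
#             wall bumps, most of which happen near the goal;
#   iMUS    - (intermediate inactivation) poorly concentrated departures,
#             a non-trivial probability of targeting the low-value zone and
#             mostly random reorientation -> disorganised trajectories.
#
# Numeric parameter values are the package's own calibration of these
# regimes (the underlying study reports no generative parameters); they are
# all configurable.

agent_conditions <- c("novice", "expert", "dMUS", "iMUS", "probe")

new_agent_params <- function(condition, kappa_align, p_low_target, kappa_run,
                             rotate_at_start, p_reorient_success,
                             turn_bias = c("ccw", "cw", "none"),
                             speed_mean = 0.15, speed_sd = 0.03,
                             speed_floor = 0.05, wall_margin = 0.02,
                             recovery_duration = 1, rotation_speed = 90,
                             align_tolerance = 5) {
  turn_bias <- match.arg(turn_bias)
  stopifnot(kappa_align >= 0, kappa_run >= 0,
            p_low_target >= 0, p_low_target <= 1,
            p_reorient_success >= 0, p_reorient_success <= 1)
  structure(list(condition = condition,
                 kappa_align = kappa_align,
                 p_low_target = p_low_target,
                 kappa_run = kappa_run,
                 rotate_at_start = rotate_at_start,
                 p_reorient_success = p_reorient_success,
                 turn_bias = turn_bias,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 speed_floor = speed_floor,
                 wall_margin = wall_margin,
                 recovery_duration = recovery_duration,
                 rotation_speed = rotation_speed,
                 align_tolerance = align_tolerance),
            class = "agent_params")
}

#' Default generative parameters for each behavioural condition
#'
#' @param condition one of `"novice"`, `"expert"`, `"dMUS"`, `"iMUS"`,
#'   `"probe"`.
#' @param ... named fields overriding the condition defaults (e.g.
#'   `kappa_align`, `p_low_target`, `speed_mean`).
#' @return an object of class `agent_params`.
#' @examples
#' default_params("expert")$p_low_target       # 0
#' default_params("novice")$rotate_at_start    # FALSE
#' @export
default_params <- function(condition, ...) {
  base <- switch(condition,
    novice = list(kappa_align = 2, p_low_target = 0.3, kappa_run = 60,
                  rotate_at_start = FALSE, p_reorient_success = 0.3,
                  turn_bias = "none"),
    expert = list(kappa_align = 40, p_low_target = 0, kappa_run = 200,
                  rotate_at_start = TRUE, p_reorient_success = 0.9,
                  turn_bias = "ccw"),
    dMUS = list(kappa_align = 8, p_low_target = 0, kappa_run = 100,
                rotate_at_start = TRUE, p_reorient_success = 0.6,
                turn_bias = "ccw"),
    iMUS = list(kappa_align = 1.5, p_low_target = 0.2, kappa_run = 60,
                rotate_at_start = TRUE, p_reorient_success = 0.3,
                turn_bias = "ccw"),
    probe = list(kappa_align = 0, p_low_target = 0, kappa_run = 150,
                 rotate_at_start = FALSE, p_reorient_success = 1,
                 turn_bias = "none"),
    stop("unknown condition: ", condition)
  )
  args <- modifyList(base, list(...))
  do.call(new_agent_params, c(list(condition = condition), args))
}

# truncated-normal per-trial running speed
draw_speed <- function(params) {
  for (i in 1:100) {
    s <- rnorm(1, params$speed_mean, params$speed_sd)
    if (s >= params$speed_floor) return(s)
  }
  params$speed_floor
}

new_trial <- function(samples, start_direction, outcome, reward_drops, bumps,
                      condition, goal_zone = NA_character_, side = NA_character_,
                      beacon = NULL, trial_id = NA_integer_,
                      session_id = NA_character_, subject_id = NA_character_) {
  structure(list(trial_id = trial_id, session_id = session_id,
                 subject_id = subject_id, condition = condition,
                 start_direction = start_direction, samples = samples,
                 outcome = outcome, reward_drops = reward_drops,
                 bumps = bumps, goal_zone = goal_zone, side = side,
                 beacon = beacon),
            class = "vr_trial")
}

# in-place scene rotation from `from` toward `to` under a turn bias, at
# `rotation_speed` deg/s; the final sample snaps exactly onto `to`.
rotation_angles <- function(from, to, bias, rotation_speed, dt) {
  step <- rotation_speed * dt
  if (bias == "ccw") {        # counterclockwise = decreasing arena angle
    gap <- wrap360(from - to); dirn <- -1
  } else if (bias == "cw") {
    gap <- wrap360(to - from); dirn <- 1
  } else {
    sg <- signed_diff(to, from); gap <- abs(sg); dirn <- sign(sg)
  }
  nfull <- floor(gap / step)
  ang <- if (nfull > 0) from + dirn * step * seq_len(nfull) else numeric(0)
  wrap360(c(ang, to))
}

#' Simulate one trial of the main place-preference task
#'
#' The trial runs in two phases. If the agent rotates at start, the scene
#' first turns in place (per `turn_bias`, at `rotation_speed` deg/s) onto a
#' goal angle drawn as the target-zone centre plus von Mises
#' (`kappa_align`) noise; the target is the low-value zone with probability
#' `p_low_target`, else the high-value zone. The agent then runs forward at
#' a per-trial speed, each step's heading jittered by von Mises
#' (`kappa_run`) noise. Hitting the arena wall records a bump, pauses for
#' `recovery_duration` s, and reorients either toward the goal zone (with
#' probability `p_reorient_success`) or toward a random interior point. The
#' trial ends on reward-zone entry or at `config$trial_timeout`.
#'
#' @param params an `agent_params` object.
#' @param config a main-task `arena_config`.
#' @param start_direction one of `config$start_directions` (degrees).
#' @param seed integer seed; the trial is deterministic given the seed.
#' @return an object of class `vr_trial` with fields `samples`
#'   (data.frame `t`, `x`, `y`, `scene_dir`), `outcome`
#'   (`high`/`low`/`timeout`), `reward_drops`, and `bumps` (sample indices
#'   of wall contacts).
#' @export
simulate_trial <- function(params, config, start_direction, seed) {
  if (!identical(config$task, "main"))
    stop("simulate_trial() expects a main-task config; see simulate_probe_trial()")
  if (!any(circular_deviation(start_direction, config$start_directions) < 1e-9))
    stop("invalid start direction: ", start_direction)
  set.seed(as.integer(seed %% .Machine$integer.max))
  dt <- 1 / config$sample_rate
  speed <- draw_speed(params)
  x0 <- config$start_position[1]; y0 <- config$start_position[2]

  goal_zone <- if (runif(1) < params$p_low_target) "low" else "high"
  zc <- config$zones[[goal_zone]]$center_angle
  goal_angle <- wrap360(zc + signed180(rvonmises(1, 0, params$kappa_align)))

  ts <- list(0); xs <- list(x0); ys <- list(y0); sc <- list(start_direction)
  tcur <- 0

  if (params$rotate_at_start &&
      circular_deviation(start_direction, goal_angle) > 1e-9) {
    ang <- rotation_angles(start_direction, goal_angle, params$turn_bias,
                           params$rotation_speed, dt)
    ts <- c(ts, list(tcur + dt * seq_along(ang)))
    xs <- c(xs, list(rep(x0, length(ang))))
    ys <- c(ys, list(rep(y0, length(ang))))
    sc <- c(sc, list(ang))
    tcur <- tcur + dt * length(ang)
  }

  heading <- if (params$rotate_at_start) goal_angle else start_direction
  pos <- c(x0, y0)
  margin_r <- config$arena_radius - params$wall_margin
  zh <- config$zones$high; zl <- config$zones$low
  bumps <- integer(0)
  outcome <- "timeout"
  chunk <- 2L * config$sample_rate

  while (tcur < config$trial_timeout - 1e-9) {
    k <- min(chunk, ceiling((config$trial_timeout - tcur) / dt - 1e-9))
    if (k <= 0) break
    noise <- signed180(rvonmises(k, 0, params$kappa_run))
    hd <- wrap360(heading + noise)
    rr_ <- deg2rad(hd)
    px <- pos[1] + cumsum(speed * dt * cos(rr_))
    py <- pos[2] + cumsum(speed * dt * -sin(rr_))
    rad <- sqrt(px^2 + py^2)
    aa <- arena_angle_from_xy(px, py)
    in_hi <- rad >= zh$inner_radius & rad <= zh$outer_radius &
      circular_deviation(aa, zh$center_angle) <= zh$angular_halfwidth
    in_lo <- rad >= zl$inner_radius & rad <= zl$outer_radius &
      circular_deviation(aa, zl$center_angle) <= zl$angular_halfwidth
    i_zone <- which(in_hi | in_lo)[1]
    i_wall <- which(rad >= margin_r)[1]

    if (!is.na(i_zone) && (is.na(i_wall) || i_zone <= i_wall)) {
      idx <- seq_len(i_zone)
      ts <- c(ts, list(tcur + dt * idx))
      xs <- c(xs, list(px[idx])); ys <- c(ys, list(py[idx]))
      sc <- c(sc, list(hd[idx]))
      outcome <- if (in_hi[i_zone]) "high" else "low"
      break
    }
    if (!is.na(i_wall)) {
      idx <- seq_len(i_wall)
      scale <- margin_r / rad[i_wall]
      px[i_wall] <- px[i_wall] * scale; py[i_wall] <- py[i_wall] * scale
      ts <- c(ts, list(tcur + dt * idx))
      xs <- c(xs, list(px[idx])); ys <- c(ys, list(py[idx]))
      sc <- c(sc, list(hd[idx]))
      tcur <- tcur + dt * i_wall
      n_samples <- sum(lengths(ts))
      bumps <- c(bumps, n_samples)
      pos <- c(px[i_wall], py[i_wall])
      # recovery pause: stationary samples after the bump
      n_pause <- min(round(params$recovery_duration * config$sample_rate),
                     max(0, floor((config$trial_timeout - tcur) / dt)))
      if (n_pause > 0) {
        ts <- c(ts, list(tcur + dt * seq_len(n_pause)))
        xs <- c(xs, list(rep(pos[1], n_pause)))
        ys <- c(ys, list(rep(pos[2], n_pause)))
        sc <- c(sc, list(rep(hd[i_wall], n_pause)))
        tcur <- tcur + dt * n_pause
      }
      # reorientation: toward the goal zone on success, else toward a
      # uniform random interior point
      if (runif(1) < params$p_reorient_success) {
        zg <- config$zones[[goal_zone]]
        rmid <- (zg$inner_radius + zg$outer_radius) / 2
        target <- rmid * unit_from_arena(zg$center_angle)[1, ]
      } else {
        rt <- config$perimeter_radius * sqrt(runif(1))
        at <- runif(1, 0, 360)
        target <- rt * unit_from_arena(at)[1, ]
      }
      heading <- arena_angle_from_xy(target[1] - pos[1], target[2] - pos[2])
      next
    }
    ts <- c(ts, list(tcur + dt * seq_len(k)))
    xs <- c(xs, list(px)); ys <- c(ys, list(py)); sc <- c(sc, list(hd))
    tcur <- tcur + dt * k
    pos <- c(px[k], py[k])
  }

  samples <- data.frame(t = unlist(ts), x = unlist(xs), y = unlist(ys),
                        scene_dir = unlist(sc))
  drops <- switch(outcome, high = config$zones$high$reward_drops,
                  low = config$zones$low$reward_drops, 0L)
  new_trial(samples, start_direction, outcome, drops, bumps,
            condition = params$condition, goal_zone = goal_zone)
}

# deterministic per-trial seed derived from (session seed, trial index)
trial_seed <- function(session_seed, i) {
  (as.numeric(session_seed) * 48271 + i * 16807) %% 2147483647
}

#' Simulate a full session of the main task
#'
#' Start directions are drawn as shuffled balanced blocks of the six
#' options, so with `n_trials` divisible by 6 every direction appears
#' equally often. Trials are simulated independently with per-trial seeds
#' derived from the session seed, so sessions are reproducible.
#'
#' @param params an `agent_params` object.
#' @param config a main-task `arena_config`.
#' @param n_trials number of trials (60 pre-training, 40 post-training).
#' @param seed integer session seed.
#' @param subject_id,condition,day session metadata carried into outputs.
#' @return an object of class `vr_session` (list of `vr_trial`s plus
#'   metadata).
#' @export
simulate_session <- function(params, config, n_trials = 60, seed = 1,
                             subject_id = "s1", condition = params$condition,
                             day = 1L) {
  if (n_trials <= 0) stop("n_trials must be positive")
  set.seed(as.integer(seed %% .Machine$integer.max))
  dirs <- config$start_directions
  nblock <- n_trials %/% length(dirs)
  rem <- n_trials %% length(dirs)
  starts <- c(unlist(lapply(seq_len(nblock), function(i) sample(dirs))),
              if (rem > 0) sample(dirs, rem))
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    tr <- simulate_trial(params, config, starts[i], trial_seed(seed, i))
    tr$trial_id <- i
    tr$subject_id <- subject_id
    tr$session_id <- sprintf("%s_%s_d%02d", subject_id, condition, day)
    trials[[i]] <- tr
  }
  structure(list(trials = trials, subject_id = subject_id,
                 condition = condition, day = day, seed = seed),
            class = "vr_session")
}

#' Simulate one trial of the object-guided (probe) task
#'
#' A beacon-homing agent: the heading aims at the beacon with von Mises
#' (`kappa_run`) per-step noise; wall contacts are recorded as bumps and
#' followed by re-aiming at the beacon. The trial ends when the agent
#' enters the 0.4 m-radius disc around the beacon or at the 60 s timeout.
#' Left trials are simulated as exact mirror images of right trials, so
#' identical seeds give mirror-symmetric trajectories.
#'
#' @param params an `agent_params` object (typically
#'   `default_params("probe")`).
#' @param config a probe-task `arena_config` from [build_probe_arena()].
#' @param side `"left"` or `"right"` beacon position.
#' @param seed integer seed.
#' @return a `vr_trial`; `outcome` is `"high"` when the beacon zone is
#'   reached (rewards are equal on both sides), `"timeout"` otherwise.
#' @export
simulate_probe_trial <- function(params, config, side = c("right", "left"),
                                 seed = 1) {
  side <- match.arg(side)
  if (!identical(config$task, "probe"))
    stop("simulate_probe_trial() expects a probe-task config")
  set.seed(as.integer(seed %% .Machine$integer.max))
  dt <- 1 / config$sample_rate
  speed <- draw_speed(params)
  beacon <- config$beacon_positions$right   # canonical frame; mirror at end
  pos <- config$start_position
  start_direction <- config$start_directions[1]
  margin_r <- config$arena_radius - params$wall_margin
  heading <- arena_angle_from_xy(beacon[1] - pos[1], beacon[2] - pos[2])
  ts <- list(0); xs <- list(pos[1]); ys <- list(pos[2]); sc <- list(heading)
  tcur <- 0; bumps <- integer(0); outcome <- "timeout"
  chunk <- 2L * config$sample_rate

  while (tcur < config$trial_timeout - 1e-9) {
    k <- min(chunk, ceiling((config$trial_timeout - tcur) / dt - 1e-9))
    if (k <= 0) break
    noise <- signed180(rvonmises(k, 0, params$kappa_run))
    hd <- wrap360(heading + noise)
    rr_ <- deg2rad(hd)
    px <- pos[1] + cumsum(speed * dt * cos(rr_))
    py <- pos[2] + cumsum(speed * dt * -sin(rr_))
    dist_b <- sqrt((px - beacon[1])^2 + (py - beacon[2])^2)
    i_zone <- which(dist_b <= config$reward_zone_radius)[1]
    i_wall <- which(sqrt(px^2 + py^2) >= margin_r)[1]
    if (!is.na(i_zone) && (is.na(i_wall) || i_zone <= i_wall)) {
      idx <- seq_len(i_zone)
      ts <- c(ts, list(tcur + dt * idx))
      xs <- c(xs, list(px[idx])); ys <- c(ys, list(py[idx]))
      sc <- c(sc, list(hd[idx]))
      outcome <- "high"
      break
    }
    if (!is.na(i_wall)) {
      idx <- seq_len(i_wall)
      rad <- sqrt(px[i_wall]^2 + py[i_wall]^2)
      px[i_wall] <- px[i_wall] * margin_r / rad
      py[i_wall] <- py[i_wall] * margin_r / rad
      ts <- c(ts, list(tcur + dt * idx))
      xs <- c(xs, list(px[idx])); ys <- c(ys, list(py[idx]))
      sc <- c(sc, list(hd[idx]))
      tcur <- tcur + dt * i_wall
      bumps <- c(bumps, sum(lengths(ts)))
      pos <- c(px[i_wall], py[i_wall])
      n_pause <- min(round(params$recovery_duration * config$sample_rate),
                     max(0, floor((config$trial_timeout - tcur) / dt)))
      if (n_pause > 0) {
        ts <- c(ts, list(tcur + dt * seq_len(n_pause)))
        xs <- c(xs, list(rep(pos[1], n_pause)))
        ys <- c(ys, list(rep(pos[2], n_pause)))
        sc <- c(sc, list(rep(hd[i_wall], n_pause)))
        tcur <- tcur + dt * n_pause
      }
      heading <- arena_angle_from_xy(beacon[1] - pos[1], beacon[2] - pos[2])
      next
    }
    ts <- c(ts, list(tcur + dt * seq_len(k)))
    xs <- c(xs, list(px)); ys <- c(ys, list(py)); sc <- c(sc, list(hd))
    tcur <- tcur + dt * k
    pos <- c(px[k], py[k])
  }

  samples <- data.frame(t = unlist(ts), x = unlist(xs), y = unlist(ys),
                        scene_dir = unlist(sc))
  beacon_used <- beacon
  if (side == "left") {   # reflect across the north-south axis
    samples$x <- -samples$x
    samples$scene_dir <- wrap360(180 - samples$scene_dir)
    beacon_used <- c(-beacon[1], beacon[2])
  }
  new_trial(samples, start_direction, outcome,
            reward_drops = if (outcome == "high") 2L else 0L,
            bumps = bumps, condition = params$condition, side = side,
            beacon = beacon_used)
}

#' Simulate a probe-task session
#'
#' Left/right beacon sides are balanced in shuffled blocks of two.
#'
#' @inheritParams simulate_session
#' @param config a probe-task `arena_config`.
#' @return a `vr_session` of probe trials.
#' @export
simulate_probe_session <- function(params, config, n_trials = 40, seed = 1,
                                   subject_id = "s1",
                                   condition = params$condition, day = 1L) {
  if (n_trials <= 0) stop("n_trials must be positive")
  set.seed(as.integer(seed %% .Machine$integer.max))
  nblock <- n_trials %/% 2; rem <- n_trials %% 2
  sides <- c(unlist(lapply(seq_len(nblock),
                           function(i) sample(c("left", "right")))),
             if (rem > 0) sample(c("left", "right"), rem))
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    tr <- simulate_probe_trial(params, config, sides[i], trial_seed(seed, i))
    tr$trial_id <- i
    tr$subject_id <- subject_id
    tr$session_id <- sprintf("%s_%s_probe_d%02d", subject_id, condition, day)
    trials[[i]] <- tr
  }
  structure(list(trials = trials, subject_id = subject_id,
                 condition = condition, day = day, seed = seed),
            class = "vr_session")
}

#' @export
print.vr_trial <- function(x, ...) {
  cat(sprintf("<vr_trial %s: start %g deg, outcome %s, %d samples, %d bumps>\n",
              x$condition, x$start_direction, x$outcome, nrow(x$samples),
              length(x$bumps)))
  invisible(x)
}

#' @export
print.vr_session <- function(x, ...) {
  oc <- table(vapply(x$trials, function(t) t$outcome, character(1)))
  cat(sprintf("<vr_session %s %s day %d: %d trials (%s)>\n", x$subject_id,
              x$condition, x$day, length(x$trials),
              paste(names(oc), oc, sep = "=", collapse = ", ")))
  invisible(x)
}
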