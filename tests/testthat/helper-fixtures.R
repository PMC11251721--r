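# Hand-constructed trajectory fixtures (no simulator involved), used to
# test the metric extractors against known geometry.

# straight ray from the centre along an arena-frame angle, constant speed
straight_ray_trial <- function(angle, r_max = 0.7, speed = 0.1, dt = 1 / 60,
                               outcome = "high") {
  n <- ceiling(r_max / (speed * dt))
  d <- speed * dt * (0:n)
  rad <- angle * pi / 180
  samples <- data.frame(t = dt * (0:n),
                        x = d * cos(rad), y = d * -sin(rad),
                        scene_dir = rep(angle, n + 1))
  structure(list(trial_id = 1L, session_id = "fx", subject_id = "fx",
                 condition = "fixture", start_direction = angle,
                 samples = samples, outcome = outcome,
                 reward_drops = if (outcome == "high") 12L else 0L,
                 bumps = integer(0), goal_zone = "high",
                 side = NA_character_, beacon = NULL),
            class = "vr_trial")
}

# trial built from explicit sample coordinates
path_trial <- function(x, y, t = seq_along(x) / 60, scene = NULL,
                       outcome = "high", start_direction = 270,
                       bumps = integer(0), beacon = NULL) {
  if (is.null(scene)) {
    scene <- c(atan2(-diff(y), diff(x)) * 180 / pi, 0) %% 360
    scene[length(scene)] <- scene[length(scene) - 1]
  }
  structure(list(trial_id = 1L, session_id = "fx", subject_id = "fx",
                 condition = "fixture", start_direction = start_direction,
                 samples = data.frame(t = t, x = x, y = y, scene_dir = scene),
                 outcome = outcome, reward_drops = 0L, bumps = bumps,
                 goal_zone = NA_character_, side = NA_character_,
                 beacon = beacon),
            class = "vr_trial")
}

# resample a trial's trajectory at k-fold density by linear interpolation
densify_trial <- function(trial, k = 10) {
  sm <- trial$samples
  n <- nrow(sm)
  tt <- approx(seq_len(n), sm$t, n = (n - 1) * k + 1)$y
  trial$samples <- data.frame(
    t = tt,
    x = approx(sm$t, sm$x, xout = tt)$y,
    y = approx(sm$t, sm$y, xout = tt)$y,
    scene_dir = approx(sm$t, sm$scene_dir, xout = tt)$y)
  trial
}

# synthetic per-subject summary table for merge/compare tests
fake_summary_df <- function(subjects, condition, visit, crossings, speed) {
  data.frame(subject_id = subjects, condition = condition,
             high_visit_pct = visit, mean_crossings = crossings,
             mean_speed = speed, stringsAsFactors = FALSE)
}
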