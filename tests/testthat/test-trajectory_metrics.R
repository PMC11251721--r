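cfg <- build_main_arena()

test_that("DD and PCD of a straight ray equal the ray angle", {
  for (ang in c(200, 170, 45.5)) {
    tr <- straight_ray_trial(ang)
    expect_equal(departing_direction(tr, cfg), ang, tolerance = 1e-8)
    expect_equal(perimeter_crossing_direction(tr, cfg), ang, tolerance = 1e-8)
    expect_equal(dd_deviation(tr, cfg), circular_deviation(ang, 180),
                 tolerance = 1e-8)
    expect_equal(nrow(perimeter_crossings(tr, cfg)), 1)
  }
})

test_that("crossing angles are interpolated between bracketing samples", {
  # two-sample jump across the departure circle: from angle 10 (inside) to
  # angle 30 (outside); expected value frozen from a dense brute-force
  # resampling of the same segment
  p0 <- 0.05 * c(cos(-10 * pi / 180), sin(-10 * pi / 180))
  p1 <- 0.30 * c(cos(-30 * pi / 180), sin(-30 * pi / 180))
  tr <- path_trial(c(0, p0[1], p1[1]), c(0, p0[2], p1[2]), scene = c(0, 0, 0))
  dd <- departing_direction(tr, cfg)
  dense <- densify_trial(tr, 2000)
  sm <- dense$samples
  i <- which(sqrt(sm$x^2 + sm$y^2) >= cfg$departure_circle_radius)[1]
  brute <- (-atan2(sm$y[i], sm$x[i]) * 180 / pi) %% 360
  expect_equal(dd, brute, tolerance = 0.05)
  expect_equal(dd, 22.194912, tolerance = 1e-4)  # frozen brute-force value
})

test_that("DD/PCD are stable under 10x dense resampling", {
  p <- default_params("dMUS")
  for (s in 1:5) {
    tr <- simulate_trial(p, cfg, 315, seed = 400 + s)
    tr10 <- densify_trial(tr, 10)
    expect_lt(abs(circular_deviation(departing_direction(tr, cfg),
                                     departing_direction(tr10, cfg))), 0.5)
    expect_lt(abs(circular_deviation(perimeter_crossing_direction(tr, cfg),
                                     perimeter_crossing_direction(tr10, cfg))),
              0.5)
  }
})

test_that("perimeter crossings count only inside-to-outside transitions", {
  # path: out to 0.7, back in to 0.5, out again to 0.75 (along East)
  xs <- c(seq(0, 0.7, by = 0.01), seq(0.69, 0.5, by = -0.01),
          seq(0.51, 0.75, by = 0.01))
  tr <- path_trial(xs, rep(0, length(xs)), outcome = "low")
  expect_equal(nrow(perimeter_crossings(tr, cfg)), 2)
  expect_equal(perimeter_crossing_direction(tr, cfg), 0)  # first touch only
  # trajectory confined inside the perimeter has none, and PCD errors
  tr_in <- path_trial(seq(0, 0.3, by = 0.01), rep(0, 31), outcome = "timeout")
  expect_equal(nrow(perimeter_crossings(tr_in, cfg)), 0)
  expect_error(perimeter_crossing_direction(tr_in, cfg), "PCD undefined")
  expect_error(departing_direction(
    path_trial(c(0, 0.01), c(0, 0), outcome = "timeout"), cfg), "undefined")
})

test_that("scene rotation trace is normalized, continuous and oriented", {
  p <- default_params("expert", kappa_align = Inf, kappa_run = Inf)
  tr <- simulate_trial(p, cfg, 315, seed = 1)
  trace <- scene_rotation_trace(tr, cfg)
  expect_equal(trace$normalized_distance[1], 0)
  expect_equal(trace$normalized_distance[nrow(trace)], 1)
  expect_true(all(diff(trace$normalized_distance) >= 0))
  expect_true(all(abs(diff(trace$scene_direction)) <= 180))
  # ccw alignment from NE (315) to the high zone: monotone decreasing
  expect_true(all(diff(trace$scene_direction) <= 1e-9))
  expect_equal(trace$scene_direction[1], 315)
  expect_equal(trace$scene_direction[nrow(trace)], 180, tolerance = 1e-6)
  # novice noise-free: flat trace at the start direction
  tr_n <- simulate_trial(default_params("novice", kappa_run = Inf), cfg, 270, 2)
  tn <- scene_rotation_trace(tr_n, cfg)
  expect_equal(range(tn$scene_direction), c(270, 270))
})

test_that("unwrapping takes the minimal jump across the 0/360 seam", {
  tr <- path_trial(c(0, 0.05, 0.1, 0.15), c(0, 0, 0, 0),
                   scene = c(359, 1, 3, 5), outcome = "timeout")
  u <- scene_rotation_trace(tr, cfg)
  expect_equal(diff(u$scene_direction)[1], 2)  # +2, not -358
})

test_that("first turn direction uses a threshold on the excursion", {
  flat <- path_trial(c(0, 0.1, 0.2), c(0, 0, 0), scene = c(90, 94, 86),
                     outcome = "timeout")
  expect_equal(first_turn_direction(flat, threshold = 10), "none")
  ccw <- path_trial(rep(0, 30), rep(0, 30), scene = (315 - 2 * (0:29)) %% 360,
                    outcome = "timeout")
  expect_equal(first_turn_direction(ccw, threshold = 10), "ccw")
  cw <- path_trial(rep(0, 30), rep(0, 30), scene = (10 + 2 * (0:29)) %% 360,
                   outcome = "timeout")
  expect_equal(first_turn_direction(cw, threshold = 10), "cw")
})

test_that("path lengths match analytic geometry", {
  tr <- straight_ray_trial(170, r_max = 0.62)
  pl <- path_lengths(tr, cfg)
  expect_equal(pl$travel_distance, 0.62, tolerance = 2e-3)
  expect_equal(pl$excess_travel_distance, 0, tolerance = 2e-3)
  expect_equal(pl$mean_speed, 10, tolerance = 0.1)   # 0.1 m/s in cm/s
  # semicircular detour from (0,0) to (0.62, 0): arc length = pi*r vs the
  # straight chord 0.62 -> excess = pi*0.31 - 0.62
  th <- seq(pi, 0, length.out = 2000)
  xs <- 0.31 + 0.31 * cos(th); ys <- 0.31 * sin(th)
  tr2 <- path_trial(xs, ys, outcome = "low")
  pl2 <- path_lengths(tr2, cfg)
  expect_equal(pl2$travel_distance, pi * 0.31, tolerance = 1e-4)
  expect_equal(pl2$excess_travel_distance, pi * 0.31 - 0.62, tolerance = 1e-4)
  # timeout: excess undefined, travel still computed
  tr3 <- path_trial(c(0, 0.1), c(0, 0), outcome = "timeout")
  pl3 <- path_lengths(tr3, cfg)
  expect_true(is.na(pl3$excess_travel_distance))
  expect_equal(pl3$travel_distance, 0.1)
})

test_that("metric extraction is invariant to time rescaling except rates", {
  p <- default_params("dMUS")
  tr <- simulate_trial(p, cfg, 45, seed = 77)
  tr2 <- tr
  tr2$samples$t <- tr$samples$t * 2
  m1 <- trial_metrics(tr, cfg); m2 <- trial_metrics(tr2, cfg)
  expect_equal(m2$departing_direction, m1$departing_direction)
  expect_equal(m2$perimeter_crossing_direction, m1$perimeter_crossing_direction)
  expect_equal(m2$travel_distance, m1$travel_distance)
  expect_equal(m2$latency, 2 * m1$latency)
  expect_equal(m2$mean_speed, m1$mean_speed / 2)
})

test_that("probe trials classify as direct hit or failed", {
  pc <- build_probe_arena()
  pp <- default_params("probe")
  ok <- simulate_probe_trial(pp, pc, "right", seed = 2)
  expect_equal(classify_probe_trial(ok, pc), "direct_hit")
  bumped <- ok; bumped$bumps <- c(5L)
  expect_equal(classify_probe_trial(bumped, pc), "failed")
  to <- ok; to$outcome <- "timeout"; to$bumps <- integer(0)
  expect_equal(classify_probe_trial(to, pc), "failed")
  expect_error(classify_probe_trial(ok, cfg), "probe-task config")
})

test_that("completed trials satisfy the distance invariants", {
  p <- default_params("iMUS")
  s <- simulate_session(p, cfg, n_trials = 12, seed = 31)
  m <- session_metrics(s, cfg)
  done <- m$outcome != "timeout"
  expect_true(all(m$travel_distance[done] >= 0.62 - 1e-6))
  expect_true(all(m$excess_travel_distance[done] >= -1e-6))
  expect_true(all(m$n_perimeter_crossings[done] >= 1))
  expect_true(all(m$dd_deviation <= 180 & m$dd_deviation >= 0, na.rm = TRUE))
})
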