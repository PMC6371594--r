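test_that("intended-target inference minimizes the approach angle", {
  ts <- target_set(rbind(c(0.5, 0, 0), c(0, 0.5, 0)))
  p0 <- c(0, 0, 0.2)  # off-origin start so directions are well defined
  expect_equal(infer_intended_target(c(0.9, 0.1, 0), p0, ts), 1L)
  expect_equal(infer_intended_target(c(0.1, 0.9, 0), p0, ts), 2L)
  # exact bisector: documented tie-break to the lowest id
  expect_equal(infer_intended_target(c(1, 1, 0) / sqrt(2), c(0, 0, 0.2), ts),
               1L)
  # zero velocity carries no intent
  expect_true(is.na(infer_intended_target(c(0, 0, 0), p0, ts)))
  # coincident target is reported as reached
  expect_equal(infer_intended_target(c(1, 0, 0), c(0, 0.5, 0), ts), 2L)
})

test_that("inference matches a brute-force arccos oracle", {
  set.seed(321)
  lay <- test_layout()
  ts <- lay$targets
  for (i in 1:2000) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    p <- lay$start_position + rnorm(3, sd = 0.05)
    ang <- apply(ts$positions, 1, function(t) {
      d <- t - p
      acos(sum(v * d) / sqrt(sum(d^2)))
    })
    expect_equal(infer_intended_target(v, p, ts),
                 ts$ids[which.min(ang)])
  }
})

test_that("the attraction step lands exactly on the intended target", {
  # q = 0 puts the end-effector at (0.85, 0, 0); the goal configuration of
  # a target at (0, 0.85, 0) is (pi/2, 0, 0)
  ts <- target_set(rbind(c(0, 0.85 - 1e-9, 0), c(0.5, -0.2, 0.1)))
  dx <- attract(c(0, 0, 0), 1L, ts)
  expect_equal(dx, c(-0.85, 0.85, 0), tolerance = 1e-6)
  # coincident target: zero ideal vector
  p <- arm_forward(c(0.3, 0.2, 0.4))$position
  ts2 <- target_set(rbind(p, c(0.5, 0, 0)))
  expect_lt(max(abs(attract(c(0.3, 0.2, 0.4), 1L, ts2))), 1e-9)
  expect_error(attract(c(0, 0, 0), 99L, ts), "not in the target set")
})

test_that("attraction identity holds over random configuration-target pairs", {
  set.seed(55)
  for (i in 1:200) {
    q <- c(runif(1, -pi, pi), runif(2, -1, 1))
    tpos <- rbind(c(runif(1, 0.3, 0.7), runif(1, -0.3, 0.3),
                    runif(1, -0.3, 0.3)),
                  c(0.5, 0.3, -0.1))
    ts <- target_set(tpos)
    pos <- arm_forward(q)$position
    dx <- attract(q, 1L, ts)
    expect_lt(max(abs(dx - (tpos[1, ] - pos))), 1e-12)
  }
})

test_that("blending follows the closed forms at the alpha limits", {
  v <- c(0.01, -0.02, 0.005); u <- c(-1, 2, 0.5)
  expect_equal(blend(v, u, alpha = 0), 1.5 * v)
  expect_equal(blend(v, u, alpha = 1),
               1.5 * sqrt(sum(v^2)) * u / sqrt(sum(u^2)))
  expect_equal(blend(c(1, 0, 0), c(0, 2, 0), 0.5), c(0.75, 0.75, 0))
  expect_error(blend(v, u, alpha = 1.2), "alpha")
  expect_error(blend(v, c(0, 0, 0), alpha = 0.5), "ideal")
  # alpha = 0 tolerates an undefined ideal direction
  expect_equal(blend(v, c(0, 0, 0), alpha = 0), 1.5 * v)
})

test_that("blend norm and plane contracts hold for random triples", {
  set.seed(99)
  for (i in 1:500) {
    v <- rnorm(3) * 0.01; u <- rnorm(3); a <- runif(1)
    dx <- blend(v, u, a)
    expect_lte(sqrt(sum(dx^2)), 1.5 * sqrt(sum(v^2)) + 1e-12)
    # blended vector stays in span{decoded, ideal}
    n <- c(v[2] * u[3] - v[3] * u[2], v[3] * u[1] - v[1] * u[3],
           v[1] * u[2] - v[2] * u[1])
    expect_lt(abs(sum(dx * n)), 1e-12)
  }
})

test_that("volition is preserved when the decoded command is orthogonal", {
  v <- c(0.01, 0, 0); u <- c(0, 1, 0)   # decoded orthogonal to ideal
  for (a in c(0.2, 0.5, 0.9)) {
    dx <- blend(v, u, a)
    expect_gt(sum(dx * v), 0)
  }
  # at alpha = 1 the decoded contribution vanishes entirely
  expect_equal(sum(blend(v, u, 1) * v), 0)
})

test_that("inertia mixes the current and previous compensation vectors", {
  p <- c(0.4, 0, -0.1)
  dx <- c(0.01, 0.005, -0.002); prev <- c(-0.004, 0.002, 0.01)
  # beta = 1: no inertia
  s1 <- control_step(p, dx, beta = 1, previous = prev)
  expect_equal(s1$displacement, dx)
  # beta = 0: pure inertia, displacement equals the previous vector
  s0 <- control_step(p, dx, beta = 0, previous = prev)
  expect_equal(s0$displacement, prev)
  # first applied step ignores inertia regardless of beta
  sf <- control_step(p, dx, beta = 0.3, previous = NULL)
  expect_equal(sf$displacement, dx)
  # constant stream: the recursion's fixed point is the constant itself
  s <- control_step(p, dx, beta = 0.4, previous = dx)
  expect_equal(s$displacement, dx)
  # new configuration is consistent with the new position
  expect_equal(arm_forward(s1$config)$position, s1$position,
               tolerance = 1e-9)
  expect_error(control_step(p, dx, beta = 2), "beta")
})

test_that("steps leaving the workspace are clamped at the boundary", {
  p <- c(0.84, 0, 0)
  st <- control_step(p, c(0.1, 0, 0), beta = 1)
  expect_true(st$clamped)
  expect_lte(sqrt(sum(st$position^2)), 0.85)
  expect_gt(sqrt(sum(st$position^2)), 0.849)
})

test_that("a zero-velocity stream holds position for the whole trial", {
  lay <- test_layout()
  vel <- matrix(0, 10, 3)
  tr <- run_trial(vel, lay$targets, shared_control_params(0.6, 0.6),
                  lay$start_config)
  expect_true(all(tr$gated))
  expect_equal(nrow(tr$waypoints), 11)
  for (k in 1:11)
    expect_equal(tr$waypoints[k, ], lay$start_position, tolerance = 1e-9)
  # empty trajectory: just the start waypoint
  tr0 <- run_trial(matrix(numeric(0), 0, 3), lay$targets,
                   shared_control_params(1, 1), lay$start_config)
  expect_equal(nrow(tr0$waypoints), 1)
})

test_that("with compensation off the waypoints integrate the decoded stream", {
  lay <- test_layout()
  tpos <- lay$targets$positions[1, ]
  # noise-free straight-line decoded velocities toward target 1
  dir <- (tpos - lay$start_position) /
    sqrt(sum((tpos - lay$start_position)^2))
  vel <- matrix(rep(dir * 0.005, each = 20), 20, 3)
  tr <- run_trial(vel, lay$targets,
                  shared_control_params(0, 1, reach_tolerance = 0),
                  lay$start_config)
  expected <- integrate_raw(vel, lay$start_position, scale = 1.5)
  expect_equal(tr$waypoints, expected, tolerance = 1e-9)
})

test_that("full compensation closes in on the intended target monotonically", {
  lay <- test_layout()
  spec <- trajectory_spec(trials_per_direction = 1, seed = 19,
                          angular_noise_sd = 0.7)
  trials <- generate_trials(spec, lay$targets, lay$start_position)
  for (tr in trials) {
    run <- run_trial(tr, lay$targets, shared_control_params(1, 1),
                     lay$start_config)
    # every un-gated step strictly reduces the distance to the target that
    # was intended at that step (the step points straight at it and is
    # shorter than twice the remaining distance)
    for (k in which(!run$gated)) {
      tpos <- lay$targets$positions[match(run$intended[k],
                                          lay$targets$ids), ]
      d_before <- sqrt(sum((run$waypoints[k, ] - tpos)^2))
      d_after <- sqrt(sum((run$waypoints[k + 1, ] - tpos)^2))
      s <- sqrt(sum((run$waypoints[k + 1, ] - run$waypoints[k, ])^2))
      if (s < 2 * d_before) expect_lt(d_after, d_before)
    }
  }
  # with a single candidate the reach converges to within tolerance
  one <- target_set(lay$targets$positions[1, , drop = FALSE])
  spec1 <- trajectory_spec(n_directions = 1, trials_per_direction = 3,
                           n_steps = 80, seed = 5, angular_noise_sd = 0.4)
  for (tr in generate_trials(spec1, one, lay$start_position)) {
    run <- run_trial(tr, one, shared_control_params(1, 1),
                     lay$start_config)
    expect_equal(run$reached, 1L)
  }
})

test_that("the inferred target switches when the decoded stream retargets", {
  lay <- test_layout()
  t1 <- lay$targets$positions[1, ]; t2 <- lay$targets$positions[2, ]
  d1 <- (t1 - lay$start_position) / sqrt(sum((t1 - lay$start_position)^2))
  d2 <- (t2 - lay$start_position) / sqrt(sum((t2 - lay$start_position)^2))
  vel <- rbind(matrix(rep(d1 * 0.008, each = 5), 5, 3),
               matrix(rep(d2 * 0.008, each = 10), 10, 3))
  tr <- run_trial(vel, lay$targets, shared_control_params(0.8, 1),
                  lay$start_config)
  expect_equal(tr$intended[1], 1L)
  # switches within one step of the stream change (step 6)
  expect_true(2L %in% tr$intended[6:7])
  expect_equal(tr$intended[tr$n_steps], 2L)
})

test_that("trials are deterministic in their inputs", {
  s <- small_ensemble(seed = 23, trials_per_direction = 1)
  p <- shared_control_params(0.6, 0.6)
  r1 <- run_trial(s$trials[[1]], s$layout$targets, p, s$layout$start_config)
  r2 <- run_trial(s$trials[[1]], s$layout$targets, p, s$layout$start_config)
  expect_identical(r1, r2)
})

test_that("waypoint CSV export keeps stream alignment", {
  s <- small_ensemble(seed = 29, trials_per_direction = 1, n_steps = 15)
  tr <- run_trial(s$trials[[1]], s$layout$targets,
                  shared_control_params(0.6, 0.6, reach_tolerance = 0),
                  s$layout$start_config)
  path <- withr::local_tempfile(fileext = ".csv")
  write_waypoints(tr, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), tr$n_steps + 1)
  expect_equal(df$step, 0:tr$n_steps)
  expect_equal(df$x[1], tr$start_position[1])
})
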