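test_that("differential-drive kinematics: straight motion, turn direction, closed-form arc", {
  kin <- list(V = 1, c = 1, axle_width = 5.3)
  p0 <- robot_pose(0, -130, 0.3)

  # equal wheel speeds: pure forward translation
  p1 <- step_kinematics(p0, 0.5, kin)
  expect_equal(p1[["heading"]], 0.3)
  expect_equal(p1[["x"]], cos(0.3))
  expect_equal(p1[["y"]], -130 + sin(0.3))

  # u > 0.5 turns left (counter-clockwise), u < 0.5 right
  expect_gt(step_kinematics(p0, 0.9, kin)[["heading"]], 0.3)
  expect_lt(step_kinematics(p0, 0.1, kin)[["heading"]], 0.3)

  # constant u traces the analytic differential-drive arc of radius
  # V * axle / (2 c (2u - 1)), up to Euler discretization error
  V <- 0.5; cc <- 0.1; u <- 0.9; L <- 5.3; n <- 200
  omega <- 2 * cc * (2 * u - 1) / L
  R <- V / omega
  arc_error <- function(dt) {
    p <- robot_pose(0, -100, pi / 2)
    k <- list(V = V, c = cc, axle_width = L, dt = dt)
    for (i in seq_len(round(n / dt))) p <- step_kinematics(p, u, k)
    cx <- 0 - R * sin(pi / 2); cy <- -100 + R * cos(pi / 2)
    thn <- pi / 2 + omega * n
    sqrt((p[["x"]] - (cx + R * sin(thn)))^2 +
         (p[["y"]] - (cy - R * cos(thn)))^2)
  }
  expect_lt(arc_error(1), 0.5)
  # Euler error vanishes with the step size
  expect_lt(arc_error(0.1), arc_error(1) / 5)

  expect_error(step_kinematics(p0, NA_real_, kin), "invalid")
  expect_error(step_kinematics(p0, 1.2, kin), "invalid")
})

test_that("collision resolution slides along walls and never ends a maze trial", {
  maze <- maze_config(timeout_steps = 200)
  kin <- list(V = 1, c = 1, axle_width = 5.3)
  # drive straight into the stem's right wall at a shallow angle
  p <- robot_pose(10, -100, pi / 4)
  for (i in 1:40) p <- step_kinematics(p, 0.5, kin, maze)
  expect_true(vtemaze:::pose_valid(p, maze))
  # slid along the wall: y kept increasing, x pinned near the wall
  expect_gt(p[["y"]], -100)
  expect_lte(p[["x"]], maze$hw_c - maze$robot$body_radius + 1e-9)
  # head-on: motion fully cancelled, heading still free
  q <- robot_pose(maze$hw_c - maze$robot$body_radius, -60, 0)
  q2 <- step_kinematics(q, 0.9, kin, maze)
  expect_equal(q2[["x"]], q[["x"]])
  expect_equal(q2[["y"]], q[["y"]])
  expect_gt(q2[["heading"]], 0)
  expect_true(attr(q2, "collided"))
})

test_that("maze configuration validates its geometry", {
  expect_error(maze_config(central_arm_width = -1), "positive")
  expect_error(maze_config(central_arm_width = 5), "narrower")
  expect_error(maze_config(cue_side = "left", reward_side = "right"), "agree")
  maze <- maze_config()
  expect_identical(maze$timeout_steps, 4000L)
  # reward and punishment occupy opposite distal ends
  expect_identical(vtemaze:::zone_at(-135, 0, maze), 1)
  expect_identical(vtemaze:::zone_at(135, 0, maze), -1)
  m2 <- vtemaze:::toggle_reward_side(maze)
  expect_identical(vtemaze:::zone_at(-135, 0, m2), -1)
  expect_identical(vtemaze:::zone_at(135, 0, m2), 1)
  expect_identical(m2$cue_side, m2$reward_side)
})

test_that("sensor channels obey their ranges on random poses and detect the right things", {
  maze <- maze_config()
  set.seed(42)
  for (i in 1:200) {
    f <- sense(random_valid_pose(maze), maze)
    expect_true(all(f$whiskers %in% c(0L, 1L)))
    expect_true(all(f$camera >= 0 & f$camera <= 1))
    expect_true(all(f$ir >= 0))
    expect_true(f$reward %in% c(-1, 0, 1))
  }
  # mid-corridor, far from cue and walls: whiskers and IR silent, no reward
  f <- sense(robot_pose(0, -70, pi / 2), maze)
  expect_identical(sum(f$whiskers), 0L)
  expect_identical(sum(f$ir), 0)
  expect_identical(f$reward, 0)
  # the reward channel fires only inside the zones
  expect_identical(sense(robot_pose(-135, 0, 0), maze)$reward, 1)
  expect_identical(sense(robot_pose(135, 0, 0), maze)$reward, -1)
  # whiskers touch the cue post when close enough, on the cue side only
  near_cue <- sense(robot_pose(-10, -18, pi / 2), maze)
  expect_gt(sum(near_cue$whiskers), 0)
  far_side <- sense(robot_pose(10, -18, pi / 2), maze)
  expect_identical(sum(far_side$whiskers), 0L)
  # IR readings grow monotonically while approaching a wall head-on
  irs <- vapply(c(20, 12, 8, 5), function(d) {
    max(sense(robot_pose(0, -maze$hw_x - maze$central_arm_length + d, -pi / 2),
              maze)$ir)
  }, numeric(1))
  expect_identical(irs[1], 0)
  expect_true(all(diff(irs) > 0))
})

test_that("camera panorama matches a dense ray-casting oracle", {
  maze <- maze_config()
  set.seed(7)
  for (i in 1:25) {
    p <- random_valid_pose(maze)
    expect_identical(sense(p, maze)$camera, camera_oracle(p, maze))
  }
})

test_that("trial termination: timeout at the exact step budget, reward before it, determinism", {
  maze <- maze_config()
  circler <- make_fixture("timeout_policy")
  rec <- run_trial(circler, maze)
  expect_identical(rec$outcome, "timeout")
  expect_identical(rec$env_steps, maze$timeout_steps)

  oracle <- make_fixture("oracle_policy")
  rec2 <- run_trial(oracle, maze)
  expect_identical(rec2$outcome, "reward")
  expect_lt(rec2$env_steps, maze$timeout_steps)

  ctrl <- hebbian_controller(benign_params())
  m2 <- maze_config(timeout_steps = 600)
  ra <- run_trial(ctrl, m2)
  rb <- run_trial(ctrl, m2)
  expect_identical(ra$trajectory, rb$trajectory)
  expect_identical(ra$neural_log, rb$neural_log)
  # neural log cadence: one tick per delta environment steps (plus the
  # closing reward tick when a zone is entered)
  expect_lte(abs(nrow(ra$neural_log) - ra$env_steps / ctrl$params$delta), 2)
})

test_that("familiarization: 20 wall-reset episodes, alternating clamps, learned IR-motor weights", {
  maze <- maze_config(timeout_steps = 1500)
  ctrl <- hebbian_controller(benign_params())
  fam <- run_familiarization(ctrl, maze)
  expect_length(fam$records, 20L)
  expect_true(all(vapply(fam$records, function(r) r$outcome, character(1)) ==
                  "wall_reset"))
  clamps <- vapply(fam$records, function(r) r$clamp_u, numeric(1))
  expect_identical(clamps, rep(c(0.2, 0.8), 10))
  # cue and reward are deactivated: the reward state stays 0, so the logged
  # reward-module v - s is exactly 1 (pinned virtual unit minus silent state)
  expect_true(all(vapply(fam$records, function(r) {
    all(r$neural_log$vs_reward == 1)
  }, logical(1))))
  expect_gt(sum(fam$controller$W[["ir->motor"]] != 0), 0)
})

test_that("sessions toggle the rewarded side every five trials and keep the protocol invariants", {
  maze <- maze_config(timeout_steps = 800)
  oracle <- make_fixture("oracle_policy")
  sess <- run_session(oracle, maze, n_trials = 12)
  sides <- vapply(sess$records, function(r) r$reward_side, character(1))
  expect_identical(sides,
                   c(rep("left", 5), rep("right", 5), rep("left", 2)))
  expect_identical(length(unique(cumsum(c(TRUE, sides[-1] != sides[-12])))),
                   as.integer(ceiling(12 / 5)))
  # ground-truth steering succeeds on every trial
  expect_identical(sess$success_rate, 100)
  # termination trichotomy
  expect_true(all(sess$outcomes %in% c("reward", "punishment", "timeout")))
  expect_error(run_session(oracle, maze, n_trials = 0), "n_trials")

  # learning off: a fixed controller repeats itself exactly within a block
  ctrl <- hebbian_controller(benign_params())
  s2 <- run_session(ctrl, maze, n_trials = 5, learning = FALSE)
  tr <- lapply(s2$records, function(r) r$trajectory)
  for (i in 2:5) expect_identical(tr[[i]], tr[[1]])
})
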