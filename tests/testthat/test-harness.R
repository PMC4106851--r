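test_that("the default start-position grid tiles the central arm with 280 cells", {
  maze <- maze_config()
  grid <- start_position_grid(maze)
  expect_identical(nrow(grid), 280L)
  expect_identical(nrow(unique(grid)), 280L)
  # every cell is a valid start inside the central arm
  ok <- vapply(seq_len(nrow(grid)), function(i) {
    p <- robot_pose(grid$x[i], grid$y[i], pi / 2)
    vtemaze:::pose_valid(p, maze) && p[["y"]] <= -maze$hw_x
  }, logical(1))
  expect_true(all(ok))
  expect_error(start_position_grid(maze, margin = 50), "margin")
})

test_that("robustness maps: perfect policies give mean 100 / variance 0; random ones match binomial theory", {
  maze <- maze_config(timeout_steps = 800)
  oracle <- make_fixture("oracle_policy")
  grid <- start_position_grid(maze, nx = 3L, ny = 4L)
  rmap <- robustness_grid(oracle, maze, grid = grid, n_trials = 3)
  expect_identical(rmap$n_positions, 12L)
  expect_equal(rmap$mean, 100)
  expect_equal(rmap$variance, 0)
  expect_true(all(rmap$grid$success_rate >= 0 & rmap$grid$success_rate <= 100))

  # i.i.d. coin-flip arm choice: success rates are Binomial(n, 1/2) shares;
  # the map mean stays within 3 standard errors of 50%
  set.seed(66)
  cmap <- robustness_grid(coin_policy(), maze, grid = grid, n_trials = 20)
  n_total <- 12 * 20
  se <- 100 * sqrt(0.25 / n_total)
  expect_lt(abs(cmap$mean - 50), 3 * se)

  bad_grid <- data.frame(x = 100, y = 0)
  expect_error(robustness_grid(oracle, maze, grid = bad_grid), "central arm")
})

test_that("maze-size sweep: identity scaling is exact, doubling keeps the oracle perfect, degenerate sizes fail", {
  maze <- maze_config(timeout_steps = 800)
  oracle <- make_fixture("oracle_policy")
  base <- robustness_grid(oracle, maze,
                          grid = start_position_grid(maze, 2L, 3L),
                          n_trials = 2)
  sweep <- maze_size_sweep(oracle, maze, scales = c(1, 2),
                           grid_nx = 2L, grid_ny = 3L, n_trials = 2)
  expect_identical(sweep$mean[1], base$mean)
  expect_identical(sweep$variance[1], base$variance)
  expect_equal(sweep$mean[2], 100)
  expect_error(maze_size_sweep(oracle, maze, scales = 0.05,
                               grid_nx = 2L, grid_ny = 2L, n_trials = 1),
               "narrower")
})

test_that("reward-distance sweep: baseline at the original distance, flat for a cue reflex, validated inputs", {
  maze <- maze_config(timeout_steps = 1200)
  oracle <- make_fixture("oracle_policy")
  base <- run_session(oracle, maze, n_trials = 4)$success_rate
  sw <- reward_distance_sweep(oracle, maze,
                              distances = c(120, 150, 180), n_trials = 4)
  expect_identical(sw$success_rate[1], base)
  # the ground-truth follower tracks the cue: flat 100% at any distance
  expect_true(all(sw$success_rate == 100))
  expect_error(reward_distance_sweep(oracle, maze, distances = 80), ">=")
})

test_that("learning-on/off replay pairs success curves per weight snapshot", {
  maze <- maze_config(timeout_steps = 800)
  ctrl <- hebbian_controller(benign_params())
  fam <- run_familiarization(ctrl, maze)
  sess <- run_session(fam$controller, maze, n_trials = 3,
                      record_weights = "start")
  snaps <- lapply(sess$records, function(r) r$weight_start)
  start0 <- data.frame(x = maze$start_pose[["x"]], y = maze$start_pose[["y"]])
  rep_curves <- learning_onoff_replay(fam$controller, maze, snaps,
                                      starts = start0, n_trials = 1)
  expect_identical(nrow(rep_curves), 3L)
  expect_named(rep_curves, c("trial", "learning_on", "learning_off"))
  # determinism: the learning-on replay of block-1 snapshots from the
  # original start reproduces the baseline outcome of each trial
  expect_equal(rep_curves$learning_on,
               100 * as.numeric(sess$outcomes == "reward"))

  # all-zero snapshots with learning off behave as a fresh frozen controller
  zero_W <- reset_phase(ctrl)$W
  rz <- learning_onoff_replay(ctrl, maze, list(zero_W), starts = start0,
                              n_trials = 1)
  fresh <- run_session(reset_phase(ctrl), maze, n_trials = 1,
                       learning = FALSE)
  expect_equal(rz$learning_off[1],
               100 * as.numeric(fresh$outcomes[1] == "reward"))
})

test_that("group-variance comparison: null and separated cases, both methods, validation", {
  same <- c(100, 200, 300, 400)
  res <- compare_group_variances(same, same)
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 0)

  set.seed(77)
  hl <- stats::rnorm(8, mean = 300, sd = 10)
  others <- stats::rnorm(10, mean = 700, sd = 10)  # 40 SD apart
  t_res <- compare_group_variances(hl, others)
  expect_lt(t_res$p_value, 0.001)
  p_res <- compare_group_variances(hl, others, method = "permutation",
                                   n_perm = 2000)
  expect_lt(p_res$p_value, 0.01)
  expect_lt(p_res$statistic, 0)

  expect_error(compare_group_variances(1, c(1, 2)), "two robots")
})
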