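scalar_frame <- function(reward = 0, whisker5 = 0) {
  w <- integer(32)
  if (whisker5) w[5] <- 1L
  structure(list(whiskers = w, camera = numeric(20), ir = numeric(6),
                 reward = reward), class = "sensor_frame")
}

test_that("state units mirror the sensory signals proportionally", {
  p <- controller_params(k_touch = 2, k_reward = 1.5, delta = 10)
  ctrl <- hebbian_controller(p)

  c1 <- set_states(ctrl, scalar_frame())
  expect_identical(c1$s$tactile, numeric(32))
  expect_identical(c1$s$motor, 0.5)  # held output seeds the motor state

  c2 <- set_states(ctrl, scalar_frame(reward = -1))
  expect_identical(c2$s$reward, -1.5)

  c3 <- set_states(ctrl, scalar_frame(whisker5 = 1))
  expect_identical(c3$s$tactile[5], 2)
  expect_identical(sum(c3$s$tactile), 2)

  bad <- scalar_frame()
  bad$ir <- numeric(3)
  expect_error(set_states(ctrl, bad), "dimensions")
})

test_that("the modified Hebbian rule matches its scalar hand computation", {
  # eta = 0.5, zeta = 0.1, s_j = 1, ds_i = 0.4, W = 0.2  ->  0.38
  p <- controller_params(eta = 0.5, zeta = 0.1, delta = 10, tau = 1)
  ctrl <- hebbian_controller(p)
  ctrl$W[["reward->motor"]][1, 1] <- 0.2
  s_now <- list(tactile = numeric(32), vision = numeric(20), ir = numeric(6),
                reward = 1, motor = 0.4)
  s_then <- s_now
  s_then$motor <- 0.0
  ctrl$s <- s_now
  ctrl$hist <- list(s_now, s_then)
  out <- hebbian_update(ctrl)
  expect_equal(out$W[["reward->motor"]][1, 1], 0.38)
  # zero presynaptic state: no potentiation anywhere else, only decay
  expect_identical(out$W[["tactile->motor"]], ctrl$W[["tactile->motor"]] * 0.9)
})

test_that("with zero state change every weight decays geometrically at (1 - zeta)", {
  p <- controller_params(eta = 0.7, zeta = 0.05, delta = 10, tau = 1)
  ctrl <- hebbian_controller(p)
  set.seed(3)
  for (pr in p$pairs) {
    ctrl$W[[pr]][] <- stats::runif(length(ctrl$W[[pr]]))
  }
  W0 <- ctrl$W
  frozen <- ctrl$s
  ctrl$hist <- list(frozen, frozen, frozen)
  n <- 7
  for (i in seq_len(n)) ctrl <- hebbian_update(ctrl)
  for (pr in p$pairs) {
    expect_equal(ctrl$W[[pr]], W0[[pr]] * (1 - 0.05)^n)
  }
})

test_that("virtual units propagate through the sigmoid; the reward unit is pinned", {
  p <- controller_params(delta = 10, slope = 1)
  ctrl <- hebbian_controller(p)
  # all-zero weights: every non-reward virtual unit sits at sigmoid(0) = 0.5
  out <- virtual_update(ctrl)
  for (m in c("tactile", "vision", "ir", "motor")) {
    expect_true(all(out$v[[m]] == 0.5))
  }
  expect_identical(out$v$reward, 1)
  # one scalar path: W = 2, e_j = 0.3, slope 1  ->  sigmoid(0.6)
  p2 <- controller_params(topology = "reward->motor", delta = 10, slope = 1)
  c2 <- hebbian_controller(p2)
  c2$W[["reward->motor"]][1, 1] <- 2
  c2$v$reward <- 1
  c2$s$reward <- 0.7   # e = v - s = 0.3
  out2 <- virtual_update(c2)
  expect_equal(out2$v$motor, 1 / (1 + exp(-0.6)))
  expect_equal(out2$u, out2$v$motor)
})

test_that("a full tick follows the step order and a two-tick scenario matches pencil-and-paper", {
  # scalar reward->motor controller: eta 0.5, zeta 0.1, tau 1, slope 1,
  # k_reward 1. Tick 1 (reward = 1): ds_motor = 0.5 (zero history), so
  # W <- 0.5*0.5*1 = 0.25; e_reward = 1 - 1 = 0 so u stays 0.5.
  # Tick 2 (reward = 0): ds_motor = 0, W <- 0.25*0.9 = 0.225;
  # e_reward = 1 - 0 = 1 so u = sigmoid(0.225).
  p <- controller_params(eta = 0.5, zeta = 0.1, delta = 10, tau = 1,
                         slope = 1, k_reward = 1, topology = "reward->motor")
  ctrl <- hebbian_controller(p)
  expect_identical(ctrl$u, 0.5)

  t1 <- tick(ctrl, scalar_frame(reward = 1))
  expect_equal(t1$controller$W[["reward->motor"]][1, 1], 0.25)
  expect_equal(t1$u, 0.5)

  t2 <- tick(t1$controller, scalar_frame(reward = 0))
  expect_equal(t2$controller$W[["reward->motor"]][1, 1], 0.225)
  expect_equal(t2$u, 1 / (1 + exp(-0.225)))

  # learning disabled: weights bit-identical across a tick
  t3 <- tick(t1$controller, scalar_frame(reward = 0), learning = FALSE)
  expect_identical(t3$controller$W, t1$controller$W)
  expect_equal(t3$u, 1 / (1 + exp(-0.25)))  # propagation still runs
})

test_that("phase reset zeroes weights and virtual units; carry_weights preserves learning", {
  ctrl <- hebbian_controller(benign_params())
  maze <- maze_config(timeout_steps = 1000)
  fam <- run_familiarization(ctrl, maze)
  learned <- fam$controller
  expect_gt(sum(vapply(learned$W, function(m) sum(abs(m)), numeric(1))), 0)

  full <- reset_phase(learned, carry_weights = FALSE)
  expect_true(all(vapply(full$W, function(m) all(m == 0), logical(1))))
  expect_identical(full$v$reward, 1)
  expect_true(all(full$v$motor == 0))
  expect_length(full$hist, 0)

  kept <- reset_phase(learned, carry_weights = TRUE)
  expect_identical(kept$W, learned$W)
  expect_identical(kept$u, 0.5)
})

test_that("virtual-unit perturbations never alter the weight trajectory", {
  # the two pathways are separated: weights depend on state units only
  p <- controller_params(eta = 0.4, zeta = 0.02, delta = 10, tau = 2)
  a <- hebbian_controller(p)
  b <- hebbian_controller(p)
  set.seed(5)
  for (i in 1:15) {
    f <- structure(list(whiskers = as.integer(stats::runif(32) < 0.2),
                        camera = stats::runif(20), ir = stats::runif(6),
                        reward = sample(c(-1, 0, 1), 1)),
                   class = "sensor_frame")
    u_held <- stats::runif(1)
    a$u <- u_held; b$u <- u_held           # identical state-unit sequences
    b$v <- lapply(b$v, function(v) v + stats::runif(length(v), -1, 1))
    a <- hebbian_update(set_states(a, f))
    b <- hebbian_update(set_states(b, f))
    expect_identical(a$W, b$W)
  }
})

test_that("minimal topology stores exactly the five task pathways and motor output stays in (0,1)", {
  expect_identical(sort(controller_pairs("minimal")),
                   sort(c("tactile->vision", "ir->motor", "tactile->motor",
                          "reward->vision", "vision->motor")))
  expect_length(controller_pairs("full"), 20L)
  expect_error(controller_pairs(c("nose->motor")), "unknown")

  p <- controller_params(topology = "minimal", delta = 10)
  ctrl <- hebbian_controller(p)
  expect_identical(sort(names(ctrl$W)), sort(controller_pairs("minimal")))

  # sigmoid read-out keeps u strictly inside (0, 1) whatever the weights
  set.seed(8)
  for (i in 1:30) {
    for (pr in names(ctrl$W)) ctrl$W[[pr]][] <- stats::rnorm(length(ctrl$W[[pr]]), sd = 5)
    f <- structure(list(whiskers = as.integer(stats::runif(32) < 0.5),
                        camera = stats::runif(20), ir = stats::runif(6),
                        reward = sample(c(-1, 0, 1), 1)),
                   class = "sensor_frame")
    out <- tick(ctrl, f)
    expect_true(out$u > 0 && out$u < 1)
    ctrl <- out$controller
  }
})

test_that("parameter validation enforces the documented ranges", {
  expect_error(controller_params(delta = 5), "delta")
  expect_error(controller_params(delta = 35), "delta")
  expect_error(controller_params(V = 0), "positive")
  expect_error(controller_params(eta = -1), "finite")
  expect_error(controller_params(eta = c(0.1, 0.2)), "named")
})
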