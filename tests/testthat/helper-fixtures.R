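# Shared helpers: independent oracles and small parameter sets.

# Independent state-machine VTE counter (deliberately written as an explicit
# per-sample loop, unlike the vectorised detector under test).
brute_force_vte <- function(u, theta, rule = "hysteresis") {
  m <- 2 * u - 1
  n <- 0L
  if (rule == "hysteresis") {
    arm <- 0L
    for (mi in m) {
      band <- if (theta == 0) sign(mi) else if (mi > theta) 1L else if (mi < -theta) -1L else 0L
      if (band != 0L) {
        if (arm != 0L && band != arm) n <- n + 1L
        arm <- band
      }
    }
  } else {
    for (i in seq_along(m)[-1]) {
      if (sign(m[i]) != 0 && sign(m[i - 1]) != 0 &&
          sign(m[i]) != sign(m[i - 1]) &&
          abs(m[i] - m[i - 1]) > 2 * theta) {
        n <- n + 1L
      }
    }
  }
  n
}

# Dense ray-casting camera oracle: one ray per 0.1 degree, binned.
camera_oracle <- function(pose, maze, n_rays = 3600) {
  th <- pose[["heading"]]; x <- pose[["x"]]; y <- pose[["y"]]
  n <- maze$robot$n_pixels
  width <- 2 * pi / n
  px <- numeric(n)
  seg <- maze$walls$seg
  black <- maze$walls$black
  for (r in 0:(n_rays - 1)) {
    a <- th + r * 2 * pi / n_rays + 1e-4  # offset dodges exact endpoints
    hit <- vtemaze:::ray_first_hit(x, y, a, seg)
    if (is.finite(hit[1]) && black[hit[2]]) {
      px[floor(((a - th) %% (2 * pi)) / width) + 1] <- 1
    }
  }
  px
}

random_valid_pose <- function(maze) {
  repeat {
    p <- robot_pose(stats::runif(1, -maze$x_end, maze$x_end),
                    stats::runif(1, maze$y_bottom, maze$hw_x),
                    stats::runif(1, 0, 2 * pi))
    if (vtemaze:::pose_valid(p, maze)) return(p)
  }
}

# A hand-picked parameter set that learns visibly and hits walls during
# familiarization (used where a behaving controller is needed).
benign_params <- function(delta = 10, ...) {
  controller_params(eta = 0.5, zeta = 0.01, delta = delta, tau = 2,
                    slope = 1, V = 1.5,
                    c_familiarization = 0.8, c_maze = 0.8, ...)
}

# Policy choosing an arm at random each trial, ground-truth steering to it;
# succeeds iff the chosen side is the rewarded one.
coin_policy <- function(delta = 5L) {
  side <- "left"
  fn <- function(pose, frame, step, maze) {
    if (step <= delta) {
      side <<- if (stats::runif(1) < 0.5) "left" else "right"
    }
    x <- pose[["x"]]; y <- pose[["y"]]; th <- pose[["heading"]]
    if (y < -4) {
      tx <- 0; ty <- 0
    } else {
      xz <- maze$x_end - maze$reward_zone_depth / 2
      tx <- if (side == "left") -xz else xz
      ty <- 0
    }
    err <- atan2(ty - y, tx - x) - th
    err <- atan2(sin(err), cos(err))
    min(1, max(0, 0.5 + 1.2 * err))
  }
  scripted_policy(fn, delta = delta, V = 1, c = 1, name = "coin")
}

# Fabricate a session_record carrying given per-module series (for analysis
# modules that only read neural logs).
fake_session <- function(series_list) {
  records <- lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    n <- length(s$motor)
    structure(list(
      trial_index = i, phase = "maze_solving", outcome = "reward",
      env_steps = n * 10L,
      trajectory = data.frame(x = numeric(n + 1), y = numeric(n + 1),
                              heading = numeric(n + 1)),
      neural_log = data.frame(
        neural_step = seq_len(n), env_step = seq_len(n) * 10L,
        u = s$motor, u_raw = s$motor,
        vs_tactile = s$tactile, vs_vision = s$vision, vs_ir = s$ir,
        vs_reward = s$reward
      ),
      blocked = 0L
    ), class = "trial_record")
  })
  structure(list(records = records,
                 outcomes = rep("reward", length(records)),
                 success_rate = 100, blocked = 0L,
                 n_trials = length(records)),
            class = "session_record")
}
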