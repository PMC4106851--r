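#' Scripted (non-learning) policy
#'
#' Wraps a function `fn(pose, frame, step, maze)` returning a motor output in
#' `[0, 1]` so it can drive the same trial engine as a learned controller.
#' Used for oracles and stubs: ground-truth steering, constant circling,
#' zig-zag generators. Scripted policies have no weights and ignore the
#' learning flag.
#'
#' @param fn Function of `(pose, frame, step, maze)` returning `u`.
#' @param delta Neural update period in environment steps.
#' @param V,c Forward speed and turn conversion constant.
#' @param name Label used in printing.
#' @return A `scripted_policy` object.
#' @export
scripted_policy <- function(fn, delta = 10L, V = 1, c = 1, name = "scripted") {
  stopifnot(is.function(fn))
  structure(list(fn = fn, delta = as.integer(delta), V = V, c = c, name = name),
            class = "scripted_policy")
}

#' @export
tick.scripted_policy <- function(controller, frame, learning = TRUE, ...,
                                 pose = NULL, step = 0L, maze = NULL) {
  u <- controller$fn(pose, frame, step, maze)
  u <- min(1, max(0, u))
  list(controller = controller, u = u)
}

#' @export
print.scripted_policy <- function(x, ...) {
  cat("scripted policy '", x$name, "' (delta = ", x$delta,
      ", V = ", x$V, ", c = ", x$c, ")\n", sep = "")
  invisible(x)
}

ctrl_delta <- function(controller) {
  if (inherits(controller, "hebbian_controller")) controller$params$delta
  else controller$delta
}

ctrl_kin <- function(controller, maze, phase) {
  if (inherits(controller, "hebbian_controller")) {
    p <- controller$params
    cc <- if (phase == "familiarization") p$c_familiarization else p$c_maze
    list(V = p$V, c = cc, axle_width = maze$robot$axle_width)
  } else {
    list(V = controller$V, c = controller$c, axle_width = maze$robot$axle_width)
  }
}

# Schmitt-trigger state step shared by the offline counter and the online
# suppressor. arm is -1/0/+1 (last threshold band left); returns the new arm
# and whether an event fired at this sample.
schmitt_step <- function(m, arm, theta) {
  band <- if (theta == 0) sign(m) else if (m > theta) 1 else if (m < -theta) -1 else 0
  if (band == 0) return(list(arm = arm, event = FALSE))
  list(arm = band, event = arm != 0 && band != arm)
}

#' Run one trial
#'
#' Steps the environment at one-step cadence (pose, reward channel, wheel
#' speeds recomputed from the held motor output) and ticks the controller
#' every `delta` steps. A maze-solving trial ends at the first entry of the
#' body centre into the reward or punishment zone, or at exactly
#' `timeout_steps`; wall contact makes the robot slide, never aborts. On
#' zone entry the controller receives one final tick with the reward-bearing
#' frame so the reward state reaches the Hebbian rule before the trial
#' closes. A familiarization trial instead clamps the motor output to
#' `clamp_u`, senses neither cue nor reward, and ends at the first wall
#' contact (`wall_reset`).
#'
#' @param controller A `hebbian_controller` or [scripted_policy()].
#' @param maze A [maze_config()].
#' @param learning Apply Hebbian updates during ticks.
#' @param phase `"maze_solving"` or `"familiarization"`.
#' @param start Start pose; defaults to the maze's.
#' @param clamp_u Fixed motor output for familiarization trials.
#' @param theta_suppress When non-`NULL`, online VTE suppression: every
#'   detected sign change of `2u - 1` beyond the threshold band overrides
#'   that neural step's motor output to 0.5 (zero angular velocity); the
#'   controller's held motor state sees the override.
#' @param record_weights `"none"`, `"start"` (snapshot the full weight set at
#'   trial start) or `"means"` (log per-pair mean weights each neural step).
#' @param trial_index,seed Bookkeeping stored in the record; the simulation
#'   itself is noise-free and deterministic.
#' @return A `trial_record`: outcome, `env_steps`, trajectory, per-tick
#'   `neural_log`, suppression count, and the updated controller in
#'   `$controller`.
#' @export
run_trial <- function(controller, maze, learning = TRUE,
                      phase = c("maze_solving", "familiarization"),
                      start = maze$start_pose, clamp_u = NULL,
                      theta_suppress = NULL,
                      record_weights = "none",
                      trial_index = 1L, seed = NULL) {
  phase <- match.arg(phase)
  if (!is.null(seed)) set.seed(seed)
  if (!pose_valid(start, maze)) stop("start pose outside maze free space")
  if (phase == "familiarization" && is.null(clamp_u)) {
    stop("familiarization trials need clamp_u")
  }
  delta <- ctrl_delta(controller)
  kin <- ctrl_kin(controller, maze, phase)
  is_hebb <- inherits(controller, "hebbian_controller")
  n_max <- maze$timeout_steps
  max_ticks <- n_max %/% delta + 2L

  traj <- matrix(NA_real_, nrow = n_max + 1L, ncol = 3L,
                 dimnames = list(NULL, c("x", "y", "heading")))
  traj[1L, ] <- unclass(start)
  nl_u <- numeric(max_ticks)
  nl_uraw <- numeric(max_ticks)
  nl_env <- integer(max_ticks)
  nl_vs <- matrix(NA_real_, nrow = max_ticks, ncol = 5L,
                  dimnames = list(NULL, paste0("vs_", module_order)))
  wmeans <- if (identical(record_weights, "means") && is_hebb) {
    matrix(NA_real_, nrow = max_ticks,
           ncol = length(controller$params$pairs),
           dimnames = list(NULL, controller$params$pairs))
  }
  w_start <- if (identical(record_weights, "start") && is_hebb) controller$W

  pose <- start
  u_held <- if (is_hebb) controller$u else 0.5
  if (phase == "familiarization") u_held <- clamp_u
  arm <- 0L
  blocked <- 0L
  tick_i <- 0L
  outcome <- "timeout"
  steps <- 0L

  log_tick <- function(env_step, u_eff, u_raw) {
    tick_i <<- tick_i + 1L
    nl_env[tick_i] <<- env_step
    nl_u[tick_i] <<- u_eff
    nl_uraw[tick_i] <<- u_raw
    if (is_hebb) {
      nl_vs[tick_i, ] <<- vapply(module_order, function(m) {
        mean(controller$v[[m]] - controller$s[[m]])
      }, numeric(1))
      if (!is.null(wmeans)) {
        wmeans[tick_i, ] <<- vapply(controller$W, mean, numeric(1))
      }
    }
  }

  do_tick <- function(env_step) {
    frame <- sense(pose, maze)
    if (phase == "familiarization") {
      frame$whiskers[] <- 0L
      frame$reward <- 0
    }
    if (is_hebb && phase == "familiarization") controller$u <<- clamp_u
    res <- tick(controller, frame, learning = learning,
                pose = pose, step = env_step, maze = maze)
    controller <<- res$controller
    u_raw <- res$u
    u_eff <- u_raw
    if (!is.null(theta_suppress)) {
      st <- schmitt_step(2 * u_raw - 1, arm, theta_suppress)
      arm <<- st$arm
      if (st$event) {
        u_eff <- 0.5
        blocked <<- blocked + 1L
      }
    }
    if (phase == "familiarization") u_eff <- clamp_u
    if (is_hebb) controller$u <<- u_eff
    log_tick(env_step, u_eff, u_raw)
    u_eff
  }

  for (t in seq_len(n_max)) {
    if ((t - 1L) %% delta == 0L) u_held <- do_tick(t)
    pose <- step_kinematics(pose, u_held, kin, maze)
    traj[t + 1L, ] <- unclass(pose)
    steps <- t
    if (phase == "familiarization") {
      if (isTRUE(attr(pose, "collided"))) {
        outcome <- "wall_reset"
        break
      }
    } else {
      z <- zone_at(pose[["x"]], pose[["y"]], maze)
      if (z != 0) {
        if (is_hebb) do_tick(t)  # final tick: reward state reaches the Hebbian rule
        outcome <- if (z > 0) "reward" else "punishment"
        break
      }
    }
  }

  ti <- seq_len(tick_i)
  neural_log <- data.frame(
    neural_step = ti, env_step = nl_env[ti],
    u = nl_u[ti], u_raw = nl_uraw[ti]
  )
  if (is_hebb) neural_log <- cbind(neural_log, as.data.frame(nl_vs[ti, , drop = FALSE]))
  rec <- structure(list(
    trial_index = as.integer(trial_index), phase = phase, outcome = outcome,
    env_steps = steps,
    trajectory = as.data.frame(traj[seq_len(steps + 1L), , drop = FALSE]),
    neural_log = neural_log,
    weight_start = w_start,
    weight_means = if (!is.null(wmeans)) wmeans[ti, , drop = FALSE],
    blocked = blocked, theta_suppress = theta_suppress,
    reward_side = maze$reward_side, seed = seed,
    controller = controller
  ), class = "trial_record")
  rec
}

#' Run the familiarization phase
#'
#' Twenty episodes with cue and reward deactivated and the motor output
#' clamped to one of two fixed values (a right-turn-inducing and a
#' left-turn-inducing one), switching on every wall contact/reset. Hebbian
#' learning runs throughout, and the learned weights are the point of the
#' phase: they seed the maze-solving session with the basic IR-vision-motor
#' correlations.
#'
#' @param controller A `hebbian_controller` (reset fully at entry).
#' @param maze A [maze_config()].
#' @param n_episodes Number of clamped episodes.
#' @param clamp_values The two alternating motor outputs.
#' @return List with `records` (one `trial_record` per episode) and
#'   `controller` (weights carried forward).
#' @export
run_familiarization <- function(controller, maze, n_episodes = 20L,
                                clamp_values = c(0.2, 0.8)) {
  stopifnot(inherits(controller, "hebbian_controller"))
  controller <- reset_phase(controller, carry_weights = FALSE)
  records <- vector("list", n_episodes)
  for (ep in seq_len(n_episodes)) {
    clamp <- clamp_values[(ep - 1L) %% 2L + 1L]
    rec <- run_trial(controller, maze, learning = TRUE,
                     phase = "familiarization", clamp_u = clamp,
                     trial_index = ep)
    controller <- rec$controller
    rec$controller <- NULL
    rec$clamp_u <- clamp
    records[[ep]] <- rec
  }
  list(records = records, controller = controller)
}

#' Run a maze-solving session
#'
#' Runs `n_trials` trials from a fixed start. The rewarded side (and the
#' tactile cue with it) toggles after every fifth trial, so blocks of five
#' alternate sides. Weights persist across trials; virtual units, state
#' history and the held motor output are re-initialized at each trial start,
#' so with learning off a fixed controller reproduces identical trajectories
#' within a reward block.
#'
#' @param controller A controller whose familiarization phase is complete
#'   (or a scripted policy).
#' @param maze A [maze_config()]; its `reward_side` is the initial side.
#' @param n_trials Number of trials.
#' @param learning Hebbian updates on?
#' @param start Start pose for every trial.
#' @param theta_suppress Optional online VTE-suppression threshold, see
#'   [run_trial()].
#' @param record_weights See [run_trial()].
#' @param block_length Trials per reward-side block.
#' @return A `session_record`: list of trial records, `success_rate`
#'   (percent of trials reaching the reward), total `blocked` suppression
#'   events, and the final controller.
#' @export
run_session <- function(controller, maze, n_trials = 100L, learning = TRUE,
                        start = maze$start_pose, theta_suppress = NULL,
                        record_weights = "none", block_length = 5L) {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  is_hebb <- inherits(controller, "hebbian_controller")
  if (is_hebb) controller <- reset_phase(controller, carry_weights = TRUE)
  records <- vector("list", n_trials)
  cur <- maze
  blocked <- 0L
  for (i in seq_len(n_trials)) {
    if (is_hebb) {
      w <- controller$W
      controller <- reset_phase(controller, carry_weights = TRUE)
      controller$W <- w
    }
    rec <- run_trial(controller, cur, learning = learning, start = start,
                     theta_suppress = theta_suppress,
                     record_weights = record_weights, trial_index = i)
    controller <- rec$controller
    rec$controller <- NULL
    blocked <- blocked + rec$blocked
    records[[i]] <- rec
    if (i %% block_length == 0L) cur <- toggle_reward_side(cur)
  }
  outcomes <- vapply(records, function(r) r$outcome, character(1))
  structure(list(
    records = records,
    success_rate = 100 * mean(outcomes == "reward"),
    outcomes = outcomes,
    blocked = blocked, theta_suppress = theta_suppress,
    n_trials = n_trials, controller = controller
  ), class = "session_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat("trial ", x$trial_index, " (", x$phase, "): ", x$outcome,
      " after ", x$env_steps, " env steps (",
      nrow(x$neural_log), " neural steps)\n", sep = "")
  invisible(x)
}

#' @export
print.session_record <- function(x, ...) {
  tab <- table(factor(x$outcomes,
                      levels = c("reward", "punishment", "timeout", "wall_reset")))
  cat("session of ", x$n_trials, " trials: success rate ",
      round(x$success_rate, 1), "%\n", sep = "")
  cat("  outcomes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$theta_suppress)) {
    cat("  VTE suppression theta = ", x$theta_suppress,
        ", blocked events = ", x$blocked, "\n", sep = "")
  }
  invisible(x)
}
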