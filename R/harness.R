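#' Start-position grid for robustness experiments
#'
#' Uniformly spaced positions inside the central arm: `nx` lateral by `ny`
#' longitudinal, default 7 x 40 = 280 positions. A body-radius margin keeps
#' every grid pose valid.
#'
#' @param maze A [maze_config()].
#' @param nx,ny Lateral and longitudinal grid counts.
#' @param margin Extra clearance beyond the body radius (cm).
#' @return Data frame of `x`, `y` grid positions.
#' @export
start_position_grid <- function(maze, nx = 7L, ny = 40L, margin = 0.5) {
  r <- maze$robot$body_radius + margin
  x_lo <- -maze$hw_c + r
  x_hi <- maze$hw_c - r
  y_lo <- maze$y_bottom + r
  y_hi <- -maze$hw_x - r
  if (x_hi <= x_lo || y_hi <= y_lo) stop("central arm too small for the grid margin")
  expand.grid(x = seq(x_lo, x_hi, length.out = nx),
              y = seq(y_lo, y_hi, length.out = ny))
}

#' Success-rate map over perturbed start positions
#'
#' For every grid position, re-runs the whole protocol from that position —
#' familiarization (for learning controllers) and a fresh session — and
#' records the session success rate in percent. The aggregate mean and
#' variance of the per-position rates are the robustness statistics: a low
#' variance means the behaviour survives start-position perturbation.
#'
#' @param controller A `hebbian_controller` (re-familiarized per position)
#'   or a [scripted_policy()].
#' @param maze A [maze_config()].
#' @param grid Data frame of start positions, default
#'   [start_position_grid()] (280 cells).
#' @param n_trials Trials per session.
#' @param heading Start heading at every grid position.
#' @param refamiliarize Re-run familiarization from the perturbed position
#'   (the perturbation applies to the whole protocol); `FALSE` reuses the
#'   controller as given.
#' @return A `robustness_map`: the grid with a `success_rate` column, plus
#'   `mean` and `variance` across positions.
#' @export
robustness_grid <- function(controller, maze, grid = start_position_grid(maze),
                            n_trials = 100L, heading = pi / 2,
                            refamiliarize = TRUE) {
  rates <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    start <- robot_pose(grid$x[i], grid$y[i], heading)
    if (!pose_valid(start, maze) || abs(grid$x[i]) > maze$hw_c ||
        grid$y[i] > -maze$hw_x) {
      stop("grid position outside the central arm")
    }
    ctrl <- controller
    if (inherits(ctrl, "hebbian_controller") && refamiliarize) {
      fam_maze <- maze
      fam_maze$start_pose <- start
      ctrl <- run_familiarization(ctrl, fam_maze)$controller
    }
    sess <- run_session(ctrl, maze, n_trials = n_trials, start = start)
    rates[i] <- sess$success_rate
  }
  structure(list(
    grid = cbind(grid, success_rate = rates),
    mean = mean(rates), variance = stats::var(rates),
    n_positions = nrow(grid), n_trials = n_trials
  ), class = "robustness_map")
}

#' @export
print.robustness_map <- function(x, ...) {
  cat("robustness map over ", x$n_positions, " start positions (",
      x$n_trials, " trials each)\n", sep = "")
  cat(sprintf("  success rate mean %.1f%%, variance %.1f\n", x$mean, x$variance))
  invisible(x)
}

#' Robustness across maze sizes
#'
#' Repeats [robustness_grid()] with the maze's arm lengths/widths scaled,
#' reporting the success-rate variance per size. Scaling by 1 reproduces
#' the base grid result.
#'
#' @param controller Controller or policy.
#' @param maze Base [maze_config()].
#' @param scales Data frame with columns `sx`, `sy` (width and length
#'   multipliers), or a numeric vector of uniform scales.
#' @param ... Passed to [robustness_grid()] (e.g. a smaller `grid` spec via
#'   `grid_nx`/`grid_ny`, `n_trials`).
#' @param grid_nx,grid_ny Grid resolution per size.
#' @return Data frame: `sx`, `sy`, `mean`, `variance`.
#' @export
maze_size_sweep <- function(controller, maze, scales,
                            grid_nx = 7L, grid_ny = 40L, ...) {
  if (is.numeric(scales)) scales <- data.frame(sx = scales, sy = scales)
  out <- vector("list", nrow(scales))
  for (i in seq_len(nrow(scales))) {
    sx <- scales$sx[i]; sy <- scales$sy[i]
    m2 <- maze_config(
      central_arm_length = maze$central_arm_length * sy,
      central_arm_width = maze$central_arm_width * sx,
      cross_arm_length = maze$cross_arm_length * sx,
      cross_arm_width = maze$cross_arm_width * sy,
      cue_side = maze$cue_side,
      reward_zone_depth = maze$reward_zone_depth,
      timeout_steps = maze$timeout_steps,
      robot = maze$robot
    )
    rg <- robustness_grid(controller, m2,
                          grid = start_position_grid(m2, grid_nx, grid_ny), ...)
    out[[i]] <- data.frame(sx = sx, sy = sy, mean = rg$mean,
                           variance = rg$variance)
  }
  do.call(rbind, out)
}

#' Success rate as the reward moves away from the cue
#'
#' Lengthens the rewarded branch so the reward sits further from the tactile
#' cue, and measures the session success rate at each distance. A reflexive
#' cue-follower stays flat; a controller that tracks the expected reward
#' location degrades.
#'
#' @param controller Controller or policy.
#' @param maze Base maze; `distances` are cross-arm lengths (cm) and must
#'   not fall below the original.
#' @param distances Numeric vector of cross-arm lengths to test.
#' @param n_trials Trials per session.
#' @param refamiliarize Re-run familiarization per distance.
#' @return Data frame: `distance`, `success_rate`.
#' @export
reward_distance_sweep <- function(controller, maze, distances,
                                  n_trials = 100L, refamiliarize = TRUE) {
  if (any(distances < maze$cross_arm_length)) {
    stop("distances must be >= the original cross-arm length")
  }
  out <- numeric(length(distances))
  for (i in seq_along(distances)) {
    m2 <- maze_config(
      central_arm_length = maze$central_arm_length,
      central_arm_width = maze$central_arm_width,
      cross_arm_length = distances[i],
      cross_arm_width = maze$cross_arm_width,
      cue_side = maze$cue_side,
      reward_zone_depth = maze$reward_zone_depth,
      timeout_steps = maze$timeout_steps,
      robot = maze$robot
    )
    ctrl <- controller
    if (inherits(ctrl, "hebbian_controller") && refamiliarize) {
      ctrl <- run_familiarization(ctrl, m2)$controller
    }
    out[i] <- run_session(ctrl, m2, n_trials = n_trials)$success_rate
  }
  data.frame(distance = distances, success_rate = out)
}

#' Learning-on vs learning-off replay from per-trial weight snapshots
#'
#' Given the weight set at the start of each baseline trial, replays the
#' evaluation twice per snapshot — weights frozen versus learning active —
#' from a set of perturbed start positions, yielding the paired
#' success-rate curves that separate controllers which *use* ongoing
#' learning from those which do not.
#'
#' @param controller A `hebbian_controller` (supplies parameters/topology).
#' @param maze A [maze_config()].
#' @param snapshots List of weight sets, one per baseline trial — the
#'   `weight_start` fields of a session run with
#'   `record_weights = "start"`.
#' @param starts Data frame of start positions (`x`, `y`); default a coarse
#'   central-arm grid.
#' @param heading Start heading.
#' @param n_trials Trials per start per condition.
#' @return Data frame: `trial`, `learning_on`, `learning_off` success rates
#'   in percent.
#' @export
learning_onoff_replay <- function(controller, maze, snapshots,
                                  starts = start_position_grid(maze, 3L, 5L),
                                  heading = pi / 2, n_trials = 1L) {
  stopifnot(inherits(controller, "hebbian_controller"))
  eval_once <- function(W, learning) {
    succ <- 0L
    tot <- 0L
    for (i in seq_len(nrow(starts))) {
      ctrl <- reset_phase(controller, carry_weights = FALSE)
      ctrl$W <- W
      start <- robot_pose(starts$x[i], starts$y[i], heading)
      sess <- run_session(ctrl, maze, n_trials = n_trials,
                          learning = learning, start = start)
      succ <- succ + sum(sess$outcomes == "reward")
      tot <- tot + n_trials
    }
    100 * succ / tot
  }
  on <- numeric(length(snapshots))
  off <- numeric(length(snapshots))
  for (t in seq_along(snapshots)) {
    on[t] <- eval_once(snapshots[[t]], learning = TRUE)
    off[t] <- eval_once(snapshots[[t]], learning = FALSE)
  }
  data.frame(trial = seq_along(snapshots), learning_on = on,
             learning_off = off)
}

#' Compare success-rate variances between VTE groups
#'
#' Two-sample comparison of per-robot success-rate variances, the rat-like
#' high-to-low group against the pooled others, by Student's t-test
#' (the default) or a permutation test on the difference of means.
#'
#' @param hl Numeric vector of per-robot variances in the HL group.
#' @param others Numeric vector of per-robot variances in the pooled other
#'   groups.
#' @param method `"t"` or `"permutation"`.
#' @param n_perm Permutations for the permutation test.
#' @param seed Seed for the permutation draw.
#' @return List with `statistic`, `p_value`, `method`, group means.
#' @export
compare_group_variances <- function(hl, others, method = c("t", "permutation"),
                                    n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  if (length(hl) < 2L || length(others) < 2L) {
    stop("need at least two robots per group")
  }
  if (method == "t") {
    tt <- stats::t.test(hl, others)
    res <- list(statistic = unname(tt$statistic), p_value = tt$p.value,
                method = "Welch two-sample t-test")
  } else {
    set.seed(seed)
    obs <- mean(hl) - mean(others)
    pool <- c(hl, others)
    n1 <- length(hl)
    perm <- replicate(n_perm, {
      idx <- sample.int(length(pool), n1)
      mean(pool[idx]) - mean(pool[-idx])
    })
    res <- list(statistic = obs,
                p_value = (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm),
                method = "permutation test on mean difference")
  }
  res$mean_hl <- mean(hl)
  res$mean_others <- mean(others)
  res
}
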