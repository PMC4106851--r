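#' Differential-drive kinematic step
#'
#' Advances the robot pose by one environment step under the standard
#' differential-drive wheel mix: the left and right wheel speeds are
#' `V - c*(2u - 1)` and `V + c*(2u - 1)`, so the forward speed is the
#' constant `V` and the angular velocity is `2c(2u - 1) / axle_width`.
#' Motor outputs above 0.5 therefore turn the robot left (counter-clockwise)
#' and outputs below 0.5 turn it right. Integration is explicit Euler with a
#' fixed step `dt`.
#'
#' When a maze is supplied, collisions are resolved by sliding: the motion
#' component into the wall is cancelled (tried as full move, then the x-only
#' and y-only components), rotation is always applied, and a `collided`
#' attribute on the returned pose reports whether any cancellation happened.
#'
#' @param pose A [robot_pose()].
#' @param u Motor output in `[0, 1]`.
#' @param params List with `V` (forward speed, cm/step), `c` (turn conversion
#'   constant) and optionally `axle_width`, `body_radius`, `dt`.
#' @param maze Optional [maze_config()] for collision resolution; `NULL`
#'   integrates in free space.
#' @return The advanced `robot_pose`; attribute `collided` is `TRUE` when a
#'   wall blocked part of the motion.
#' @export
step_kinematics <- function(pose, u, params, maze = NULL) {
  if (!is.finite(u) || u < 0 || u > 1) stop("invalid motor output u")
  if (any(!is.finite(unclass(pose)))) stop("non-finite pose")
  V <- params$V
  cc <- params$c
  if (!is.finite(V) || V <= 0 || !is.finite(cc) || cc < 0) {
    stop("forward speed and turn constant must be positive")
  }
  axle <- if (is.null(params$axle_width)) 5.3 else params$axle_width
  dt <- if (is.null(params$dt)) 1 else params$dt

  th <- pose[["heading"]]
  omega <- 2 * cc * (2 * u - 1) / axle
  dx <- V * cos(th) * dt
  dy <- V * sin(th) * dt
  th2 <- th + omega * dt

  x1 <- pose[["x"]]; y1 <- pose[["y"]]
  collided <- FALSE
  if (is.null(maze)) {
    x2 <- x1 + dx; y2 <- y1 + dy
  } else {
    r <- maze$robot$body_radius
    ok <- function(x, y) {
      inside_free(x, y, maze) && wall_clearance(x, y, maze) >= r
    }
    if (ok(x1 + dx, y1 + dy)) {
      x2 <- x1 + dx; y2 <- y1 + dy
    } else if (ok(x1 + dx, y1)) {
      x2 <- x1 + dx; y2 <- y1; collided <- TRUE
    } else if (ok(x1, y1 + dy)) {
      x2 <- x1; y2 <- y1 + dy; collided <- TRUE
    } else {
      x2 <- x1; y2 <- y1; collided <- TRUE
    }
  }
  out <- robot_pose(x2, y2, th2)
  attr(out, "collided") <- collided
  out
}
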