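#' T-maze configuration
#'
#' Builds the simulated T-maze arena: a central (stem) corridor joined to a
#' horizontal cross corridor whose two distal ends hold the reward and the
#' punishment zone. All dimensions are centimetres, scaled to the e-puck
#' robot. The coordinate origin sits at the junction centre, `+y` points into
#' the cross corridor and headings are counter-clockwise radians from `+x`.
#'
#' The tactile cue is a cylindrical post protruding at the junction corner on
#' `cue_side`; the cue and the reward are always on the same side. One wall —
#' by default the entire distal ("back") wall of the cross corridor, the top
#' of the T — is black; every other surface renders white/transparent to the
#' omnidirectional camera, so the black wall is the only visual landmark.
#'
#' @param central_arm_length,central_arm_width Stem corridor dimensions (cm).
#' @param cross_arm_length Length of each side of the cross corridor measured
#'   from the stem edge (cm).
#' @param cross_arm_width Cross corridor width (cm).
#' @param cue_side,reward_side `"left"` or `"right"`; must agree.
#' @param reward_zone_depth Depth of the reward/punishment zones at the
#'   distal cross-arm ends (cm).
#' @param timeout_steps Environment-step budget per trial before timeout.
#' @param start_pose Initial pose; default is the stem centreline, 10 cm from
#'   the closed end, heading toward the junction.
#' @param robot Robot geometry overrides, see [robot_spec()].
#'
#' @return An object of class `maze_config`.
#' @export
maze_config <- function(central_arm_length = 120, central_arm_width = 40,
                        cross_arm_length = 120, cross_arm_width = 40,
                        cue_side = c("left", "right"),
                        reward_side = NULL,
                        reward_zone_depth = 10,
                        timeout_steps = 4000L,
                        start_pose = NULL,
                        robot = robot_spec()) {
  cue_side <- match.arg(cue_side)
  if (is.null(reward_side)) reward_side <- cue_side
  if (!identical(reward_side, cue_side)) {
    stop("cue_side and reward_side must agree: the tactile cue marks the rewarded arm")
  }
  dims <- c(central_arm_length, central_arm_width,
            cross_arm_length, cross_arm_width, reward_zone_depth)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop("all maze dimensions must be positive and finite")
  }
  if (central_arm_width < 2 * robot$body_radius ||
      cross_arm_width < 2 * robot$body_radius) {
    stop("corridor narrower than the robot body")
  }
  timeout_steps <- as.integer(timeout_steps)
  if (is.na(timeout_steps) || timeout_steps < 1L) stop("timeout_steps must be >= 1")

  hw_c <- central_arm_width / 2   # stem half width
  hw_x <- cross_arm_width / 2     # cross corridor half width
  x_end <- hw_c + cross_arm_length
  y_bottom <- -hw_x - central_arm_length

  maze <- structure(list(
    central_arm_length = central_arm_length,
    central_arm_width  = central_arm_width,
    cross_arm_length   = cross_arm_length,
    cross_arm_width    = cross_arm_width,
    cue_side = cue_side, reward_side = reward_side,
    reward_zone_depth = reward_zone_depth,
    timeout_steps = timeout_steps,
    robot = robot,
    # derived geometry
    hw_c = hw_c, hw_x = hw_x, x_end = x_end, y_bottom = y_bottom,
    cue_center = c(if (cue_side == "left") -hw_c else hw_c, -hw_x),
    cue_radius = 2
  ), class = "maze_config")
  maze$walls <- maze_walls(maze)
  maze$start_pose <- if (is.null(start_pose)) {
    robot_pose(0, y_bottom + 10, pi / 2)
  } else {
    start_pose
  }
  if (!pose_valid(maze$start_pose, maze)) {
    stop("start pose does not fit inside the central arm")
  }
  maze
}

#' Robot physical geometry
#'
#' e-puck-scale constants: body radius 3.7 cm, axle width 5.3 cm, 32 whiskers
#' of 20 cm split over the left and right body sides, 6 IR sensors on the
#' front half with 10 cm range.
#'
#' @param body_radius,axle_width,whisker_length,ir_range Geometry in cm.
#' @param n_whiskers,n_pixels,n_ir Sensor counts (32/20/6).
#' @param k_ir Fixed IR proportional constant.
#' @return A plain list of robot constants.
#' @export
robot_spec <- function(body_radius = 3.7, axle_width = 5.3,
                       whisker_length = 20, ir_range = 10,
                       n_whiskers = 32L, n_pixels = 20L, n_ir = 6L,
                       k_ir = 1.0) {
  list(body_radius = body_radius, axle_width = axle_width,
       whisker_length = whisker_length, ir_range = ir_range,
       n_whiskers = as.integer(n_whiskers), n_pixels = as.integer(n_pixels),
       n_ir = as.integer(n_ir), k_ir = k_ir)
}

#' Robot pose
#'
#' @param x,y Position of the body centre (cm).
#' @param heading Heading in radians, counter-clockwise from `+x`.
#' @return A `robot_pose` object (named numeric of length 3).
#' @export
robot_pose <- function(x, y, heading) {
  p <- c(x = as.numeric(x), y = as.numeric(y), heading = as.numeric(heading))
  if (any(!is.finite(p))) stop("non-finite pose")
  class(p) <- "robot_pose"
  p
}

# Wall segment table. Each row: x1,y1,x2,y2 and a black flag. The black wall
# defaults to the full distal wall of the cross corridor (top of the T).
maze_walls <- function(maze) {
  hw_c <- maze$hw_c; hw_x <- maze$hw_x
  xe <- maze$x_end; yb <- maze$y_bottom
  w <- rbind(
    c(-hw_c, yb,     hw_c, yb),      # closed end of the stem
    c(-hw_c, yb,    -hw_c, -hw_x),   # stem left wall
    c( hw_c, yb,     hw_c, -hw_x),   # stem right wall
    c(-xe,  -hw_x,  -hw_c, -hw_x),   # cross bottom, left of junction
    c( hw_c, -hw_x,  xe,  -hw_x),    # cross bottom, right of junction
    c(-xe,  -hw_x,  -xe,   hw_x),    # left end wall
    c( xe,  -hw_x,   xe,   hw_x),    # right end wall
    c(-xe,   hw_x,   xe,   hw_x)     # distal back wall (black)
  )
  colnames(w) <- c("x1", "y1", "x2", "y2")
  list(seg = w, black = c(rep(FALSE, 7), TRUE))
}

# Point-membership in the maze free space (union of stem and cross corridor).
inside_free <- function(x, y, maze) {
  in_stem  <- abs(x) <= maze$hw_c & y >= maze$y_bottom & y <= -maze$hw_x
  in_cross <- abs(x) <= maze$x_end & abs(y) <= maze$hw_x
  in_stem | in_cross
}

# Minimum distance from (x, y) to the wall set and the cue post surface.
wall_clearance <- function(x, y, maze) {
  s <- maze$walls$seg
  dx <- s[, "x2"] - s[, "x1"]
  dy <- s[, "y2"] - s[, "y1"]
  len2 <- dx * dx + dy * dy
  t <- ((x - s[, "x1"]) * dx + (y - s[, "y1"]) * dy) / len2
  t <- pmin(1, pmax(0, t))
  px <- s[, "x1"] + t * dx
  py <- s[, "y1"] + t * dy
  d <- sqrt((x - px)^2 + (y - py)^2)
  cue <- maze$cue_center
  d_cue <- sqrt((x - cue[1])^2 + (y - cue[2])^2) - maze$cue_radius
  min(min(d), d_cue)
}

# A pose is valid when the body disc fits in free space.
pose_valid <- function(pose, maze) {
  inside_free(pose[["x"]], pose[["y"]], maze) &&
    wall_clearance(pose[["x"]], pose[["y"]], maze) >= maze$robot$body_radius
}

# Which zone (if any) contains the body centre: +1 reward, -1 punishment, 0.
zone_at <- function(x, y, maze) {
  if (abs(y) > maze$hw_x) return(0)
  depth <- maze$reward_zone_depth
  in_left  <- x <= -maze$x_end + depth && x >= -maze$x_end
  in_right <- x >=  maze$x_end - depth && x <=  maze$x_end
  if (!in_left && !in_right) return(0)
  reward_left <- maze$reward_side == "left"
  if ((in_left && reward_left) || (in_right && !reward_left)) 1 else -1
}

# Flip the rewarded (and cued) side, preserving everything else.
toggle_reward_side <- function(maze) {
  other <- if (maze$reward_side == "left") "right" else "left"
  maze$reward_side <- other
  maze$cue_side <- other
  maze$cue_center <- c(if (other == "left") -maze$hw_c else maze$hw_c, -maze$hw_x)
  maze
}

#' @export
print.maze_config <- function(x, ...) {
  cat("T-maze (", x$central_arm_length, "x", x$central_arm_width,
      " stem, 2x", x$cross_arm_length, "x", x$cross_arm_width, " cross, cm)\n",
      sep = "")
  cat("  reward/cue side: ", x$reward_side,
      ", zone depth ", x$reward_zone_depth, " cm",
      ", timeout ", x$timeout_steps, " steps\n", sep = "")
  cat("  start pose: (", round(x$start_pose[["x"]], 2), ", ",
      round(x$start_pose[["y"]], 2), ") heading ",
      round(x$start_pose[["heading"]], 3), " rad\n", sep = "")
  invisible(x)
}

#' @export
print.robot_pose <- function(x, ...) {
  cat(sprintf("pose (%.2f, %.2f) heading %.3f rad\n",
              x[["x"]], x[["y"]], x[["heading"]]))
  invisible(x)
}
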