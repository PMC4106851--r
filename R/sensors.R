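#' One tick of sensor readings
#'
#' Computes the four sensory channels at a pose:
#'
#' * `whiskers`: 32 binary values (16 per body side, fanned over the side
#'   arcs), 1 exactly when the whisker segment touches the tactile cue post.
#'   Whiskers sense nothing but the cue.
#' * `camera`: 20-pixel omnidirectional panorama. Each pixel covers an 18
#'   degree bearing bin (bin 1 starts at the heading); a pixel is 1 when any
#'   part of its bin's visible field is the black back wall, and 0 otherwise
#'   (all other surfaces are white/transparent). Visibility is computed
#'   exactly by a critical-angle sweep over wall-endpoint bearings, with
#'   occlusion.
#' * `ir`: 6 front-half proximity readings, `k_ir * max(0, 1 - d/d_max)`
#'   where `d` is the body-surface-to-wall distance along the sensor ray
#'   (`d_max` = 10 cm); 0 beyond range, so readings decrease with distance.
#' * `reward`: +1 inside the reward zone, -1 inside the punishment zone,
#'   0 elsewhere.
#'
#' @param pose A valid [robot_pose()].
#' @param maze A [maze_config()].
#' @param params Unused; accepted so callers can pass controller parameters
#'   uniformly (input scaling happens in the controller, not the sensors).
#' @return A `sensor_frame`: list with `whiskers`, `camera`, `ir`, `reward`.
#' @export
sense <- function(pose, maze, params = NULL) {
  rb <- maze$robot
  x <- pose[["x"]]; y <- pose[["y"]]; th <- pose[["heading"]]

  frame <- list(
    whiskers = sense_whiskers(x, y, th, maze),
    camera   = sense_camera(x, y, th, maze),
    ir       = sense_ir(x, y, th, maze),
    reward   = zone_at(x, y, maze)
  )
  class(frame) <- "sensor_frame"
  frame
}

# Body-frame whisker angles: 16 fanned along each side of the body.
whisker_angles <- function(n = 32L) {
  half <- n %/% 2L
  left <- seq(10, 170, length.out = half) * pi / 180
  c(left, -left)
}

sense_whiskers <- function(x, y, th, maze) {
  rb <- maze$robot
  ang <- th + whisker_angles(rb$n_whiskers)
  cx <- cos(ang); cy <- sin(ang)
  x0 <- x + rb$body_radius * cx
  y0 <- y + rb$body_radius * cy
  x1 <- x + (rb$body_radius + rb$whisker_length) * cx
  y1 <- y + (rb$body_radius + rb$whisker_length) * cy
  cue <- maze$cue_center
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  t <- ((cue[1] - x0) * dx + (cue[2] - y0) * dy) / len2
  t <- pmin(1, pmax(0, t))
  d <- sqrt((cue[1] - (x0 + t * dx))^2 + (cue[2] - (y0 + t * dy))^2)
  as.integer(d <= maze$cue_radius)
}

# First wall hit along a ray from (x, y) at absolute angle a.
# Returns c(distance, segment index); Inf if nothing is hit (cannot happen
# from inside a closed maze).
ray_first_hit <- function(x, y, a, seg) {
  dx <- cos(a); dy <- sin(a)
  ex <- seg[, "x2"] - seg[, "x1"]
  ey <- seg[, "y2"] - seg[, "y1"]
  denom <- dx * ey - dy * ex
  wx <- seg[, "x1"] - x
  wy <- seg[, "y1"] - y
  t <- (wx * ey - wy * ex) / denom
  s <- (wx * dy - wy * dx) / denom
  t[!is.finite(t) | s < 0 | s > 1 | t < 1e-9] <- Inf
  i <- which.min(t)
  c(t[i], i)
}

# Visible angular intervals (absolute bearings, possibly wrapping) in which
# the first-hit surface is the black wall. Exact up to the critical-angle
# decomposition: between consecutive wall-endpoint bearings the first-hit
# segment is constant, so one midpoint ray per interval suffices.
black_visible_intervals <- function(x, y, maze) {
  seg <- maze$walls$seg
  black <- maze$walls$black
  ang <- atan2(c(seg[, "y1"], seg[, "y2"]) - y,
               c(seg[, "x1"], seg[, "x2"]) - x) %% (2 * pi)
  ang <- sort(unique(c(ang, 0)))
  bounds <- c(ang, ang[1] + 2 * pi)
  out <- NULL
  for (k in seq_len(length(bounds) - 1L)) {
    a0 <- bounds[k]; a1 <- bounds[k + 1L]
    if (a1 - a0 < 1e-12) next
    hit <- ray_first_hit(x, y, (a0 + a1) / 2, seg)
    if (is.finite(hit[1]) && black[hit[2]]) {
      out <- rbind(out, c(a0, a1))
    }
  }
  out
}

sense_camera <- function(x, y, th, maze) {
  n <- maze$robot$n_pixels
  px <- numeric(n)
  iv <- black_visible_intervals(x, y, maze)
  if (is.null(iv)) return(px)
  width <- 2 * pi / n
  b0 <- (th + (seq_len(n) - 1L) * width) %% (2 * pi)
  for (k in seq_len(n)) {
    if (circ_overlap(b0[k], b0[k] + width, iv) > 1e-9) px[k] <- 1
  }
  px
}

# Total overlap length between interval [a0, a1] (a1 > a0, a0 in [0, 2pi))
# and a matrix of intervals with the same convention, on the circle.
circ_overlap <- function(a0, a1, iv) {
  tot <- 0
  for (r in seq_len(nrow(iv))) {
    for (shift in c(-2 * pi, 0, 2 * pi)) {
      lo <- max(a0, iv[r, 1] + shift)
      hi <- min(a1, iv[r, 2] + shift)
      if (hi > lo) tot <- tot + (hi - lo)
    }
  }
  tot
}

# Body-frame IR directions: 6 uniform across the front half.
ir_angles <- function(n = 6L) {
  seq(-75, 75, length.out = n) * pi / 180
}

sense_ir <- function(x, y, th, maze) {
  rb <- maze$robot
  seg <- maze$walls$seg
  ang <- th + ir_angles(rb$n_ir)
  out <- numeric(rb$n_ir)
  for (k in seq_along(ang)) {
    hit <- ray_first_hit(x, y, ang[k], seg)
    d <- max(0, hit[1] - rb$body_radius)
    out[k] <- rb$k_ir * max(0, 1 - d / rb$ir_range)
  }
  out
}

#' @export
print.sensor_frame <- function(x, ...) {
  cat("sensor frame: ", sum(x$whiskers), "/", length(x$whiskers),
      " whiskers, ", sum(x$camera > 0), "/", length(x$camera),
      " dark pixels, max IR ", round(max(x$ir), 3),
      ", reward ", x$reward, "\n", sep = "")
  invisible(x)
}
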