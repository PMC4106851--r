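#' Count vicarious trial-and-error events in a motor output series
#'
#' A VTE event is a filtered sign change of the signed motor value
#' `m = 2u - 1`. Under the default `"hysteresis"` rule (a Schmitt trigger)
#' an event fires each time `m` crosses from above `+theta` to below
#' `-theta` or vice versa since the last event, which filters the noisy
#' fluctuation around zero turning. The alternative `"delta"` rule counts a
#' step as an event when `m` changes sign and `|m_t - m_{t-1}| > 2 theta`.
#'
#' @param u_series Motor outputs per neural step, values in `[0, 1]`.
#' @param theta Threshold in `[0, 1]`.
#' @param rule `"hysteresis"` (default) or `"delta"`.
#' @param mask Optional logical vector (same length) restricting counting to
#'   a window, e.g. near the choice point; events are counted only at
#'   masked-in samples, with detector state still tracked over the whole
#'   series.
#' @return Integer count, with attribute `events`: data frame of
#'   `neural_step`, `from_value`, `to_value` (signed motor values around
#'   each crossing).
#' @export
count_vtes <- function(u_series, theta = 0.1, rule = c("hysteresis", "delta"),
                       mask = NULL) {
  rule <- match.arg(rule)
  if (length(u_series) == 0) {
    out <- 0L
    attr(out, "events") <- data.frame(neural_step = integer(),
                                      from_value = numeric(),
                                      to_value = numeric())
    return(out)
  }
  if (any(u_series < 0 | u_series > 1, na.rm = TRUE)) {
    stop("motor outputs must lie in [0, 1]")
  }
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  m <- 2 * u_series - 1
  n <- length(m)
  if (!is.null(mask)) stopifnot(length(mask) == n)

  if (rule == "hysteresis") {
    # vectorised Schmitt trigger: keep samples outside the threshold band,
    # count alternations of their sign
    band <- ifelse(m > theta, 1L, ifelse(m < -theta, -1L, 0L))
    idx <- which(band != 0L)
    ev_at <- integer(0)
    if (length(idx) > 1L) {
      flips <- which(diff(band[idx]) != 0L) + 1L
      ev_at <- idx[flips]
    }
    prev_at <- if (length(ev_at)) idx[match(ev_at, idx) - 1L] else integer(0)
  } else {
    sgn <- sign(m)
    ev_at <- which(seq_len(n) > 1 &
                   sgn != c(0, sgn[-n]) & sgn != 0 & c(0, sgn[-n]) != 0 &
                   abs(m - c(0, m[-n])) > 2 * theta)
    prev_at <- ev_at - 1L
  }
  if (!is.null(mask) && length(ev_at)) {
    keep <- mask[ev_at]
    ev_at <- ev_at[keep]
    prev_at <- prev_at[keep]
  }
  out <- length(ev_at)
  attr(out, "events") <- data.frame(
    neural_step = ev_at,
    from_value = m[prev_at],
    to_value = m[ev_at]
  )
  out
}

#' Per-trial VTE counts for a session
#'
#' @param session A `session_record` from [run_session()].
#' @param theta,rule,choice_point_radius See [count_vtes()]; when
#'   `choice_point_radius` is finite, only neural steps whose pose lies
#'   within that distance of the junction centre are counted (the
#'   rodent-protocol windowed variant).
#' @return Integer vector of per-trial counts.
#' @export
session_vte_counts <- function(session, theta = 0.1,
                               rule = c("hysteresis", "delta"),
                               choice_point_radius = Inf) {
  rule <- match.arg(rule)
  vapply(session$records, function(rec) {
    u <- rec$neural_log$u
    mask <- NULL
    if (is.finite(choice_point_radius)) {
      es <- pmin(rec$neural_log$env_step, nrow(rec$trajectory) - 1L)
      xy <- rec$trajectory[es + 1L, c("x", "y"), drop = FALSE]
      mask <- sqrt(xy$x^2 + xy$y^2) <= choice_point_radius
    }
    as.integer(count_vtes(u, theta = theta, rule = rule, mask = mask))
  }, integer(1))
}

#' Run a session with online VTE suppression
#'
#' Re-runs the maze-solving session while detecting VTE events online at the
#' motor level; each would-be event overrides that neural step's motor
#' output to `u = 0.5` (zero angular velocity), forcing the robot to keep
#' its current direction. The Hebbian pathway sees the overridden motor
#' state. `theta = 1` blocks nothing (sigmoid outputs never leave the unit
#' band) and reproduces the unsuppressed session bit-exactly; `theta = 0`
#' blocks every sign change.
#'
#' @param controller Controller at the state it would enter the session.
#' @param maze A [maze_config()].
#' @param theta Suppression threshold in `[0, 1]`.
#' @param n_trials,learning,start Passed to [run_session()].
#' @return The `session_record`, whose `blocked` field is the total number
#'   of suppressed events over the session.
#' @export
suppress_vte_session <- function(controller, maze, theta, n_trials = 100L,
                                 learning = TRUE, start = maze$start_pose) {
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  run_session(controller, maze, n_trials = n_trials, learning = learning,
              start = start, theta_suppress = theta)
}

#' Classify a per-trial VTE profile
#'
#' A documented heuristic standing in for by-eye classification: with
#' `early = mean(counts[1:20])` and `late` the mean over the last half of
#' the session,
#'
#' * `"HL"` (high-to-low, the rat-like pattern) when `early >= 2 * late`
#'   and the early peak reaches `floor`;
#' * `"H"` when the overall mean reaches `floor` without such a decline;
#' * `"L"` when the overall mean stays below `floor`;
#' * `"unclassified"` otherwise.
#'
#' @param counts Per-trial VTE counts, at least 20 trials.
#' @param floor_count Minimum VTE level treated as "high" (events/trial).
#' @return Character label with attribute `stats` (early, late and overall
#'   means) — the label never travels without its statistics.
#' @export
classify_vte_pattern <- function(counts, floor_count = 2) {
  if (length(counts) < 20L) stop("need at least 20 trials to classify")
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- length(counts)
  early <- mean(counts[1:20])
  late <- mean(counts[(n %/% 2 + 1):n])
  overall <- mean(counts)
  label <- if (early >= 2 * late && max(counts[1:20]) >= floor_count) {
    "HL"
  } else if (overall >= floor_count) {
    "H"
  } else if (overall < floor_count) {
    "L"
  } else {
    "unclassified"
  }
  attr(label, "stats") <- c(early = early, late = late, overall = overall)
  label
}
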