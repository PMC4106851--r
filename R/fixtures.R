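#' Deterministic test fixtures
#'
#' Builds the scripted policies, canned genomes and synthetic series used
#' throughout the test suite and examples:
#'
#' * `oracle_policy` — ground-truth waypoint steering into the currently
#'   rewarded arm; succeeds on every trial.
#' * `timeout_policy` — constant hard turn; circles inside the central arm
#'   until the step budget runs out.
#' * `zigzag_policy` — alternates between two motor values every `period`
#'   neural steps for exactly `k` sign crossings, then holds 0.5; the
#'   programmed crossing count makes VTE detector checks exact.
#' * `canned_genome` — reproducible 49-gene genome (`stats::runif` under
#'   `seed`).
#' * `logistic_series` — iterates the chaotic logistic map
#'   `x <- 4 x (1 - x)`; its analytic largest Lyapunov exponent is `log(2)`.
#' * `sine_series` — pure sinusoid (periodic, zero exponent).
#'
#' @param kind Fixture name as above.
#' @param ... Fixture-specific knobs: `delta`, `V`, `c` for policies;
#'   `n_crossings`, `period`, `u_hi`, `u_lo` for the zig-zag; `seed` for the
#'   genome;
#'   `n`, `x0` for the logistic map; `n`, `period`, `amplitude` for the
#'   sinusoid.
#' @return A [scripted_policy()], numeric genome, or numeric series.
#' @export
make_fixture <- function(kind = c("oracle_policy", "timeout_policy",
                                  "zigzag_policy", "canned_genome",
                                  "logistic_series", "sine_series"), ...) {
  kind <- match.arg(kind)
  args <- list(...)
  switch(kind,
    oracle_policy = oracle_policy(delta = args$delta %||% 5L,
                                  V = args$V %||% 1, c = args$c %||% 1),
    timeout_policy = scripted_policy(
      function(pose, frame, step, maze) 0.9,
      delta = args$delta %||% 10L, V = args$V %||% 1, c = args$c %||% 1,
      name = "timeout"),
    zigzag_policy = zigzag_policy(k = args$n_crossings %||% 10L,
                                  period = args$period %||% 5L,
                                  u_hi = args$u_hi %||% 0.9,
                                  u_lo = args$u_lo %||% 0.1,
                                  delta = args$delta %||% 10L),
    canned_genome = {
      set.seed(args$seed %||% 42L)
      stats::runif(49)
    },
    logistic_series = {
      n <- args$n %||% 5000L
      x <- numeric(n)
      x[1] <- args$x0 %||% 0.2
      for (i in seq_len(n - 1L)) x[i + 1L] <- 4 * x[i] * (1 - x[i])
      x
    },
    sine_series = {
      n <- args$n %||% 2000L
      period <- args$period %||% 50
      amp <- args$amplitude %||% 1
      amp * sin(2 * pi * seq_len(n) / period)
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Ground-truth steering: head for the junction centre while in the stem,
# then for the centre of the rewarded zone. Proportional heading control.
oracle_policy <- function(delta = 5L, V = 1, c = 1, gain = 1.2) {
  fn <- function(pose, frame, step, maze) {
    x <- pose[["x"]]; y <- pose[["y"]]; th <- pose[["heading"]]
    if (y < -4) {
      tx <- 0; ty <- 0
    } else {
      xz <- maze$x_end - maze$reward_zone_depth / 2
      tx <- if (maze$reward_side == "left") -xz else xz
      ty <- 0
    }
    err <- atan2(ty - y, tx - x) - th
    err <- atan2(sin(err), cos(err))  # wrap to (-pi, pi]
    min(1, max(0, 0.5 + gain * err))
  }
  scripted_policy(fn, delta = delta, V = V, c = c, name = "oracle")
}

# Exactly k programmed threshold crossings: phases of `period` neural steps
# alternate u_hi / u_lo for k + 1 phases, then hold 0.5.
zigzag_policy <- function(k = 10L, period = 5L, u_hi = 0.9, u_lo = 0.1,
                          delta = 10L) {
  fn <- function(pose, frame, step, maze) {
    t <- (step - 1L) %/% delta + 1L  # neural step index
    phase <- (t - 1L) %/% period + 1L
    if (phase > k + 1L) return(0.5)
    if (phase %% 2L == 1L) u_hi else u_lo
  }
  p <- scripted_policy(fn, delta = delta, V = 1, c = 1, name = "zigzag")
  p$k <- as.integer(k)
  p
}
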