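# Canonical module order and sizes (tactile 32, vision 20, IR 6, reward 1,
# motor 1). All pair bookkeeping uses this order.
module_order <- c("tactile", "vision", "ir", "reward", "motor")
module_sizes <- c(tactile = 32L, vision = 20L, ir = 6L, reward = 1L, motor = 1L)

#' Ordered module pairs of the controller
#'
#' @param topology `"full"` (all 20 ordered pairs between distinct modules),
#'   `"minimal"` (the five task-sufficient pathways: touch-vision, IR-motor,
#'   touch-motor, reward-vision, vision-motor) or a character vector of
#'   `"from->to"` labels for a custom mask.
#' @return Character vector of `"from->to"` pair labels.
#' @export
controller_pairs <- function(topology = "full") {
  all <- as.vector(outer(module_order, module_order,
                         function(a, b) paste0(a, "->", b)))
  keep <- as.vector(outer(module_order, module_order, `!=`))
  all <- all[keep]
  if (identical(topology, "full")) return(all)
  if (identical(topology, "minimal")) {
    return(c("tactile->vision", "ir->motor", "tactile->motor",
             "reward->vision", "vision->motor"))
  }
  if (is.character(topology)) {
    bad <- setdiff(topology, all)
    if (length(bad)) stop("unknown module pairs: ", paste(bad, collapse = ", "))
    return(topology)
  }
  stop("topology must be 'full', 'minimal' or a character mask")
}

#' Controller parameters
#'
#' The 49 evolvable scalars of the controller: a learning rate `eta` and a
#' forgetting rate `zeta` for each of the 20 ordered module pairs (40), the
#' neural update period `delta` in environment steps (integer in `[10, 30]`),
#' the delayed-state lag `tau` in neural steps, the shared sigmoid slope, the
#' motor conversion constant `c` for each phase, the forward velocity `V`,
#' and the proportional input constants for the light, touch and reward
#' modules (the IR constant is fixed in [robot_spec()]).
#'
#' @param eta,zeta Scalar (recycled) or named vector over
#'   [controller_pairs()] labels.
#' @param delta Neural update period, environment steps per controller tick.
#' @param tau Delayed-state lag in neural steps.
#' @param slope Shared sigmoid slope `a` in `1/(1 + exp(-a x))`.
#' @param c_familiarization,c_maze Turn conversion constant per phase.
#' @param V Forward velocity (cm per environment step).
#' @param k_light,k_touch,k_reward Proportional input constants.
#' @param topology See [controller_pairs()].
#' @param normalize_input When `TRUE`, each source module's contribution in
#'   the virtual-unit update is scaled by `1/size(j)`; default is a plain sum.
#' @return A `controller_params` object.
#' @export
controller_params <- function(eta = 0.1, zeta = 0.01,
                              delta = 10L, tau = 2L, slope = 1,
                              c_familiarization = 1, c_maze = 1, V = 1,
                              k_light = 1, k_touch = 1, k_reward = 1,
                              topology = "full", normalize_input = FALSE) {
  pairs <- controller_pairs(topology)
  expand <- function(x, what) {
    if (length(x) == 1L) {
      x <- stats::setNames(rep(as.numeric(x), length(pairs)), pairs)
    } else {
      if (is.null(names(x)) || !all(pairs %in% names(x))) {
        stop(what, " must be a scalar or a vector named by pair labels")
      }
      x <- x[pairs]
    }
    if (any(!is.finite(x)) || any(x < 0)) stop(what, " must be finite and >= 0")
    x
  }
  delta <- as.integer(round(delta))
  if (delta < 10L || delta > 30L) stop("delta must lie in [10, 30]")
  tau <- as.integer(round(tau))
  if (tau < 1L) stop("tau must be >= 1")
  if (V <= 0) stop("V must be positive")
  structure(list(
    eta = expand(eta, "eta"), zeta = expand(zeta, "zeta"),
    delta = delta, tau = tau, slope = slope,
    c_familiarization = c_familiarization, c_maze = c_maze, V = V,
    k_light = k_light, k_touch = k_touch, k_reward = k_reward,
    topology = topology, pairs = pairs, normalize_input = normalize_input
  ), class = "controller_params")
}

#' Construct the five-module Hebbian controller
#'
#' Each model neuron carries two units: a *state* unit mirroring the raw
#' sensor/motor signal and driving Hebbian plasticity, and a *virtual* unit
#' carrying internally propagated signals and driving behaviour. The two
#' pathways are deliberately separated: virtual units never enter the
#' learning rule, which avoids the runaway positive feedback of plain
#' Hebbian dynamics. The reward module's virtual unit is pinned to 1, which
#' makes the propagated error `v - s` a standing "seek the reward" drive.
#'
#' @param params A [controller_params()].
#' @return A `hebbian_controller` object with zeroed weights and virtual
#'   units (reward virtual unit = 1) and held motor output 0.5.
#' @export
hebbian_controller <- function(params = controller_params()) {
  stopifnot(inherits(params, "controller_params"))
  ctrl <- structure(list(params = params), class = "hebbian_controller")
  reset_phase(ctrl)
}

#' Reset the controller at a phase boundary
#'
#' Zeroes the virtual units (except the reward module, pinned at 1) and the
#' state-history buffers; by default also zeroes every synaptic weight, as
#' at the start of the familiarization phase. With `carry_weights = TRUE`
#' the weights learned so far survive, which is how familiarization feeds
#' the maze-solving phase.
#'
#' @param controller A `hebbian_controller`.
#' @param carry_weights Keep the current weights instead of zeroing them.
#' @return The reset controller.
#' @export
reset_phase <- function(controller, carry_weights = FALSE) {
  p <- controller$params
  zero <- lapply(module_sizes, function(n) numeric(n))
  names(zero) <- names(module_sizes)
  controller$s <- zero
  controller$v <- zero
  controller$v$reward <- 1
  controller$hist <- list()
  controller$u <- 0.5
  if (!carry_weights || is.null(controller$W)) {
    controller$W <- lapply(p$pairs, function(pr) {
      ft <- pair_from_to(pr)
      matrix(0, nrow = module_sizes[[ft[2]]], ncol = module_sizes[[ft[1]]])
    })
    names(controller$W) <- p$pairs
  }
  controller
}

pair_from_to <- function(pair) strsplit(pair, "->", fixed = TRUE)[[1]]

#' Load a sensor frame into the state units
#'
#' State units are set proportional to the raw signals: `k_touch * whiskers`,
#' `k_light * camera`, the IR readings as delivered by the sensor (whose
#' fixed proportional constant lives in [robot_spec()]), `k_reward * reward`,
#' and the currently held motor output for the motor module. The previous
#' state vector is pushed onto the delay history used by the Hebbian rule.
#'
#' @param controller A `hebbian_controller`.
#' @param frame A `sensor_frame` from [sense()].
#' @return The updated controller.
#' @export
set_states <- function(controller, frame) {
  p <- controller$params
  if (length(frame$whiskers) != module_sizes[["tactile"]] ||
      length(frame$camera) != module_sizes[["vision"]] ||
      length(frame$ir) != module_sizes[["ir"]]) {
    stop("sensor frame dimensions do not match module sizes")
  }
  controller$s <- list(
    tactile = p$k_touch * as.numeric(frame$whiskers),
    vision  = p$k_light * as.numeric(frame$camera),
    ir      = as.numeric(frame$ir),
    reward  = p$k_reward * as.numeric(frame$reward),
    motor   = controller$u
  )
  controller$hist <- c(list(controller$s),
                       controller$hist)[seq_len(min(length(controller$hist) + 1L,
                                                    p$tau + 1L))]
  controller
}

# State vector tau neural steps back; zeros where history is still short.
delayed_states <- function(controller) {
  p <- controller$params
  if (length(controller$hist) > p$tau) {
    controller$hist[[p$tau + 1L]]
  } else {
    zero <- lapply(module_sizes, function(n) numeric(n))
    names(zero) <- names(module_sizes)
    zero
  }
}

#' Apply the modified Hebbian rule to every enabled weight matrix
#'
#' For each enabled ordered pair `j -> i`,
#' `W <- W + eta * (ds_i %o% s_j) - zeta * W`, where
#' `ds_i = s_i(t) - s_i(t - tau)` is the *change* of the postsynaptic state
#' over the delay lag. Weights therefore grow exactly when presynaptic
#' activity and postsynaptic change coincide, and decay geometrically at
#' rate `(1 - zeta)` otherwise. Virtual units never enter this rule.
#'
#' @param controller A `hebbian_controller` whose states are current.
#' @return The updated controller.
#' @export
hebbian_update <- function(controller) {
  p <- controller$params
  s <- controller$s
  sd <- delayed_states(controller)
  for (pr in p$pairs) {
    ft <- pair_from_to(pr)
    ds_i <- s[[ft[2]]] - sd[[ft[2]]]
    controller$W[[pr]] <- controller$W[[pr]] +
      p$eta[[pr]] * outer(ds_i, s[[ft[1]]]) -
      p$zeta[[pr]] * controller$W[[pr]]
  }
  controller
}

#' Propagate signals through the virtual units
#'
#' Every module except the reward updates synchronously:
#' `v_i = sigmoid( sum_j W[j->i] %*% (v_j - s_j) )` over the enabled incoming
#' pairs, with `sigmoid(x) = 1 / (1 + exp(-slope * x))`. The reward module's
#' virtual unit stays pinned at 1. The motor module's virtual unit is the
#' motor output `u`.
#'
#' @param controller A `hebbian_controller` with weights current.
#' @return The updated controller; the new motor output is
#'   `controller$u` (also `controller$v$motor`).
#' @export
virtual_update <- function(controller) {
  p <- controller$params
  e <- mapply(function(v, s) v - s, controller$v, controller$s,
              SIMPLIFY = FALSE)
  net <- lapply(module_sizes, function(n) numeric(n))
  names(net) <- names(module_sizes)
  for (pr in p$pairs) {
    ft <- pair_from_to(pr)
    contrib <- as.numeric(controller$W[[pr]] %*% e[[ft[1]]])
    if (p$normalize_input) contrib <- contrib / module_sizes[[ft[1]]]
    net[[ft[2]]] <- net[[ft[2]]] + contrib
  }
  for (m in setdiff(names(module_sizes), "reward")) {
    controller$v[[m]] <- 1 / (1 + exp(-p$slope * net[[m]]))
  }
  controller$v$reward <- 1
  controller$u <- controller$v$motor
  controller
}

#' One controller tick
#'
#' Executes the model's per-neural-step order: sensory transfer to the state
#' units, the Hebbian weight update (skipped when `learning = FALSE`), the
#' virtual-unit propagation, and the read-out of the motor output. Between
#' ticks the engine holds `u` constant and recomputes wheel speeds from it
#' every environment step.
#'
#' @param controller A `hebbian_controller` or [scripted_policy()].
#' @param frame The current `sensor_frame`.
#' @param learning Apply the Hebbian update?
#' @param ... Passed to methods (scripted policies receive `pose` and
#'   `step`).
#' @return List with `controller` (updated) and `u` in `(0, 1)`.
#' @export
tick <- function(controller, frame, learning = TRUE, ...) {
  UseMethod("tick")
}

#' @export
tick.hebbian_controller <- function(controller, frame, learning = TRUE, ...) {
  controller <- set_states(controller, frame)
  if (learning) controller <- hebbian_update(controller)
  controller <- virtual_update(controller)
  list(controller = controller, u = controller$u)
}

#' @export
print.hebbian_controller <- function(x, ...) {
  w <- vapply(x$W, function(m) mean(abs(m)), numeric(1))
  cat("Hebbian controller: ", length(x$params$pairs), " pairs (",
      if (is.character(x$params$topology) && length(x$params$topology) == 1)
        x$params$topology else "custom",
      " topology), delta = ", x$params$delta,
      ", held u = ", round(x$u, 4), "\n", sep = "")
  cat("  mean |W|: ", signif(mean(w), 4),
      ", nonzero pairs: ", sum(w > 0), "/", length(w), "\n", sep = "")
  invisible(x)
}

#' @export
print.controller_params <- function(x, ...) {
  cat("controller parameters (", length(x$pairs),
      " pairs): delta = ", x$delta, ", tau = ", x$tau,
      ", slope = ", signif(x$slope, 4),
      ", V = ", signif(x$V, 4),
      ", c = (", signif(x$c_familiarization, 4), ", ",
      signif(x$c_maze, 4), ")\n", sep = "")
  invisible(x)
}
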