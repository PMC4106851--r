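#' Canonical genome layout
#'
#' The 49 evolvable scalars, in the fixed gene order used by
#' [decode_genome()]: for each of the 20 ordered module pairs (in
#' [controller_pairs()] order) a learning rate then a forgetting rate
#' (40 genes), followed by `delta`, `tau`, the sigmoid slope, the motor
#' conversion constants for the familiarization and maze-solving phases,
#' the forward velocity `V`, and the proportional constants for the light,
#' touch and reward modules.
#'
#' @return Character vector of 49 gene names.
#' @export
genome_layout <- function() {
  pairs <- controller_pairs("full")
  c(as.vector(rbind(paste0("eta:", pairs), paste0("zeta:", pairs))),
    "delta", "tau", "slope", "c_familiarization", "c_maze", "V",
    "k_light", "k_touch", "k_reward")
}

# Affine gene -> parameter ranges. Rates live in [0, 1]; delta is the
# documented [10, 30]; tau counts neural steps in [1, 5]; the slope spans
# [0.1, 10]; speeds and input gains span [0.1, 5].
gene_ranges <- function() {
  nm <- genome_layout()
  lo <- stats::setNames(rep(0, length(nm)), nm)
  hi <- stats::setNames(rep(1, length(nm)), nm)
  lo["delta"] <- 10; hi["delta"] <- 30
  lo["tau"] <- 1; hi["tau"] <- 5
  lo["slope"] <- 0.1; hi["slope"] <- 10
  for (g in c("c_familiarization", "c_maze", "V",
              "k_light", "k_touch", "k_reward")) {
    lo[g] <- 0.1; hi[g] <- 5
  }
  list(lo = lo, hi = hi)
}

#' Decode a 49-gene genome into controller parameters
#'
#' Genes in `[0, 1]` are mapped affinely onto their documented ranges (see
#' [genome_layout()]); `delta` and `tau` are rounded to integers. Decoding
#' is deterministic and clamps genes into `[0, 1]` first.
#'
#' @param genome Numeric vector of exactly 49 values.
#' @param topology Controller topology passed through to
#'   [controller_params()]; rates of disabled pairs are simply unused.
#' @return A [controller_params()] object.
#' @export
decode_genome <- function(genome, topology = "full") {
  if (length(genome) != 49L) {
    stop("genome must have exactly 49 genes, got ", length(genome))
  }
  g <- pmin(1, pmax(0, as.numeric(genome)))
  r <- gene_ranges()
  val <- stats::setNames(r$lo + g * (r$hi - r$lo), genome_layout())
  pairs <- controller_pairs("full")
  eta <- stats::setNames(val[paste0("eta:", pairs)], pairs)
  zeta <- stats::setNames(val[paste0("zeta:", pairs)], pairs)
  controller_params(
    eta = eta, zeta = zeta,
    delta = round(val[["delta"]]), tau = round(val[["tau"]]),
    slope = val[["slope"]],
    c_familiarization = val[["c_familiarization"]],
    c_maze = val[["c_maze"]], V = val[["V"]],
    k_light = val[["k_light"]], k_touch = val[["k_touch"]],
    k_reward = val[["k_reward"]],
    topology = topology
  )
}

#' Default per-outcome fitness rewards
#'
#' Reaching the reward scores +5 per trial and everything else 0, so the
#' standard 100-trial protocol has a maximum fitness of 500.
#' @return Named numeric vector over outcomes.
#' @export
fitness_rewards <- function() {
  c(reward = 5, punishment = 0, timeout = 0, wall_reset = 0)
}

#' Evaluate a genome (or controller) on the full protocol
#'
#' Runs the complete familiarization phase followed by an `n_trials`
#' maze-solving session from the fixed start pose, and sums the per-outcome
#' rewards. Under the default table a controller that reaches the reward on
#' all 100 trials scores 500.
#'
#' @param g A 49-gene genome, a [controller_params()], a
#'   `hebbian_controller`, or a [scripted_policy()] (scripted policies skip
#'   familiarization — they have nothing to learn).
#' @param maze A [maze_config()].
#' @param n_trials Trials in the maze-solving session.
#' @param rewards Per-outcome reward table.
#' @param topology Used when `g` is a raw genome.
#' @return The summed fitness (numeric scalar); attribute `session` carries
#'   the session record.
#' @export
evaluate_fitness <- function(g, maze, n_trials = 100L,
                             rewards = fitness_rewards(),
                             topology = "full") {
  controller <- if (inherits(g, "scripted_policy")) {
    g
  } else if (inherits(g, "hebbian_controller")) {
    g
  } else if (inherits(g, "controller_params")) {
    hebbian_controller(g)
  } else {
    hebbian_controller(decode_genome(g, topology = topology))
  }
  if (inherits(controller, "hebbian_controller")) {
    fam <- run_familiarization(controller, maze)
    controller <- fam$controller
  }
  sess <- run_session(controller, maze, n_trials = n_trials)
  fit <- sum(rewards[sess$outcomes])
  attr(fit, "session") <- sess
  fit
}

#' Evolve genomes with the standard GA
#'
#' Tournament selection, single-point crossover with probability 0.7,
#' per-gene uniform-redraw mutation at rate 0.01, and elitism copying the
#' five best individuals unchanged into the next generation. Reproducible
#' under a fixed seed.
#'
#' @param fitness Fitness function taking one genome and returning a
#'   scalar; defaults to [evaluate_fitness()] against `maze`.
#' @param maze Maze used by the default fitness (ignored when a custom
#'   `fitness` is given).
#' @param pop_size,generations Population size and generation count
#'   (the reference budget is 100 and 1000).
#' @param n_genes Genome length.
#' @param elite Number of elites copied unchanged.
#' @param tournament_size Tournament size for parent selection.
#' @param p_crossover,p_mutation Crossover and per-gene mutation rates.
#' @param seed RNG seed.
#' @param n_trials Trials per evaluation for the default fitness.
#' @param verbose Print a line per generation.
#' @return A `ga_state`: final `population` (list), `fitness` vector,
#'   `best_genome`, `best_fitness`, and a per-generation `history` data
#'   frame (generation, best, mean, quartiles).
#' @export
evolve <- function(fitness = NULL, maze = maze_config(),
                   pop_size = 100L, generations = 1000L,
                   n_genes = 49L, elite = 5L, tournament_size = 3L,
                   p_crossover = 0.7, p_mutation = 0.01,
                   seed = 1L, n_trials = 100L, verbose = FALSE) {
  if (pop_size <= elite) stop("population must exceed the elite count")
  if (is.null(fitness)) {
    fitness <- function(g) as.numeric(evaluate_fitness(g, maze, n_trials = n_trials))
  }
  set.seed(seed)
  pop <- lapply(seq_len(pop_size), function(i) stats::runif(n_genes))
  hist_rows <- vector("list", generations)
  fit <- vapply(pop, fitness, numeric(1))
  for (gen in seq_len(generations)) {
    ord <- order(fit, decreasing = TRUE)
    q <- stats::quantile(fit, c(0.25, 0.5, 0.75), names = FALSE)
    hist_rows[[gen]] <- data.frame(
      generation = gen, best = fit[ord[1]], mean = mean(fit),
      q25 = q[1], median = q[2], q75 = q[3]
    )
    if (verbose) {
      message(sprintf("gen %d: best %.2f mean %.2f", gen, fit[ord[1]], mean(fit)))
    }
    if (gen == generations) break
    next_pop <- pop[ord[seq_len(elite)]]
    while (length(next_pop) < pop_size) {
      pa <- pop[[tournament_pick(fit, tournament_size)]]
      pb <- pop[[tournament_pick(fit, tournament_size)]]
      child <- if (stats::runif(1) < p_crossover) {
        cut <- sample.int(n_genes - 1L, 1L)
        c(pa[seq_len(cut)], pb[(cut + 1L):n_genes])
      } else {
        pa
      }
      mut <- stats::runif(n_genes) < p_mutation
      if (any(mut)) child[mut] <- stats::runif(sum(mut))
      next_pop[[length(next_pop) + 1L]] <- child
    }
    new_fit <- c(fit[ord[seq_len(elite)]],
                 vapply(next_pop[(elite + 1L):pop_size], fitness, numeric(1)))
    pop <- next_pop
    fit <- new_fit
  }
  best <- which.max(fit)
  structure(list(
    population = pop, fitness = fit,
    best_genome = pop[[best]], best_fitness = fit[best],
    history = do.call(rbind, hist_rows),
    seed = seed, pop_size = pop_size, generations = generations
  ), class = "ga_state")
}

tournament_pick <- function(fit, k) {
  cand <- sample.int(length(fit), k, replace = FALSE)
  cand[which.max(fit[cand])]
}

#' @export
print.ga_state <- function(x, ...) {
  cat("GA run: ", x$pop_size, " individuals x ", x$generations,
      " generations (seed ", x$seed, ")\n", sep = "")
  cat("  best fitness ", round(x$best_fitness, 3), "\n", sep = "")
  invisible(x)
}
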