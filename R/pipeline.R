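#' Default run configuration
#'
#' A complete, explicit configuration for [run_pipeline()]: every default
#' the simulator relies on is materialized here, so a serialized config
#' carries no hidden constants.
#'
#' @return Nested list with `maze`, `controller`, `ga`, `analysis`, `seed`
#'   and `out_dir` sections.
#' @export
default_run_config <- function() {
  list(
    maze = list(
      central_arm_length = 120, central_arm_width = 40,
      cross_arm_length = 120, cross_arm_width = 40,
      cue_side = "left", reward_zone_depth = 10, timeout_steps = 4000
    ),
    controller = list(topology = "full", genome = NULL,
                      normalize_input = FALSE),
    ga = list(pop_size = 100, generations = 1000, n_trials = 100,
              elite = 5, tournament_size = 3,
              p_crossover = 0.7, p_mutation = 0.01),
    analysis = list(
      stages = c("session", "vte"),
      n_trials = 100, theta = 0.1, vte_rule = "hysteresis",
      vte_floor = 2,
      mle = list(m = 5, J = 1, fit_len = 10, mean_period = "weighted"),
      robustness = list(nx = 7, ny = 40, n_trials = 100)
    ),
    seed = 1, out_dir = NULL
  )
}

#' Read a run configuration from JSON
#'
#' Unspecified fields fall back to [default_run_config()] values, section
#' by section.
#'
#' @param path JSON file path.
#' @return Config list.
#' @export
read_run_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  user$config_hash <- NULL
  merge_config(default_run_config(), user)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Write a run configuration (with its hash) to JSON
#'
#' @param config Config list.
#' @param path Output path.
#' @return The config hash, invisibly.
#' @export
write_run_config <- function(config, path) {
  h <- config_hash(config)
  config$config_hash <- h
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(h)
}

#' MD5 hash of a configuration's canonical JSON form
#'
#' @param config Config list.
#' @return Hash string.
#' @export
config_hash <- function(config) {
  config$config_hash <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(canonical_numbers(config), tmp, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

# Whole-number doubles and integers serialize identically and NULL entries
# are dropped, so a JSON round-trip keeps the hash stable.
canonical_numbers <- function(x) {
  if (is.list(x)) {
    x <- x[!vapply(x, is.null, logical(1))]
    return(lapply(x, canonical_numbers))
  }
  if (is.double(x) && length(x) && all(is.finite(x)) &&
      all(x == round(x)) && all(abs(x) < .Machine$integer.max)) {
    return(as.integer(x))
  }
  x
}

maze_from_config <- function(cfg) {
  m <- cfg$maze
  maze_config(
    central_arm_length = m$central_arm_length,
    central_arm_width = m$central_arm_width,
    cross_arm_length = m$cross_arm_length,
    cross_arm_width = m$cross_arm_width,
    cue_side = m$cue_side,
    reward_zone_depth = m$reward_zone_depth,
    timeout_steps = m$timeout_steps
  )
}

#' Run the configured pipeline
#'
#' Orchestrates the requested stages in order: `evolve` (GA over the 49
#' parameters), `session` (familiarization plus maze-solving trials),
#' `vte` (per-trial counts and pattern label), `mle` (per-module Lyapunov
#' summary) and `robustness` (start-position grid). All randomness is
#' seeded from `config$seed`; identical configs produce identical bundles.
#' When `config$out_dir` is set, each stage writes CSV/JSON artifacts
#' stamped with the config hash and seed.
#'
#' @param config See [default_run_config()].
#' @return A result bundle (list by stage) with the config and its hash.
#' @export
run_pipeline <- function(config = default_run_config()) {
  hash <- config_hash(config)
  maze <- maze_from_config(config)
  set.seed(config$seed)
  out <- list(config = config, config_hash = hash)
  stages <- config$analysis$stages
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_config(config, file.path(out_dir, "config.json"))
  }
  stamp <- function(x) c(x, list(config_hash = hash, seed = config$seed))
  emit_json <- function(x, name) {
    if (!is.null(out_dir)) {
      jsonlite::write_json(stamp(x), file.path(out_dir, name),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
  }
  emit_csv <- function(df, name) {
    if (!is.null(out_dir)) {
      utils::write.csv(cbind(df, config_hash = hash, seed = config$seed),
                       file.path(out_dir, name), row.names = FALSE)
    }
  }

  genome <- config$controller$genome
  if ("evolve" %in% stages) {
    ga <- config$ga
    out$evolve <- evolve(maze = maze, pop_size = ga$pop_size,
                         generations = ga$generations,
                         elite = ga$elite,
                         tournament_size = ga$tournament_size,
                         p_crossover = ga$p_crossover,
                         p_mutation = ga$p_mutation,
                         seed = config$seed, n_trials = ga$n_trials)
    genome <- out$evolve$best_genome
    emit_csv(out$evolve$history, "ga_history.csv")
    emit_json(list(best_genome = genome,
                   best_fitness = out$evolve$best_fitness),
              "best_genome.json")
  }

  needs_session <- any(c("session", "vte", "mle") %in% stages)
  if (needs_session) {
    if (is.null(genome)) stop("session stage needs a genome (or an evolve stage)")
    params <- decode_genome(genome, topology = config$controller$topology)
    params$normalize_input <- isTRUE(config$controller$normalize_input)
    ctrl <- hebbian_controller(params)
    fam <- run_familiarization(ctrl, maze)
    sess <- run_session(fam$controller, maze,
                        n_trials = config$analysis$n_trials,
                        theta_suppress = config$analysis$theta_suppress)
    out$session <- sess
    trials <- data.frame(
      trial = seq_len(sess$n_trials), outcome = sess$outcomes,
      env_steps = vapply(sess$records, function(r) r$env_steps, integer(1))
    )
    if ("vte" %in% stages) {
      counts <- session_vte_counts(sess, theta = config$analysis$theta,
                                   rule = config$analysis$vte_rule)
      if (length(counts) >= 20L) {
        label <- classify_vte_pattern(counts,
                                      floor_count = config$analysis$vte_floor)
        lab_chr <- as.character(label)
        lab_stats <- as.list(attr(label, "stats"))
      } else {
        lab_chr <- NA_character_  # too few trials to read a profile
        lab_stats <- list(overall = mean(counts))
      }
      out$vte <- list(counts = counts, label = lab_chr,
                      stats = lab_stats,
                      theta = config$analysis$theta,
                      rule = config$analysis$vte_rule)
      trials$vte_count <- counts
      emit_json(out$vte, "vte.json")
    }
    emit_csv(trials, "trials.csv")
    emit_json(list(success_rate = sess$success_rate,
                   n_trials = sess$n_trials,
                   blocked = sess$blocked),
              "session_summary.json")
    if ("mle" %in% stages) {
      mle_cfg <- config$analysis$mle
      out$mle <- session_mle(sess, m = mle_cfg$m, J = mle_cfg$J,
                             fit_len = mle_cfg$fit_len,
                             mean_period = mle_cfg$mean_period)
      emit_csv(out$mle$summary, "mle_summary.csv")
    }
  }

  if ("robustness" %in% stages) {
    if (is.null(genome)) stop("robustness stage needs a genome")
    rcfg <- config$analysis$robustness
    params <- decode_genome(genome, topology = config$controller$topology)
    ctrl <- hebbian_controller(params)
    grid <- start_position_grid(maze, rcfg$nx, rcfg$ny)
    out$robustness <- robustness_grid(ctrl, maze, grid = grid,
                                      n_trials = rcfg$n_trials)
    emit_csv(out$robustness$grid, "robustness.csv")
    emit_json(list(mean = out$robustness$mean,
                   variance = out$robustness$variance,
                   n_positions = out$robustness$n_positions),
              "robustness_summary.json")
  }
  out
}

#' Serialize a trial record to plain-text logs
#'
#' Writes one CSV per log stream (trajectory, neural log, optional weight
#' means) plus a JSON summary carrying outcome, step counts, seed and the
#' config hash.
#'
#' @param rec A `trial_record`.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @param config_hash Hash to stamp into the summary.
#' @return The summary path, invisibly.
#' @export
write_trial_record <- function(rec, dir, prefix = "trial",
                               config_hash = NA_character_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rec$trajectory,
                   file.path(dir, paste0(prefix, "_trajectory.csv")),
                   row.names = FALSE)
  utils::write.csv(rec$neural_log,
                   file.path(dir, paste0(prefix, "_neural_log.csv")),
                   row.names = FALSE)
  if (!is.null(rec$weight_means)) {
    utils::write.csv(as.data.frame(rec$weight_means),
                     file.path(dir, paste0(prefix, "_weights.csv")),
                     row.names = FALSE)
  }
  summary_path <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(list(
    trial_index = rec$trial_index, phase = rec$phase,
    outcome = rec$outcome, env_steps = rec$env_steps,
    neural_steps = nrow(rec$neural_log),
    blocked = rec$blocked, seed = rec$seed,
    config_hash = config_hash
  ), summary_path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
     null = "null")
  invisible(summary_path)
}

#' Serialize controller parameters to a flat JSON record
#'
#' @param params A [controller_params()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_controller_params <- function(params, path) {
  jsonlite::write_json(list(
    eta = as.list(params$eta), zeta = as.list(params$zeta),
    delta = params$delta, tau = params$tau, slope = params$slope,
    c_familiarization = params$c_familiarization, c_maze = params$c_maze,
    V = params$V, k_light = params$k_light, k_touch = params$k_touch,
    k_reward = params$k_reward,
    topology = params$topology, normalize_input = params$normalize_input
  ), path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read controller parameters from a flat JSON record
#'
#' @param path JSON file written by [write_controller_params()].
#' @return A [controller_params()].
#' @export
read_controller_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  controller_params(
    eta = unlist(x$eta), zeta = unlist(x$zeta), delta = x$delta,
    tau = x$tau, slope = x$slope,
    c_familiarization = x$c_familiarization, c_maze = x$c_maze, V = x$V,
    k_light = x$k_light, k_touch = x$k_touch, k_reward = x$k_reward,
    topology = x$topology, normalize_input = isTRUE(x$normalize_input)
  )
}

#' Save a weight set as a dense numeric array with a JSON header
#'
#' Values go to `<path>.txt` (one number per line, pair-major, row-major
#' within each matrix); `<path>.json` names each ordered pair and its
#' dimensions.
#'
#' @param W Named list of weight matrices (a controller's `$W`).
#' @param path Path prefix (no extension).
#' @return `path`, invisibly.
#' @export
save_weights <- function(W, path) {
  header <- lapply(names(W), function(pr) {
    list(pair = pr, nrow = nrow(W[[pr]]), ncol = ncol(W[[pr]]))
  })
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  vals <- unlist(lapply(W, function(m) as.vector(t(m))), use.names = FALSE)
  writeLines(format(vals, digits = 17, trim = TRUE, scientific = TRUE),
             paste0(path, ".txt"))
  invisible(path)
}

#' Load a weight set saved by [save_weights()]
#'
#' @param path Path prefix (no extension).
#' @return Named list of weight matrices.
#' @export
load_weights <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  vals <- as.numeric(readLines(paste0(path, ".txt")))
  W <- list()
  at <- 1L
  for (h in header) {
    n <- h$nrow * h$ncol
    W[[h$pair]] <- matrix(vals[at:(at + n - 1L)], nrow = h$nrow,
                          byrow = TRUE)
    at <- at + n
  }
  W
}
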