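#' Maximum Lyapunov exponent by the Rosenstein small-data method
#'
#' Estimates the largest Lyapunov exponent of a scalar series:
#'
#' 1. delay-embed into `m`-dimensional vectors with lag `J`;
#' 2. compute the series' mean period from the FFT power spectrum (by
#'    default the reciprocal of the power-weighted mean frequency;
#'    alternatively the dominant spectral peak) and pair each embedded
#'    point with its Euclidean nearest neighbour at temporal separation
#'    greater than the mean period;
#' 3. track the log of each pair's distance over time, average the
#'    log-distance curve over pairs, and take the least-squares slope of
#'    its first `fit_len` points as the exponent (per neural step).
#'
#' The fit is accepted only when its R-squared exceeds 0.8; rejected fits
#' and negative slopes report `lambda1 = 0`, so the reported exponent is
#' always non-negative. Pairs at exactly zero distance are floored at
#' machine epsilon times the series scale.
#'
#' @param x Numeric series (needs `length > (m - 1) * J + fit_len + 1`).
#' @param m Embedding dimension.
#' @param J Embedding delay (samples).
#' @param fit_len Number of initial divergence-curve points fitted.
#' @param mean_period `"weighted"` or `"peak"`.
#' @param r2_min Acceptance gate on the fit.
#' @return An `mle_estimate`: `lambda1`, `r_squared`, `accepted`,
#'   `n_points`, `params`, and the full divergence curve for inspection.
#' @export
mle_rosenstein <- function(x, m = 5L, J = 1L, fit_len = 10L,
                           mean_period = c("weighted", "peak"),
                           r2_min = 0.8) {
  mean_period <- match.arg(mean_period)
  x <- as.numeric(x)
  n <- length(x)
  if (n <= (m - 1L) * J + fit_len + 1L) {
    stop("series too short for embedding dimension ", m,
         ", delay ", J, " and fit length ", fit_len)
  }
  if (stats::sd(x) == 0) {
    return(reject_estimate(n, m, J, fit_len, fit_len))
  }

  # delay embedding: rows are reconstructed vectors
  M <- n - (m - 1L) * J
  emb <- matrix(0, nrow = M, ncol = m)
  for (k in seq_len(m)) emb[, k] <- x[seq_len(M) + (k - 1L) * J]

  # mean period from the power spectrum
  xc <- x - mean(x)
  p <- Mod(stats::fft(xc))^2
  half <- 2:(n %/% 2 + 1L)
  freq <- (half - 1L) / n
  pw <- p[half]
  mp <- if (sum(pw) == 0) {
    1
  } else if (mean_period == "weighted") {
    1 / (sum(pw * freq) / sum(pw))
  } else {
    1 / freq[which.max(pw)]
  }
  min_sep <- max(1L, ceiling(mp))

  # nearest neighbour with temporal exclusion, chunked for memory
  nn <- integer(M)
  nn_d <- rep(Inf, M)
  sq <- rowSums(emb^2)
  chunk <- max(1L, min(M, 2048L))
  for (from in seq(1L, M, by = chunk)) {
    to <- min(M, from + chunk - 1L)
    rows <- from:to
    d2 <- outer(sq[rows], sq, "+") - 2 * emb[rows, , drop = FALSE] %*% t(emb)
    sep <- abs(outer(rows, seq_len(M), "-"))
    d2[sep <= min_sep] <- Inf
    j <- max.col(-d2, ties.method = "first")
    nn[rows] <- j
    nn_d[rows] <- sqrt(pmax(0, d2[cbind(seq_along(rows), j)]))
  }
  usable <- which(is.finite(nn_d))
  if (!length(usable)) return(reject_estimate(n, m, J, fit_len, fit_len))

  # mean log-divergence curve over pairs
  n_track <- fit_len + 5L
  floor_d <- .Machine$double.eps * max(stats::sd(x), 1e-12)
  curve <- numeric(n_track)
  counts <- integer(n_track)
  for (k in 0:(n_track - 1L)) {
    i <- usable[usable + k <= M & nn[usable] + k <= M]
    if (!length(i)) break
    di <- sqrt(rowSums((emb[i + k, , drop = FALSE] -
                        emb[nn[i] + k, , drop = FALSE])^2))
    di <- pmax(di, floor_d)
    curve[k + 1L] <- mean(log(di))
    counts[k + 1L] <- length(i)
  }
  valid <- which(counts > 0)
  if (length(valid) < fit_len) {
    return(reject_estimate(n, m, J, fit_len, length(valid),
                           curve = curve[valid]))
  }

  kk <- 0:(fit_len - 1L)
  yy <- curve[seq_len(fit_len)]
  slope <- stats::cov(kk, yy) / stats::var(kk)
  r2 <- if (stats::var(yy) == 0) 0 else stats::cor(kk, yy)^2
  accepted <- r2 > r2_min
  lambda1 <- if (!accepted || slope < 0) 0 else slope
  structure(list(
    lambda1 = lambda1, r_squared = r2, accepted = accepted,
    slope = slope, n_points = n, mean_period = mp,
    params = list(m = m, J = J, fit_len = fit_len),
    divergence = curve[valid], pair_counts = counts[valid]
  ), class = "mle_estimate")
}

reject_estimate <- function(n, m, J, fit_len, n_valid, curve = numeric(0)) {
  structure(list(
    lambda1 = 0, r_squared = 0, accepted = FALSE, slope = NA_real_,
    n_points = n, mean_period = NA_real_,
    params = list(m = m, J = J, fit_len = fit_len),
    divergence = curve, pair_counts = integer(0)
  ), class = "mle_estimate")
}

#' @export
print.mle_estimate <- function(x, ...) {
  cat(sprintf("MLE estimate: lambda1 = %.4f per step (R^2 = %.3f, %s; n = %d, m = %d, J = %d, fit %d)\n",
              x$lambda1, x$r_squared,
              if (x$accepted) "accepted" else "rejected",
              x$n_points, x$params$m, x$params$J, x$params$fit_len))
  invisible(x)
}

#' Extract per-module neural series from a session
#'
#' For each trial: the motor series is the motor output (the motor module's
#' virtual unit) per neural step; each sensory module's series is the mean
#' over its neurons of `v - s`, the propagated internal signal. These are
#' the quantities that actually drive behaviour, hence the ones whose
#' divergence is measured.
#'
#' @param session A `session_record` with neural logs from a
#'   `hebbian_controller`.
#' @return A list (one element per trial) of lists of numeric series named
#'   `tactile`, `vision`, `ir`, `reward`, `motor`.
#' @export
extract_module_series <- function(session) {
  lapply(session$records, function(rec) {
    nl <- rec$neural_log
    if (is.null(nl$vs_tactile)) {
      stop("session has no per-module neural logs (scripted policy?)")
    }
    list(
      tactile = nl$vs_tactile, vision = nl$vs_vision, ir = nl$vs_ir,
      reward = nl$vs_reward, motor = nl$u
    )
  })
}

#' Per-module MLE summary over a session
#'
#' Applies [mle_rosenstein()] to every trial's per-module series (short,
#' roughly 15-150 points each, so the estimates read as transient-chaos
#' divergence rates) and aggregates mean and standard deviation per module.
#' Trials too short for the embedding yield rejected estimates
#' (`lambda1 = 0`) rather than errors.
#'
#' @param session A `session_record`.
#' @inheritParams mle_rosenstein
#' @return A list with `summary` (data frame: module, mean, sd, n_accepted)
#'   and `estimates` (per-trial list of per-module `mle_estimate`s).
#' @export
session_mle <- function(session, m = 5L, J = 1L, fit_len = 10L,
                        mean_period = "weighted", r2_min = 0.8) {
  series <- extract_module_series(session)
  estimates <- lapply(series, function(tr) {
    lapply(tr, function(x) {
      tryCatch(
        mle_rosenstein(x, m = m, J = J, fit_len = fit_len,
                       mean_period = mean_period, r2_min = r2_min),
        error = function(e) reject_estimate(length(x), m, J, fit_len, 0L)
      )
    })
  })
  mods <- names(series[[1]])
  summary <- do.call(rbind, lapply(mods, function(mod) {
    lam <- vapply(estimates, function(tr) tr[[mod]]$lambda1, numeric(1))
    acc <- vapply(estimates, function(tr) tr[[mod]]$accepted, logical(1))
    data.frame(module = mod, mean = mean(lam), sd = stats::sd(lam),
               n_accepted = sum(acc), n_trials = length(lam))
  }))
  list(summary = summary, estimates = estimates)
}
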