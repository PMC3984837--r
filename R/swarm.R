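#' Swarm configuration
#'
#' Defaults follow the standard configuration of the method: 30 particles,
#' up to 100 iterations or a fitness of 1, cognitive and social constants
#' `c1 = c2 = 2`, inertia decreasing linearly from 0.9 to 0.4 over
#' `max_iter` for the real coordinate and fixed at 1 for the binary
#' coordinates, real position range `[-1, 1]`, and velocity clamps 0.1
#' (real) and 6 (binary).
#'
#' @param n_particles Swarm size (>= 2).
#' @param max_iter Iteration budget.
#' @param c1,c2 Cognitive and social acceleration constants.
#' @param inertia_start,inertia_end Real-coordinate inertia ramp endpoints.
#' @param inertia_binary Constant inertia of the binary coordinates.
#' @param x_real_range Feasible range of the real coordinate.
#' @param v_max_real,v_max_binary Velocity clamps per coordinate kind.
#' @param target_fitness Early-stopping fitness threshold.
#' @param seed Integer seed driving initialization and all stochastic
#'   updates.
#' @return An object of class `swarm_config`.
#' @export
swarm_config <- function(n_particles = 30L, max_iter = 100L, c1 = 2, c2 = 2,
                         inertia_start = 0.9, inertia_end = 0.4,
                         inertia_binary = 1, x_real_range = c(-1, 1),
                         v_max_real = 0.1, v_max_binary = 6,
                         target_fitness = 1.0, seed = 1L) {
  if (n_particles < 2L) stop("n_particles must be >= 2")
  if (c1 <= 0 || c2 <= 0) stop("c1 and c2 must be > 0")
  if (v_max_real <= 0 || v_max_binary <= 0) stop("velocity clamps must be > 0")
  structure(list(n_particles = as.integer(n_particles),
                 max_iter = as.integer(max_iter), c1 = c1, c2 = c2,
                 inertia_start = inertia_start, inertia_end = inertia_end,
                 inertia_binary = inertia_binary,
                 x_real_range = as.numeric(x_real_range),
                 v_max_real = v_max_real, v_max_binary = v_max_binary,
                 target_fitness = target_fitness, seed = as.integer(seed)),
            class = "swarm_config")
}

#' Decode a particle position
#'
#' The position `x = [a, b_1 .. b_64]` encodes the FDA regularization as
#' `lambda = 10^(5a)` and the channel set as the indices of the set bits,
#' in ascending order.
#'
#' @param a Real coordinate in `[-1, 1]`.
#' @param bits 0/1 vector of channel-inclusion bits.
#' @return List with `lambda` and `channels`.
#' @export
decode_particle <- function(a, bits) {
  list(lambda = 10^(5 * a), channels = which(bits == 1))
}

#' Feasibility of a position (invisible wall)
#'
#' A position is feasible iff the real coordinate lies inside its range
#' and at least one channel bit is set.  Infeasible positions are never
#' evaluated and never update personal or global bests; the particles
#' carrying them keep moving and are expected to fly back.
#'
#' @param a Real coordinate.
#' @param bits 0/1 bit vector.
#' @param x_real_range Feasible real range.
#' @return Logical.
#' @export
is_feasible <- function(a, bits, x_real_range = c(-1, 1)) {
  a >= x_real_range[1] && a <= x_real_range[2] && any(bits == 1)
}

#' Inertia weight schedule
#'
#' Linear ramp `inertia_start - (inertia_start - inertia_end) * t /
#' max_iter` for the real coordinate; the binary coordinates use the
#' constant `inertia_binary`.
#'
#' @param t Iteration in `0..max_iter`.
#' @param config A [swarm_config()].
#' @param kind `"real"` or `"binary"`.
#' @return Scalar inertia weight.
#' @export
inertia_weight <- function(t, config = swarm_config(), kind = c("real", "binary")) {
  kind <- match.arg(kind)
  if (t < 0 || t > config$max_iter) stop("iteration t out of [0, max_iter]")
  if (kind == "binary") return(config$inertia_binary)
  config$inertia_start -
    (config$inertia_start - config$inertia_end) * t / config$max_iter
}

clamp <- function(x, vmax) pmin(pmax(x, -vmax), vmax)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One velocity update of a particle
#'
#' `v <- w v + c1 eta1 (p - x) + c2 eta2 (g - x)` with `eta1`, `eta2`
#' drawn independently per component, uniform on `[0, 1]`, then clamped
#' componentwise to the configured maxima.  The real component uses the
#' decaying inertia at iteration `t`; binary components use the constant
#' binary inertia.  Missing personal or global bests contribute nothing.
#'
#' @param x,v Position and velocity, each `c(a, bits)` of length 65.
#' @param pbest,gbest Personal and swarm best positions (or `NULL`).
#' @param t Iteration index for the inertia schedule.
#' @param config A [swarm_config()].
#' @return Clamped velocity vector, same length as `v`.
#' @export
update_velocity <- function(x, v, pbest, gbest, t, config = swarm_config()) {
  n <- length(x)
  w <- c(inertia_weight(t, config, "real"),
         rep(config$inertia_binary, n - 1L))
  cog <- if (is.null(pbest)) 0 else config$c1 * stats::runif(n) * (pbest - x)
  soc <- if (is.null(gbest)) 0 else config$c2 * stats::runif(n) * (gbest - x)
  vmax <- c(config$v_max_real, rep(config$v_max_binary, n - 1L))
  clamp(w * v + cog + soc, vmax)
}

#' One position update of a particle
#'
#' Real coordinate: `a <- a + v_a` (not clipped; the invisible wall
#' handles excursions).  Each binary coordinate is resampled to 1 with
#' probability `S(v_j) = 1 / (1 + exp(-v_j))` using a fresh uniform draw
#' per bit.
#'
#' @param x Position `c(a, bits)`.
#' @param v Freshly updated velocity.
#' @return Updated position vector.
#' @export
update_position <- function(x, v) {
  n <- length(x)
  a <- x[1] + v[1]
  bits <- as.numeric(stats::runif(n - 1L) < sigmoid(v[-1]))
  c(a, bits)
}

#' Hybrid real-binary particle swarm search
#'
#' Runs the multiobjective hybrid PSO over `[a, b_1 .. b_n]`: the real
#' coordinate is initialized uniformly on the feasible range, each bit
#' Bernoulli(0.5), and all velocities zero.  Each iteration evaluates the
#' feasible particles (an invisible-wall condition skips out-of-range
#' positions and empty channel sets), updates personal and global bests
#' on strict improvement, then moves the swarm.  Stops when the global
#' best fitness reaches `target_fitness` or after `max_iter` iterations.
#' Identical `(fitness, config)` including `config$seed` reproduce the
#' result exactly.  Revisited positions are served from a cache rather
#' than re-evaluated (the fitness must be deterministic, as the
#' cross-validated fitness with frozen folds is).
#'
#' @param fitness Function `(lambda, channels) -> `numeric fitness, or a
#'   list/`fitness_result` with elements `fitness` and optionally
#'   `gm_accuracy`, `n_channels`, `TP`, `TN`, `FP`, `FN`.
#' @param n_bits Number of binary coordinates (channels).
#' @param config A [swarm_config()].
#' @param cache Serve repeat positions from a cache (no semantic effect).
#' @param verbose Print per-iteration progress.
#' @return An object of class `mhpso`: `gbest` (position), `lambda`,
#'   `channels`, `gbest_fitness`, `gbest_detail`, `history` (data frame
#'   with one row per particle per iteration), `history_bits` (0/1
#'   matrix aligned with `history`), `iterations_run`, `terminated_by`,
#'   `n_evaluations`, `config`.
#' @export
mhpso_search <- function(fitness, n_bits = 64L, config = swarm_config(),
                         cache = TRUE, verbose = FALSE) {
  set.seed(config$seed)
  np <- config$n_particles
  rng_range <- config$x_real_range
  a <- stats::runif(np, rng_range[1], rng_range[2])
  B <- matrix(stats::rbinom(np * n_bits, 1L, 0.5), np, n_bits)
  va <- numeric(np)
  V <- matrix(0, np, n_bits)
  pbest_a <- rep(NA_real_, np)
  pbest_B <- matrix(NA_real_, np, n_bits)
  pbest_fit <- rep(-Inf, np)
  gbest_a <- NA_real_
  gbest_B <- NULL
  gbest_fit <- -Inf
  gbest_detail <- NULL

  memo <- new.env(parent = emptyenv())
  n_eval <- 0L
  detail_cols <- c("gm_accuracy", "n_channels", "TP", "TN", "FP", "FN")
  hist <- vector("list", config$max_iter)
  hist_bits <- vector("list", config$max_iter)
  terminated_by <- "max_iter"
  iterations_run <- 0L

  for (t in seq_len(config$max_iter)) {
    if (t > 1L) {
      for (i in seq_len(np)) {
        p <- if (is.finite(pbest_fit[i])) c(pbest_a[i], pbest_B[i, ]) else NULL
        g <- if (is.finite(gbest_fit)) c(gbest_a, gbest_B) else NULL
        vi <- update_velocity(c(a[i], B[i, ]), c(va[i], V[i, ]), p, g,
                              t - 1L, config)
        xi <- update_position(c(a[i], B[i, ]), vi)
        va[i] <- vi[1]; V[i, ] <- vi[-1]
        a[i] <- xi[1]; B[i, ] <- xi[-1]
      }
    }

    fit_t <- rep(NA_real_, np)
    feas_t <- logical(np)
    det_t <- matrix(NA_real_, np, length(detail_cols),
                    dimnames = list(NULL, detail_cols))
    for (i in seq_len(np)) {
      feas <- is_feasible(a[i], B[i, ], rng_range)
      feas_t[i] <- feas
      if (!feas) next
      key <- paste0(sprintf("%.15e", a[i]), "|",
                    paste(B[i, ], collapse = ""))
      res <- if (cache && !is.null(memo[[key]])) memo[[key]] else {
        dec <- decode_particle(a[i], B[i, ])
        r <- fitness(dec$lambda, dec$channels)
        n_eval <- n_eval + 1L
        if (cache) memo[[key]] <- r
        r
      }
      fv <- if (is.list(res)) res$fitness else res
      fit_t[i] <- fv
      if (is.list(res))
        for (cn in detail_cols)
          if (!is.null(res[[cn]])) det_t[i, cn] <- res[[cn]]
      if (fv > pbest_fit[i]) {
        pbest_fit[i] <- fv; pbest_a[i] <- a[i]; pbest_B[i, ] <- B[i, ]
      }
      if (fv > gbest_fit) {
        gbest_fit <- fv; gbest_a <- a[i]; gbest_B <- B[i, ]
        gbest_detail <- if (is.list(res)) res else NULL
      }
    }

    hist[[t]] <- data.frame(iteration = t, particle = seq_len(np), a = a,
                            fitness = fit_t, feasible = feas_t, det_t,
                            gbest_fitness = gbest_fit)
    hist_bits[[t]] <- B
    iterations_run <- t
    if (verbose)
      message(sprintf("iter %3d  gbest %.4f  evals %d", t, gbest_fit, n_eval))
    if (is.finite(gbest_fit) && gbest_fit >= config$target_fitness) {
      terminated_by <- "target"
      break
    }
  }

  history <- do.call(rbind, hist[seq_len(iterations_run)])
  history_bits <- do.call(rbind, hist_bits[seq_len(iterations_run)])
  if (!is.finite(gbest_fit)) {
    warning("no feasible position was ever evaluated")
    terminated_by <- "never_feasible"
  }
  dec <- if (is.finite(gbest_fit)) decode_particle(gbest_a, gbest_B)
         else list(lambda = NA_real_, channels = integer())
  structure(list(
    gbest = if (is.finite(gbest_fit)) c(gbest_a, gbest_B) else NULL,
    lambda = dec$lambda, channels = dec$channels,
    gbest_fitness = if (is.finite(gbest_fit)) gbest_fit else NA_real_,
    gbest_detail = gbest_detail,
    history = history, history_bits = history_bits,
    iterations_run = iterations_run, terminated_by = terminated_by,
    n_evaluations = n_eval, config = config
  ), class = "mhpso")
}

#' @export
print.mhpso <- function(x, ...) {
  cat("Hybrid real-binary PSO search\n")
  cat(sprintf("  %d iterations (%s), %d fitness evaluations\n",
              x$iterations_run, x$terminated_by, x$n_evaluations))
  cat(sprintf("  gbest fitness %.4f; lambda = %.4g; %d channels\n",
              x$gbest_fitness, x$lambda, length(x$channels)))
  if (!is.null(x$channel_names) && length(x$channels))
    cat("  channels:", paste(x$channel_names[x$channels], collapse = " "), "\n")
  else if (length(x$channels))
    cat("  channels:", paste(x$channels, collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.mhpso <- function(object, ...) {
  h <- object$history
  per_iter <- tapply(h$fitness, h$iteration, max, na.rm = TRUE)
  out <- list(gbest_fitness = object$gbest_fitness,
              lambda = object$lambda, channels = object$channels,
              n_channels = length(object$channels),
              iterations_run = object$iterations_run,
              terminated_by = object$terminated_by,
              n_evaluations = object$n_evaluations,
              best_per_iteration = per_iter,
              gbest_detail = object$gbest_detail)
  class(out) <- "summary.mhpso"
  out
}

#' @export
print.summary.mhpso <- function(x, ...) {
  cat(sprintf("MHPSO: gbest fitness %.4f after %d iterations (%s)\n",
              x$gbest_fitness, x$iterations_run, x$terminated_by))
  cat(sprintf("  lambda = %.4g, %d channels: %s\n", x$lambda, x$n_channels,
              paste(x$channels, collapse = " ")))
  if (!is.null(x$gbest_detail) && !is.null(x$gbest_detail$gm_accuracy))
    cat(sprintf("  CV gm accuracy %.4f (TP %d/%d, TN %d/%d)\n",
                x$gbest_detail$gm_accuracy, x$gbest_detail$TP,
                x$gbest_detail$TP + x$gbest_detail$FN,
                x$gbest_detail$TN, x$gbest_detail$TN + x$gbest_detail$FP))
  invisible(x)
}

#' Convergence / trade-off plot of a search
#'
#' `which = "convergence"` draws the global-best fitness per iteration;
#' `which = "pareto"` draws all feasible evaluated positions in the
#' (channel count, gm accuracy) plane with the Pareto front highlighted.
#'
#' @param x An `mhpso` object.
#' @param which Plot kind.
#' @param ... Passed to the base plotting function.
#' @export
plot.mhpso <- function(x, which = c("convergence", "pareto"), ...) {
  which <- match.arg(which)
  h <- x$history
  if (which == "convergence") {
    gb <- tapply(h$gbest_fitness, h$iteration, max)
    graphics::plot(as.integer(names(gb)), gb, type = "s",
                   xlab = "iteration", ylab = "global best fitness", ...)
  } else {
    pts <- h[h$feasible & !is.na(h$gm_accuracy),
             c("n_channels", "gm_accuracy")]
    front <- pareto_front(pts)
    graphics::plot(pts$n_channels, pts$gm_accuracy, pch = 16,
                   col = "grey70", xlab = "number of channels",
                   ylab = "CV gm accuracy", ...)
    o <- order(front$n_channels)
    graphics::lines(front$n_channels[o], front$gm_accuracy[o], type = "b",
                    pch = 19, col = "firebrick")
  }
  invisible(x)
}
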