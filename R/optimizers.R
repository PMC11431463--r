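#' Configuration for the particle-swarm optimizer
#'
#' The swarm moves each particle toward the other particles, attracted in
#' proportion to their fitness and in inverse proportion to their distance,
#' scaled by a learning rate below 1. Distances are computed in parameter
#' space normalised to the unit box by the declared bounds, so seconds and
#' degrees are commensurable.
#'
#' @param bounds Tibble with columns `parameter`, `lower`, `upper` (one row
#'   per optimised dimension). Degenerate bounds (`lower == upper`) pin that
#'   coordinate.
#' @param n_particles Swarm size, >= 1.
#' @param learning_rate Step scale, in (0, 1).
#' @param decay Multiplicative learning-rate decay per iteration (1 = fixed
#'   rate).
#' @param max_iterations Iteration budget.
#' @param convergence_eps Stop early when the maximum pairwise particle
#'   distance (normalised units) falls below this.
#' @param selection_strength Exponent of the attraction weights
#'   `exp(selection_strength * (f - max f) / (max f - min f))`: fitness is
#'   range-normalised over the current swarm before weighting, so selection
#'   pressure is preserved as the swarm contracts and fitness differences
#'   shrink. Larger values chase the best particles more greedily.
#' @param explore_alpha Initial amplitude (normalised units) of the uniform
#'   exploration jitter [run_swarm()] adds to each movement; decays by
#'   `explore_decay` each iteration. Drawn from the seeded RNG, so runs stay
#'   deterministic. Set to 0 for pure attraction moves.
#' @param explore_decay Multiplicative decay of the jitter amplitude.
#' @param distance_floor Minimum distance used in the inverse-distance
#'   weights, preventing blow-up for coincident particles.
#' @param seed RNG seed for particle initialisation and exploration.
#' @return A list of class `swarm_config`.
#' @export
swarm_config <- function(bounds, n_particles = 12, learning_rate = 0.1,
                         decay = 1, max_iterations = 60,
                         convergence_eps = 1e-3, selection_strength = 10,
                         explore_alpha = 0.2, explore_decay = 0.95,
                         distance_floor = 1e-6, seed = NULL) {
  bounds <- tibble::as_tibble(bounds)
  stopifnot(all(c("parameter", "lower", "upper") %in% names(bounds)),
            all(bounds$upper >= bounds$lower),
            n_particles >= 1,
            learning_rate > 0, learning_rate < 1,
            decay > 0, decay <= 1,
            max_iterations >= 1, selection_strength > 0,
            explore_alpha >= 0, explore_decay > 0, explore_decay <= 1,
            distance_floor > 0)
  structure(
    list(bounds = bounds, n_particles = n_particles,
         learning_rate = learning_rate, decay = decay,
         max_iterations = max_iterations,
         convergence_eps = convergence_eps,
         selection_strength = selection_strength,
         explore_alpha = explore_alpha, explore_decay = explore_decay,
         distance_floor = distance_floor, seed = seed),
    class = "swarm_config"
  )
}

.normalize <- function(x, bounds) {
  span <- bounds$upper - bounds$lower
  out <- sweep(x, 2, bounds$lower)
  out <- sweep(out, 2, ifelse(span > 0, span, 1), "/")
  out[, span == 0] <- 0
  out
}

.denormalize <- function(u, bounds) {
  span <- bounds$upper - bounds$lower
  sweep(sweep(u, 2, span, "*"), 2, bounds$lower, "+")
}

# Attractor-point movement rule in normalised space. Each particle steps a
# fraction eta of the way toward the point T_i = sum_j a_ij x_j / sum_j a_ij
# (j != i), with a_ij = w(f_j) / max(d_ij, floor): attraction proportional
# to (range-normalised) fitness, inversely proportional to distance, scaled
# by the learning rate, plus an optional uniform exploration jitter of
# amplitude alpha. Positions are clipped to the unit box.
.swarm_move <- function(u, fitness, eta, beta, floor_d, alpha = 0) {
  n <- nrow(u)
  if (n < 2) return(u)
  finite_f <- fitness[is.finite(fitness)]
  w <- if (length(finite_f) > 0 && diff(range(finite_f)) > 0) {
    clamped <- pmin(pmax(fitness, min(finite_f)), max(finite_f))
    exp(beta * (clamped - max(finite_f)) / diff(range(finite_f)))
  } else {
    rep(1, n)
  }
  new_u <- u
  for (i in seq_len(n)) {
    diff <- sweep(u[-i, , drop = FALSE], 2, u[i, ])
    d <- pmax(sqrt(rowSums(diff^2)), floor_d)
    a <- w[-i] / d
    target <- colSums(u[-i, , drop = FALSE] * a) / sum(a)
    jitter <- if (alpha > 0) alpha * (runif(ncol(u)) - 0.5) else 0
    new_u[i, ] <- u[i, ] + eta * (target - u[i, ]) + jitter
  }
  pmin(pmax(new_u, 0), 1)
}

#' One swarm movement step
#'
#' Moves every particle according to the fitness- and distance-weighted
#' attraction rule (see [swarm_config()]), leaving fitness values untouched.
#' A single particle does not move.
#'
#' @param particles Tibble with one column per bounded parameter plus a
#'   `fitness` column; all particles must be evaluated.
#' @param config A [swarm_config()].
#' @param learning_rate Override of the config's learning rate (used by
#'   [run_swarm()] when the rate decays).
#' @param explore_alpha Exploration jitter amplitude; 0 (the default here)
#'   makes the step a pure, deterministic attraction move.
#' @return `particles` with updated positions, clipped to the bounds.
#' @export
swarm_step <- function(particles, config,
                       learning_rate = config$learning_rate,
                       explore_alpha = 0) {
  stopifnot(inherits(config, "swarm_config"))
  particles <- tibble::as_tibble(particles)
  dims <- config$bounds$parameter
  stopifnot(all(dims %in% names(particles)), "fitness" %in% names(particles),
            all(is.finite(particles$fitness)))
  x <- as.matrix(particles[dims])
  u <- .normalize(x, config$bounds)
  u <- .swarm_move(u, particles$fitness, learning_rate,
                   config$selection_strength, config$distance_floor,
                   alpha = explore_alpha)
  particles[dims] <- as.data.frame(.denormalize(u, config$bounds))
  particles
}

#' Run the swarm optimizer
#'
#' Initialises `n_particles` uniformly inside the bounds, then alternates
#' evaluation and movement until the iteration budget is spent or the swarm
#' has collapsed below `convergence_eps`. If the objective fails on a
#' position the particle keeps its previous fitness and the event is logged
#' in the trace. The best position/fitness ever evaluated is tracked
#' separately from the (possibly stale) particle fitnesses.
#'
#' @param objective Function taking a named numeric vector (one element per
#'   bounded parameter) and returning a scalar fitness to maximise.
#' @param config A [swarm_config()].
#' @return A list of class `swarm_result`: `best_position` (named vector),
#'   `best_fitness`, `iterations`, `converged`, and `trace` (tibble with
#'   `iteration`, `particle`, the parameter columns, `fitness`,
#'   `eval_failed`).
#' @export
run_swarm <- function(objective, config) {
  stopifnot(inherits(config, "swarm_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  dims <- config$bounds$parameter
  d <- length(dims)
  n <- config$n_particles
  u <- matrix(runif(n * d), nrow = n)
  x <- .denormalize(u, config$bounds)
  colnames(x) <- dims
  fitness <- rep(NA_real_, n)
  best_fitness <- -Inf
  best_position <- setNames(rep(NA_real_, d), dims)
  eta <- config$learning_rate
  alpha <- config$explore_alpha
  trace <- vector("list", config$max_iterations)
  converged <- FALSE
  iter_done <- 0L

  for (iter in seq_len(config$max_iterations)) {
    failed <- logical(n)
    for (i in seq_len(n)) {
      val <- tryCatch(objective(setNames(x[i, ], dims)),
                      error = function(e) NA_real_)
      if (is.na(val) || !is.finite(val)) {
        failed[i] <- TRUE # keep previous fitness
        if (is.na(fitness[i])) fitness[i] <- -Inf
      } else {
        fitness[i] <- val
        if (val > best_fitness) {
          best_fitness <- val
          best_position <- setNames(x[i, ], dims)
        }
      }
    }
    trace[[iter]] <- dplyr::bind_cols(
      tibble::tibble(iteration = iter, particle = seq_len(n)),
      tibble::as_tibble(x),
      tibble::tibble(fitness = fitness, eval_failed = failed)
    )
    iter_done <- iter
    un <- .normalize(x, config$bounds)
    spread <- if (n > 1) max(stats::dist(un)) else 0
    if (spread < config$convergence_eps) {
      converged <- TRUE
      break
    }
    un <- .swarm_move(un, fitness, eta, config$selection_strength,
                      config$distance_floor, alpha = alpha)
    x <- .denormalize(un, config$bounds)
    colnames(x) <- dims
    eta <- eta * config$decay
    alpha <- alpha * config$explore_decay
  }
  structure(
    list(best_position = best_position, best_fitness = best_fitness,
         iterations = iter_done, converged = converged,
         trace = dplyr::bind_rows(trace)),
    class = "swarm_result"
  )
}

#' @export
print.swarm_result <- function(x, ...) {
  cat("<swarm_result>", x$iterations, "iterations,",
      if (x$converged) "converged" else "budget exhausted", "\n")
  cat("  best fitness:", format(x$best_fitness), "at\n")
  print(x$best_position)
  invisible(x)
}

#' @export
tidy.swarm_result <- function(x, ...) x$trace

#' @export
glance.swarm_result <- function(x, ...) {
  tibble::tibble(best_fitness = x$best_fitness, iterations = x$iterations,
                 converged = x$converged)
}

#' Plot swarm fitness over iterations
#' @param object A `swarm_result`.
#' @param ... Unused.
#' @return A ggplot of per-particle fitness with the running best overlaid.
#' @export
autoplot.swarm_result <- function(object, ...) {
  best <- object$trace |>
    dplyr::group_by(.data$iteration) |>
    dplyr::summarise(fitness = max(.data$fitness), .groups = "drop") |>
    dplyr::mutate(fitness = cummax(.data$fitness))
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$fitness)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::geom_line(data = best, colour = "firebrick") +
    ggplot2::labs(x = "iteration", y = "fitness (profile score)")
}

#' One step of the gradient-pair method
#'
#' From two evaluated points, proposes `candidate = hi + sign * eta *
#' (hi - lo)` (a scaled step from the better point away from the worse one).
#' If the candidate outperforms at least one of the pair, the worst of the
#' trio is dropped and the step direction/size are kept; otherwise the
#' learning rate is shrunk, the direction flipped, and the pair left
#' unchanged. Learning rates of 1 or more make the method oscillate rather
#' than converge.
#'
#' @param point_hi,point_lo Numeric vectors: the better- and worse-scoring
#'   points.
#' @param objective Function returning a scalar fitness to maximise.
#' @param state List with `eta` (current learning rate), `sign` (+1/-1) and
#'   `shrink` (rate multiplier on rejection); as returned by a previous call
#'   or [gradient_pair_state()].
#' @param f_hi,f_lo Fitness at the two points; evaluated if missing.
#' @return A list: updated `point_hi`, `point_lo`, `f_hi`, `f_lo`, the
#'   `candidate` and `f_candidate`, `accepted`, and the updated `state`.
#' @examples
#' obj <- function(x) -sum(x^2)
#' st <- gradient_pair_state(eta = 0.5)
#' gradient_pair_step(1, 2, obj, st)$point_hi # 0.5
#' @export
gradient_pair_step <- function(point_hi, point_lo, objective,
                               state = gradient_pair_state(),
                               f_hi = NULL, f_lo = NULL) {
  f_hi <- f_hi %||% objective(point_hi)
  f_lo <- f_lo %||% objective(point_lo)
  if (f_lo > f_hi) { # keep the invariant hi >= lo
    tmp <- point_hi; point_hi <- point_lo; point_lo <- tmp
    tmpf <- f_hi; f_hi <- f_lo; f_lo <- tmpf
  }
  candidate <- point_hi + state$sign * state$eta * (point_hi - point_lo)
  f_candidate <- objective(candidate)
  if (f_candidate > f_lo) {
    # drop the worst of the trio, keep the two best (ordered hi, lo)
    pts <- list(candidate, point_hi)
    fs <- c(f_candidate, f_hi)
    ord <- order(fs, decreasing = TRUE)
    out <- list(point_hi = pts[[ord[1]]], point_lo = pts[[ord[2]]],
                f_hi = fs[ord[1]], f_lo = fs[ord[2]],
                candidate = candidate, f_candidate = f_candidate,
                accepted = TRUE, state = state)
  } else {
    state$eta <- state$eta * state$shrink
    state$sign <- -state$sign
    out <- list(point_hi = point_hi, point_lo = point_lo,
                f_hi = f_hi, f_lo = f_lo,
                candidate = candidate, f_candidate = f_candidate,
                accepted = FALSE, state = state)
  }
  out
}

#' @rdname gradient_pair_step
#' @param eta Initial learning rate.
#' @param sign Initial step direction (+1 = away from the worse point).
#' @param shrink Learning-rate multiplier applied on rejection.
#' @export
gradient_pair_state <- function(eta = 0.5, sign = 1, shrink = 0.5) {
  stopifnot(eta > 0, sign %in% c(-1, 1), shrink > 0, shrink < 1)
  list(eta = eta, sign = sign, shrink = shrink)
}
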