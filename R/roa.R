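#' Define a bound-constrained search space
#'
#' A rectangular (box) search domain for the remora optimizer. Every
#' coordinate of a candidate position is kept inside `[lower[i], upper[i]]`.
#'
#' @param lower,upper Numeric vectors of equal length D giving the
#'   per-dimension bounds; `lower[i] < upper[i]` must hold for all i.
#' @return An object of class `roa_space` with fields `dimension`,
#'   `lower` and `upper`.
#' @examples
#' search_space(rep(-10, 2), rep(10, 2))
#' @export
search_space <- function(lower, upper) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper))
    stop("`lower` and `upper` must have the same length")
  if (length(lower) < 1L)
    stop("invalid configuration: the search space needs at least one dimension")
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must be finite")
  if (any(lower >= upper))
    stop("every lower bound must be strictly below its upper bound")
  structure(list(dimension = length(lower), lower = lower, upper = upper),
            class = "roa_space")
}

#' Remora optimizer settings
#'
#' Defaults follow the published swarm settings: 50 search agents and 100
#' iterations on a \eqn{[-10, 10]} box. `remora_factor` scales the host
#' attraction inside the host-feeding step and `inertia_switch` is the
#' fraction of the run during which the inertia weight stays at 0.9.
#'
#' @param population Number of remoras N (>= 1).
#' @param max_iter Iteration budget Tmax (>= 1).
#' @param remora_factor Host-attraction scalar C > 0 used in host feeding.
#' @param inertia_switch Fraction in (0, 1) of `max_iter` before the
#'   inertia weight starts its sigmoid decay.
#' @param seed Integer seed; the whole run is driven by one seeded stream.
#' @return An object of class `roa_config`.
#' @export
roa_config <- function(population = 50L, max_iter = 100L, remora_factor = 0.1,
                       inertia_switch = 0.5, seed = 1L) {
  population <- as.integer(population)
  max_iter <- as.integer(max_iter)
  if (is.na(population) || population < 1L)
    stop("invalid configuration: `population` must be a positive integer")
  if (is.na(max_iter) || max_iter < 1L)
    stop("invalid configuration: `max_iter` must be a positive integer")
  if (!is.finite(remora_factor) || remora_factor <= 0)
    stop("invalid configuration: `remora_factor` must be > 0")
  if (!is.finite(inertia_switch) || inertia_switch <= 0 || inertia_switch >= 1)
    stop("invalid configuration: `inertia_switch` must lie in (0, 1)")
  structure(list(population = population, max_iter = max_iter,
                 remora_factor = remora_factor,
                 inertia_switch = inertia_switch,
                 seed = as.integer(seed)),
            class = "roa_config")
}

#' Initialize a remora population
#'
#' Draws `config$population` candidate positions uniformly inside the box
#' (coordinates independent), sets each remora's memory (`prev_position`)
#' to its starting point and assigns a host flag H drawn uniformly from
#' \{0, 1\}. Reproducible given `config$seed`.
#'
#' @param space A [search_space()].
#' @param config A [roa_config()].
#' @param init_positions Optional list of numeric positions used verbatim
#'   (after clipping) for the first `length(init_positions)` remoras;
#'   the remainder are drawn uniformly.
#' @return A list of remora states, each a list with `position`,
#'   `prev_position`, `fitness` (NA until evaluated) and `host` (0 or 1).
#' @export
initialize_population <- function(space, config, init_positions = NULL) {
  stopifnot(inherits(space, "roa_space"), inherits(config, "roa_config"))
  n_given <- length(init_positions)
  if (n_given > config$population)
    stop("more `init_positions` than population slots")
  set.seed(config$seed)
  lapply(seq_len(config$population), function(i) {
    if (i <= n_given) {
      pos <- clip_to_bounds(as.numeric(init_positions[[i]]), space)
      if (length(pos) != space$dimension)
        stop("`init_positions` entries must have length equal to the space dimension")
    } else {
      pos <- stats::runif(space$dimension, space$lower, space$upper)
    }
    list(position = pos, prev_position = pos, fitness = NA_real_,
         host = sample(0:1, 1L))
  })
}

#' Inertia weight schedule
#'
#' Constant at 0.9 for the first `inertia_switch` fraction of the run,
#' then decays along the sigmoid \eqn{1 / (1 + e^{10 t / Tmax - 2})}.
#' The value always lies in (0, 0.9] and is non-increasing in t.
#'
#' @param t Iteration index, 0 <= t <= `config$max_iter`.
#' @param config A [roa_config()].
#' @return The inertia weight, a scalar in (0, 0.9].
#' @export
inertia_weight <- function(t, config) {
  stopifnot(inherits(config, "roa_config"))
  tmax <- config$max_iter
  if (!is.finite(t) || t < 0 || t > tmax)
    stop("`t` must lie in [0, max_iter]")
  if (t < config$inertia_switch * tmax) 0.9 else 1 / (1 + exp(10 * t / tmax - 2))
}

#' Whale-phase scale factor a(t)
#'
#' Linear decay from -1 at t = 0 to -2 at t = Tmax; the spiral exponent
#' is drawn inside `[a - 1, 1]` from this scale.
#'
#' @param t Iteration index in `[0, max_iter]`.
#' @param max_iter Iteration budget.
#' @return Scalar in `[-2, -1]`.
#' @export
woa_scale <- function(t, max_iter) {
  if (!is.finite(t) || t < 0 || t > max_iter)
    stop("`t` must lie in [0, max_iter]")
  -(1 + t / max_iter)
}

#' Host volume V(t)
#'
#' The shrinking host volume used by the host-feeding step:
#' \eqn{V = 2 (1 - t / Tmax)}, from 2 at the start of the run down to 0.
#'
#' @inheritParams woa_scale
#' @return Scalar in `[0, 2]`.
#' @export
host_volume <- function(t, max_iter) {
  if (!is.finite(t) || t < 0 || t > max_iter)
    stop("`t` must lie in [0, max_iter]")
  2 * (1 - t / max_iter)
}

#' Sailfish-style elite-following move
#'
#' Exploration step toward (and past) the elite:
#' `r_best - (u * (r_best + r_rand) / 2 - r_rand)`, elementwise, where
#' `r_rand` is a random location drawn uniformly in the search box and
#' `u` a uniform draw; the fresh random location keeps the swarm
#' exploring even after it has gathered around the elite.
#'
#' @param r_best Elite position.
#' @param r_rand A random location in the search space.
#' @param uniform_draw Scalar in `[0, 1]`.
#' @return The proposed position (not yet clipped).
#' @export
sfo_move <- function(r_best, r_rand, uniform_draw) {
  if (length(r_best) != length(r_rand))
    stop("position vectors must have the same length")
  r_best - (uniform_draw * (r_best + r_rand) / 2 - r_rand)
}

#' Experience-attack probe
#'
#' A tentative step along the remora's own recent displacement,
#' `r_I + (r_I - r_pre) * z` with `z` a standard normal draw, used to
#' decide whether the remora should change host.
#'
#' @param r_i Current position.
#' @param r_pre Previous-generation position (the remora's memory).
#' @param normal_draw Scalar standard normal draw.
#' @return The probe position (not yet clipped).
#' @export
experience_attack <- function(r_i, r_pre, normal_draw) {
  if (length(r_i) != length(r_pre))
    stop("position vectors must have the same length")
  r_i + (r_i - r_pre) * normal_draw
}

#' Whale-style spiral exploitation move
#'
#' With `a = woa_scale(t, max_iter)` and spiral exponent
#' `alpha = u * (a - 1) + 1`, moves by `d * exp(alpha) * cos(2 pi alpha)`
#' where `d = |r_best - r_i|` elementwise (distance between hunter and
#' prey).
#'
#' @param r_i Current position.
#' @param r_best Elite position.
#' @param t Iteration index.
#' @param max_iter Iteration budget.
#' @param uniform_draw Scalar in `[0, 1]`.
#' @return The proposed position (not yet clipped).
#' @export
woa_move <- function(r_i, r_best, t, max_iter, uniform_draw) {
  if (length(r_i) != length(r_best))
    stop("position vectors must have the same length")
  a <- woa_scale(t, max_iter)
  alpha <- uniform_draw * (a - 1) + 1
  d <- abs(r_best - r_i)
  d * exp(alpha) * cos(2 * pi * alpha) + r_i
}

#' Host-feeding local move
#'
#' Small-step exploitation inside the shrinking host volume:
#' `V = host_volume(t)`, `B = 2 V u - V` (so `B` lies in `[-V, V]`),
#' `A = B * (r_i - C * r_best)` and the step applied is the inertia-damped
#' `r_i + w(t) * A`.
#'
#' @param r_i Current position.
#' @param r_best Elite position.
#' @param t Iteration index.
#' @param config A [roa_config()] (supplies `max_iter` and the remora
#'   factor C).
#' @param uniform_draw Scalar in `[0, 1]`.
#' @return The proposed position (not yet clipped).
#' @export
host_feeding_move <- function(r_i, r_best, t, config, uniform_draw) {
  if (length(r_i) != length(r_best))
    stop("position vectors must have the same length")
  v <- host_volume(t, config$max_iter)
  b <- 2 * v * uniform_draw - v
  a_step <- b * (r_i - config$remora_factor * r_best)
  r_i + inertia_weight(t, config) * a_step
}

#' Clamp a position into the feasible box
#'
#' @param position Numeric vector of length `space$dimension`.
#' @param space A [search_space()].
#' @return The clipped position.
#' @export
clip_to_bounds <- function(position, space) {
  if (length(position) != space$dimension)
    stop("position length does not match the space dimension")
  pmin(pmax(position, space$lower), space$upper)
}

#' Run the remora optimization algorithm
#'
#' Minimizes `objective` over the box. Each iteration, every remora
#' (i) moves by the whale spiral if its host flag is 0, otherwise by the
#' sailfish elite-following rule (against a fresh uniform random
#' location); (ii) probes with an experience attack
#' along its recent displacement; (iii) adopts the probe and redraws its
#' host flag if the probe strictly improves its own fitness, otherwise
#' takes an inertia-damped host-feeding step. All positions are clipped
#' to the box before evaluation and the elite (best-so-far) is tracked
#' with strict improvement, so the recorded trace is non-increasing.
#'
#' The global RNG state is snapshotted around every objective call, so
#' objectives that seed their own random numbers cannot perturb the
#' swarm's stream; the whole run is reproducible from `config$seed`.
#'
#' @param objective Function mapping a feasible position to a finite
#'   scalar; the optimizer minimizes it (negate to maximize).
#' @param space A [search_space()].
#' @param config A [roa_config()].
#' @param init_positions Optional list of starting positions passed to
#'   [initialize_population()].
#' @return An object of class `roa_trace`: `best_fitness` (length
#'   `max_iter + 1`, entry 1 is the post-initialization elite),
#'   `best_position`, `best_value`, `evaluations`, plus the config echo.
#' @examples
#' sp <- search_space(rep(-10, 2), rep(10, 2))
#' tr <- roa_optimize(function(x) sum(x^2), sp,
#'                    roa_config(population = 10, max_iter = 20, seed = 7))
#' tr$best_value
#' @export
roa_optimize <- function(objective, space, config, init_positions = NULL) {
  stopifnot(is.function(objective))
  n <- config$population
  tmax <- config$max_iter
  evals <- 0L

  eval_obj <- function(x) {
    has_seed <- exists(".Random.seed", envir = globalenv())
    if (has_seed) rs <- get(".Random.seed", envir = globalenv())
    val <- objective(x)
    if (has_seed) assign(".Random.seed", rs, envir = globalenv())
    evals <<- evals + 1L
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop(sprintf("objective returned a non-finite value at position (%s)",
                   paste(signif(x, 6), collapse = ", ")))
    as.numeric(val)
  }

  pop <- initialize_population(space, config, init_positions)
  for (i in seq_len(n)) pop[[i]]$fitness <- eval_obj(pop[[i]]$position)

  fits <- vapply(pop, `[[`, numeric(1), "fitness")
  best_i <- which.min(fits)
  best_pos <- pop[[best_i]]$position
  best_fit <- fits[best_i]

  trace <- numeric(tmax + 1L)
  trace[1L] <- best_fit

  for (t in seq_len(tmax)) {
    for (i in seq_len(n)) {
      rem <- pop[[i]]
      old <- rem$position
      u_move <- stats::runif(1)
      moved <- if (rem$host == 0L) {
        woa_move(old, best_pos, t, tmax, u_move)
      } else {
        r_rand <- stats::runif(space$dimension, space$lower, space$upper)
        sfo_move(best_pos, r_rand, u_move)
      }
      moved <- clip_to_bounds(moved, space)
      probe <- clip_to_bounds(
        experience_attack(moved, rem$prev_position, stats::rnorm(1)), space)
      f_probe <- eval_obj(probe)
      if (f_probe < rem$fitness) {           # host change
        new_pos <- probe
        new_fit <- f_probe
        rem$host <- sample(0:1, 1L)
      } else {                               # stay and feed around the host
        new_pos <- clip_to_bounds(
          host_feeding_move(moved, best_pos, t, config, stats::runif(1)), space)
        new_fit <- eval_obj(new_pos)
      }
      rem$prev_position <- old
      rem$position <- new_pos
      rem$fitness <- new_fit
      pop[[i]] <- rem
      if (new_fit < best_fit) {              # strict: ties keep the incumbent
        best_fit <- new_fit
        best_pos <- new_pos
      }
    }
    trace[t + 1L] <- best_fit
  }

  structure(list(best_fitness = trace, best_position = best_pos,
                 best_value = best_fit, evaluations = evals,
                 config = config, space = space),
            class = "roa_trace")
}

#' @export
print.roa_trace <- function(x, ...) {
  cat(sprintf("remora optimization trace: %d iterations, %d evaluations\n",
              length(x$best_fitness) - 1L, x$evaluations))
  cat(sprintf("  best value: %.6g at (%s)\n", x$best_value,
              paste(signif(x$best_position, 5), collapse = ", ")))
  invisible(x)
}

#' Export an optimization trace as JSON
#'
#' @param trace An `roa_trace`.
#' @param path Optional file path; when NULL the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
roa_trace_json <- function(trace, path = NULL) {
  stopifnot(inherits(trace, "roa_trace"))
  payload <- list(
    best_fitness = trace$best_fitness,
    best_position = trace$best_position,
    best_value = trace$best_value,
    evaluations = trace$evaluations,
    seed = trace$config$seed,
    config = unclass(trace$config))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
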