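#' Bound-constrained objective specification
#'
#' @param fn function mapping a numeric vector of length `length(lower)` to a
#'   scalar fitness; lower is better. Non-finite returns are treated as `+Inf`.
#' @param lower,upper numeric bound vectors, `lower < upper` elementwise.
#' @return object of class `objective_spec` with `fn`, `lower`, `upper`,
#'   `dim`.
#' @export
objective_spec <- function(fn, lower, upper) {
  abort_if(length(lower) != length(upper), "bound length mismatch")
  abort_if(any(!(lower < upper)), "need lower < upper in every dimension")
  structure(list(fn = fn, lower = as.numeric(lower),
                 upper = as.numeric(upper), dim = length(lower)),
            class = "objective_spec")
}

safe_eval <- function(spec, x) {
  v <- spec$fn(x)
  if (!is.finite(v)) Inf else v
}

clip_bounds <- function(x, spec) pmin(pmax(x, spec$lower), spec$upper)

#' Whale optimization algorithm configuration
#'
#' Defaults follow the standard experimental settings: population `n = 25`,
#' `max_iter = 100`, spiral shape constant `b = 1`, exploration switch
#' threshold `tau_a = 1` on the magnitude of the per-whale coefficient `A`
#' (0.5 is the other convention seen in the literature; both selectable).
#'
#' @param pop population size, `>= 2`.
#' @param max_iter iteration cap, `>= 1`.
#' @param b logarithmic-spiral shape constant.
#' @param tau_a exploration threshold on `|A|`, `> 0`.
#' @param seed integer seed; fixes the whole run.
#' @param tol optional fitness stop tolerance; `NULL` disables early stopping.
#' @return a config list of class `woa_config`.
#' @export
woa_config <- function(pop = 25L, max_iter = 100L, b = 1, tau_a = 1,
                       seed = 1L, tol = NULL) {
  abort_if(pop < 2L, "population must be >= 2")
  abort_if(max_iter < 1L, "max_iter must be >= 1")
  abort_if(tau_a <= 0, "tau_a must be positive")
  structure(list(pop = as.integer(pop), max_iter = as.integer(max_iter),
                 b = b, tau_a = tau_a, seed = as.integer(seed), tol = tol),
            class = "woa_config")
}

#' Uniform random population within bounds
#' @param spec an [objective_spec()].
#' @param n population size.
#' @param seed integer seed.
#' @return numeric matrix `n x dim`, every coordinate uniform in its bounds.
#' @export
init_population <- function(spec, n, seed = 1L) {
  with_seed(seed, {
    u <- matrix(runif(n * spec$dim), n, spec$dim)
    sweep(sweep(u, 2, spec$upper - spec$lower, "*"), 2, spec$lower, "+")
  })
}

#' WOA coefficient vectors
#'
#' `A = 2 a r - a`, `C = 2 r` with `r` uniform in `[0, 1]`; `a` decreases
#' linearly from 2 to 0 over the run.
#'
#' @param a current schedule value in `[0, 2]`.
#' @param r uniform draws in `[0, 1]` (scalar or vector).
#' @return list with `A` (in `[-a, a]`) and `C` (in `[0, 2]`).
#' @export
woa_coefficients <- function(a, r) {
  list(A = 2 * a * r - a, C = 2 * r)
}

#' WOA position updates
#'
#' Encircling: `D = |C * Xbest - X|`, `Xnew = Xbest - A * D`.
#' Spiral (bubble-net): `Xnew = D' exp(b l) cos(2 pi l) + Xbest` with
#' `D' = |Xbest - X|`. Exploration replaces `Xbest` by a randomly chosen
#' population member. All products are elementwise.
#'
#' @param x current position.
#' @param x_best best (or random, for [woa_explore()]) position.
#' @param A,C coefficient values (scalars broadcast or vectors).
#' @return updated position vector.
#' @export
woa_encircle <- function(x, x_best, A, C) {
  x_best - A * abs(C * x_best - x)
}

#' @rdname woa_encircle
#' @param b spiral shape constant.
#' @param l spiral parameter in `[-1, 1]`.
#' @export
woa_spiral <- function(x, x_best, b, l) {
  abs(x_best - x) * exp(b * l) * cos(2 * pi * l) + x_best
}

#' @rdname woa_encircle
#' @param x_rand a randomly selected population member's position.
#' @export
woa_explore <- function(x, x_rand, A, C) {
  x_rand - A * abs(C * x_rand - x)
}

# One WOA iteration over the whole population. Consumes randomness from the
# current RNG stream, per whale in index order:
#   p <- runif(1)
#   if p >= 0.5:  l <- runif(1, -1, 1)                      -> spiral
#   else:         rA <- runif(1); rC <- runif(dim);
#                 if |A| <  tau_a                            -> encircle
#                 else j <- sample.int(pop, 1)               -> explore
# The per-whale A is a single scalar (2 a rA - a) broadcast across all
# dimensions so the |A| branch test is well defined; C is a fresh uniform
# vector. Positions are clipped to the bounds, then all fitnesses are
# recomputed and the elitist best is updated.
woa_step <- function(state, spec, config, a) {
  pos <- state$pos
  n <- nrow(pos)
  new_pos <- pos
  for (i in seq_len(n)) {
    p <- runif(1)
    if (p >= 0.5) {
      l <- runif(1, -1, 1)
      cand <- woa_spiral(pos[i, ], state$best_x, config$b, l)
    } else {
      rA <- runif(1)
      A <- 2 * a * rA - a
      C <- 2 * runif(spec$dim)
      if (abs(A) < config$tau_a) {
        cand <- woa_encircle(pos[i, ], state$best_x, A, C)
      } else {
        j <- sample.int(n, 1)
        cand <- woa_explore(pos[i, ], pos[j, ], A, C)
      }
    }
    new_pos[i, ] <- clip_bounds(cand, spec)
  }
  fit <- apply(new_pos, 1, function(x) safe_eval(spec, x))
  state$evals <- state$evals + n
  state$pos <- new_pos
  state$fit <- fit
  k <- which.min(fit)
  if (fit[k] < state$best_f) {
    state$best_f <- fit[k]
    state$best_x <- new_pos[k, ]
  }
  state
}

make_result <- function(state, trace) {
  structure(list(best_x = state$best_x, best_f = state$best_f,
                 trace = trace, evals = state$evals),
            class = "optimizer_result")
}

init_state <- function(spec, n) {
  u <- matrix(runif(n * spec$dim), n, spec$dim)
  pos <- sweep(sweep(u, 2, spec$upper - spec$lower, "*"), 2, spec$lower, "+")
  list(pos = pos, fit = rep(Inf, n), evals = 0L)
}

seed_member <- function(state, spec, x0) {
  if (!is.null(x0)) state$pos[1L, ] <- clip_bounds(x0, spec)
  state
}

eval_all <- function(state, spec) {
  state$fit <- apply(state$pos, 1, function(x) safe_eval(spec, x))
  state$evals <- state$evals + nrow(state$pos)
  k <- which.min(state$fit)
  state$best_f <- state$fit[k]
  state$best_x <- state$pos[k, ]
  state
}

#' Minimize an objective with the whale optimization algorithm
#'
#' Population metaheuristic alternating prey encircling, logarithmic-spiral
#' bubble-net attack, and random-whale exploration. The schedule value `a`
#' decreases linearly from 2 to 0 (`a = 2 (1 - t / max_iter)`, exactly 0 at
#' the final iteration). Fully deterministic for a fixed seed.
#'
#' @param spec an [objective_spec()].
#' @param config a [woa_config()].
#' @param x0 optional position injected as population member 1 (clipped to
#'   bounds); the remaining members are random.
#' @return object of class `optimizer_result` with `best_x`, `best_f`, a
#'   nonincreasing per-iteration `trace` of the best fitness, and `evals`.
#' @export
woa_minimize <- function(spec, config = woa_config(), x0 = NULL) {
  with_seed(config$seed, {
    state <- eval_all(seed_member(init_state(spec, config$pop), spec, x0), spec)
    trace <- numeric(0)
    for (t in seq_len(config$max_iter)) {
      a <- 2 * (1 - t / config$max_iter)
      state <- woa_step(state, spec, config, a)
      trace <- c(trace, state$best_f)
      if (!is.null(config$tol) && state$best_f <= config$tol) break
    }
    make_result(state, trace)
  })
}

#' Minimize with global-best particle swarm optimization
#'
#' Standard constricted global-best PSO (inertia 0.7298, cognitive and social
#' coefficients 1.49618) behind the same interface as [woa_minimize()];
#' provided as a comparison baseline.
#'
#' @inheritParams woa_minimize
#' @return an `optimizer_result`.
#' @export
pso_minimize <- function(spec, config = woa_config(), x0 = NULL) {
  w_in <- 0.7298; c1 <- 1.49618; c2 <- 1.49618
  with_seed(config$seed, {
    state <- eval_all(seed_member(init_state(spec, config$pop), spec, x0), spec)
    n <- config$pop
    vmax <- spec$upper - spec$lower
    vel <- matrix(runif(n * spec$dim, -1, 1), n, spec$dim) *
      matrix(vmax, n, spec$dim, byrow = TRUE) * 0.1
    pbest <- state$pos; pbest_f <- state$fit
    trace <- numeric(0)
    for (t in seq_len(config$max_iter)) {
      r1 <- matrix(runif(n * spec$dim), n, spec$dim)
      r2 <- matrix(runif(n * spec$dim), n, spec$dim)
      gb <- matrix(state$best_x, n, spec$dim, byrow = TRUE)
      vel <- w_in * vel + c1 * r1 * (pbest - state$pos) +
        c2 * r2 * (gb - state$pos)
      vel <- pmin(pmax(vel, matrix(-vmax, n, spec$dim, byrow = TRUE)),
                  matrix(vmax, n, spec$dim, byrow = TRUE))
      lo <- matrix(spec$lower, n, spec$dim, byrow = TRUE)
      hi <- matrix(spec$upper, n, spec$dim, byrow = TRUE)
      state$pos <- pmin(pmax(state$pos + vel, lo), hi)
      state$fit <- apply(state$pos, 1, function(x) safe_eval(spec, x))
      state$evals <- state$evals + n
      imp <- state$fit < pbest_f
      pbest[imp, ] <- state$pos[imp, , drop = FALSE]
      pbest_f[imp] <- state$fit[imp]
      k <- which.min(pbest_f)
      if (pbest_f[k] < state$best_f) {
        state$best_f <- pbest_f[k]; state$best_x <- pbest[k, ]
      }
      trace <- c(trace, state$best_f)
      if (!is.null(config$tol) && state$best_f <= config$tol) break
    }
    make_result(state, trace)
  })
}

#' Minimize with a real-coded genetic algorithm
#'
#' Tournament selection (size 2), blend (BLX-0.5) crossover, per-gene
#' Gaussian mutation whose sd anneals linearly from 10% to 0.1% of the bound
#' range over the run, one elite survivor. Comparison baseline behind the
#' [woa_minimize()] interface.
#'
#' @inheritParams woa_minimize
#' @return an `optimizer_result`.
#' @export
ga_minimize <- function(spec, config = woa_config(), x0 = NULL) {
  p_cx <- 0.9; alpha <- 0.5
  with_seed(config$seed, {
    state <- eval_all(seed_member(init_state(spec, config$pop), spec, x0), spec)
    n <- config$pop
    p_mut <- 1 / spec$dim
    trace <- numeric(0)
    tournament <- function() {
      a <- sample.int(n, 1); b <- sample.int(n, 1)
      if (state$fit[a] <= state$fit[b]) a else b
    }
    for (t in seq_len(config$max_iter)) {
      frac <- 1 - (t - 1) / config$max_iter
      mut_sd <- (0.001 + 0.099 * frac) * (spec$upper - spec$lower)
      children <- matrix(NA_real_, n, spec$dim)
      children[1L, ] <- state$best_x  # elitism
      for (i in 2:n) {
        pa <- state$pos[tournament(), ]
        pb <- state$pos[tournament(), ]
        if (runif(1) < p_cx) {
          lo <- pmin(pa, pb); hi <- pmax(pa, pb)
          span <- hi - lo
          child <- runif(spec$dim, lo - alpha * span, hi + alpha * span)
        } else {
          child <- pa
        }
        hit <- runif(spec$dim) < p_mut
        if (any(hit)) {
          child[hit] <- child[hit] + rnorm(sum(hit), 0, mut_sd[hit])
        }
        children[i, ] <- clip_bounds(child, spec)
      }
      state$pos <- children
      state$fit <- apply(children, 1, function(x) safe_eval(spec, x))
      state$evals <- state$evals + n
      k <- which.min(state$fit)
      if (state$fit[k] < state$best_f) {
        state$best_f <- state$fit[k]; state$best_x <- children[k, ]
      }
      trace <- c(trace, state$best_f)
      if (!is.null(config$tol) && state$best_f <= config$tol) break
    }
    make_result(state, trace)
  })
}

#' Write an optimizer convergence trace to CSV
#' @param result an `optimizer_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(result, path) {
  write.csv(data.frame(iteration = seq_along(result$trace),
                       best_fitness = result$trace),
            path, row.names = FALSE)
  invisible(path)
}
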