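# Independent, deliberately naive oracles: straight loops over the layer
# equations and the position-update rules, sharing no code with R/.

# Layer-by-layer scalar evaluation of the five-layer forward pass.
naive_anfis_forward <- function(x, model, eps_floor = 1e-12) {
  c <- model$c; d <- model$d
  w <- numeric(c)
  for (i in seq_len(c)) {
    prod_mu <- 1
    for (j in seq_len(d)) {
      mu <- exp(-((x[j] - model$rho[i, j]) / model$sigma[i, j])^2)  # layer 1
      prod_mu <- prod_mu * mu                                      # layer 2
    }
    w[i] <- prod_mu
  }
  s <- 0
  for (i in seq_len(c)) s <- s + w[i]
  wbar <- if (s < eps_floor) rep(1 / c, c) else w / s               # layer 3
  out <- 0
  for (i in seq_len(c)) {
    f <- model$bias[i]
    for (j in seq_len(d)) f <- f + model$coef[i, j] * x[j]          # layer 4
    out <- out + wbar[i] * f                                        # layer 5
  }
  out
}

random_model <- function(d, c) {
  anfis_model(rho = matrix(runif(c * d, -0.2, 1.2), c, d),
              sigma = matrix(runif(c * d, 0.05, 1.5), c, d),
              coef = matrix(runif(c * d, -3, 3), c, d),
              bias = runif(c, -3, 3))
}

# Loop-based replica of one WOA iteration, consuming randomness in the
# documented per-whale order (p; l | rA, rC[, whale index]).
naive_woa_step <- function(pos, fit, best_x, best_f, spec, config, a) {
  n <- nrow(pos)
  new_pos <- pos
  for (i in seq_len(n)) {
    p <- runif(1)
    if (p >= 0.5) {
      l <- runif(1, -1, 1)
      cand <- numeric(spec$dim)
      for (j in seq_len(spec$dim)) {
        cand[j] <- abs(best_x[j] - pos[i, j]) * exp(config$b * l) *
          cos(2 * pi * l) + best_x[j]
      }
    } else {
      rA <- runif(1)
      A <- 2 * a * rA - a
      C <- 2 * runif(spec$dim)
      cand <- numeric(spec$dim)
      if (abs(A) < config$tau_a) {
        for (j in seq_len(spec$dim)) {
          cand[j] <- best_x[j] - A * abs(C[j] * best_x[j] - pos[i, j])
        }
      } else {
        k <- sample.int(n, 1)
        for (j in seq_len(spec$dim)) {
          cand[j] <- pos[k, j] - A * abs(C[j] * pos[k, j] - pos[i, j])
        }
      }
    }
    for (j in seq_len(spec$dim)) {
      cand[j] <- min(max(cand[j], spec$lower[j]), spec$upper[j])
    }
    new_pos[i, ] <- cand
  }
  new_fit <- numeric(n)
  for (i in seq_len(n)) {
    v <- spec$fn(new_pos[i, ])
    new_fit[i] <- if (!is.finite(v)) Inf else v
  }
  k <- which.min(new_fit)
  if (new_fit[k] < best_f) {
    best_f <- new_fit[k]
    best_x <- new_pos[k, ]
  }
  list(pos = new_pos, fit = new_fit, best_x = best_x, best_f = best_f)
}

# Small seasonal table for protocol tests; cheap training settings.
tiny_table <- function(n = 40, seed = 11) {
  sim <- simulate_dataset(synthetic_spec(n = n, seed = seed))
  sim$table
}

tiny_config <- function(seed = 1, optimizer = "woa") {
  training_config(rules = 2, optimizer = optimizer, pop = 6L, max_iter = 5L,
                  seed = seed)
}
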