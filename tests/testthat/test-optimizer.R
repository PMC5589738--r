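sphere_spec <- function(dim = 5, half = 10) {
  objective_spec(function(x) sum(x^2), rep(-half, dim), rep(half, dim))
}

test_that("objective_spec validates bounds", {
  expect_error(objective_spec(sum, c(0, 0), c(1, 0)), "lower < upper")
  expect_error(objective_spec(sum, 0, c(1, 2)), "mismatch")
})

test_that("init_population is in-bounds, deterministic, uniform", {
  spec <- objective_spec(sum, c(-2, 5), c(3, 6))
  pop <- init_population(spec, 1000, seed = 3)
  expect_true(all(pop[, 1] >= -2 & pop[, 1] <= 3))
  expect_true(all(pop[, 2] >= 5 & pop[, 2] <= 6))
  expect_identical(init_population(spec, 1000, seed = 3), pop)

  # DERIVED: Monte-Carlo mean vs uniform midpoint within 3 standard errors
  big <- init_population(spec, 10000, seed = 4)
  se <- (c(3, 6) - c(-2, 5)) / sqrt(12) / sqrt(10000)
  expect_true(all(abs(colMeans(big) - c(0.5, 5.5)) < 3 * se))
})

test_that("coefficient arithmetic follows A = 2ar - a, C = 2r", {
  expect_equal(woa_coefficients(2, 0.5), list(A = 0, C = 1))
  expect_equal(woa_coefficients(0, c(0.1, 0.9))$A, c(0, 0))
  expect_equal(woa_coefficients(2, 1), list(A = 2, C = 2))
})

test_that("position updates match hand arithmetic and fixed points", {
  # encircling
  expect_equal(woa_encircle(c(5, 5), c(1, 2), 0, c(1, 1)), c(1, 2))
  expect_equal(woa_encircle(c(1, 2), c(1, 2), 0.7, c(1, 1)), c(1, 2))
  expect_equal(woa_encircle(c(0, 0), c(1, 2), 0.5, c(1, 1)), c(0.5, 1))
  # spiral
  expect_equal(woa_spiral(c(1, 2), c(1, 2), 1, 0.37), c(1, 2))
  expect_equal(woa_spiral(c(0, 0), c(1, 2), 1, 0.25), c(1, 2))
  expect_equal(woa_spiral(0, 1, 1, 0), 2)
  # exploration
  expect_equal(woa_explore(c(5, 5), c(1, 2), 0, c(1, 1)), c(1, 2))
  expect_equal(woa_explore(c(0, 0), c(0, 0), 0.9, c(2, 2)), c(0, 0))
  expect_equal(woa_explore(2, 0, 1, 2), -2)
})

test_that("woa_minimize solves simple problems and honors contracts", {
  r <- woa_minimize(objective_spec(function(x) abs(x - 3), 0, 10),
                    woa_config(pop = 25, max_iter = 100, seed = 2))
  expect_lt(abs(r$best_x - 3), 0.05)

  r5 <- woa_minimize(sphere_spec(), woa_config(seed = 1))
  expect_lt(r5$best_f, 1e-2)
  expect_lte(length(r5$trace), 100)
  expect_true(all(diff(r5$trace) <= 0))
  expect_equal(r5$best_f, sum(r5$best_x^2))
  expect_true(all(r5$best_x >= -10 & r5$best_x <= 10))

  expect_identical(woa_minimize(sphere_spec(), woa_config(seed = 1)), r5)

  # early stop on tolerance
  rt <- woa_minimize(sphere_spec(), woa_config(seed = 1, tol = 1))
  expect_lt(length(rt$trace), 100)

  # non-finite objective treated as +Inf, never selected
  spec_bad <- objective_spec(function(x) if (x[1] > 0) NaN else sum(x^2),
                             rep(-10, 2), rep(10, 2))
  rb <- woa_minimize(spec_bad, woa_config(pop = 10, max_iter = 20, seed = 3))
  expect_true(is.finite(rb$best_f))
  expect_lte(rb$best_x[1], 0)
})

test_that("one woa_step matches the naive loop reimplementation exactly", {
  spec <- sphere_spec(dim = 2, half = 5)
  config <- woa_config(pop = 3, max_iter = 10, seed = 1)
  pos <- init_population(spec, 3, seed = 8)
  fit <- apply(pos, 1, spec$fn)
  k <- which.min(fit)
  for (a in c(1.7, 0.9, 0.2)) {
    state <- list(pos = pos, fit = fit, best_x = pos[k, ], best_f = fit[k],
                  evals = 0L)
    got <- withr::with_seed(33, anfiswoa:::woa_step(state, spec, config, a))
    want <- withr::with_seed(33, naive_woa_step(pos, fit, pos[k, ], fit[k],
                                                spec, config, a))
    expect_identical(got$pos, want$pos)
    expect_identical(got$fit, want$fit)
    expect_identical(got$best_x, want$best_x)
    expect_identical(got$best_f, want$best_f)
  }
})

test_that("pso and ga solve the sphere deterministically with elitist traces", {
  for (minimize in list(pso_minimize, ga_minimize)) {
    r <- minimize(sphere_spec(), woa_config(seed = 4))
    expect_lt(r$best_f, 1e-2)
    expect_true(all(diff(r$trace) <= 0))
    expect_equal(r$best_f, sum(r$best_x^2))
    expect_identical(minimize(sphere_spec(), woa_config(seed = 4)), r)
  }
})

test_that("convergence trace CSV export", {
  r <- woa_minimize(sphere_spec(2), woa_config(pop = 5, max_iter = 10, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(r, path)
  df <- read.csv(path)
  expect_identical(names(df), c("iteration", "best_fitness"))
  expect_equal(df$best_fitness, r$trace)
})
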