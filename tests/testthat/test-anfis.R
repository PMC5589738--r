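test_that("membership_degree matches the Gaussian definition", {
  expect_equal(membership_degree(0.4, 0.4, 0.2), 1)
  expect_equal(membership_degree(0.6, 0.4, 0.2), exp(-1))
  set.seed(1)
  for (k in 1:20) {
    rho <- runif(1); sigma <- runif(1, 0.05, 1); delta <- runif(1, -2, 2)
    expect_equal(membership_degree(rho + delta, rho, sigma),
                 membership_degree(rho - delta, rho, sigma))
  }
})

test_that("rule_firing is the product of per-input memberships", {
  set.seed(2)
  mod <- random_model(d = 3, c = 4)
  x <- runif(3)
  w <- rule_firing(x, mod)
  expect_true(all(w > 0 & w <= 1))
  for (i in 1:4) {
    manual <- prod(vapply(1:3, function(j)
      membership_degree(x[j], mod$rho[i, j], mod$sigma[i, j]), numeric(1)))
    expect_equal(w[i], manual, tolerance = 1e-14)
  }
  mod1 <- random_model(d = 1, c = 2)
  expect_equal(rule_firing(0.3, mod1),
               membership_degree(0.3, mod1$rho[, 1], mod1$sigma[, 1]))
  # firing 1 when the input sits on every center
  modc <- anfis_model(rho = matrix(0.5, 1, 2), sigma = matrix(0.3, 1, 2),
                      coef = matrix(0, 1, 2), bias = 0)
  expect_equal(rule_firing(c(0.5, 0.5), modc), 1)
})

test_that("normalize_firing sums to one with uniform underflow fallback", {
  expect_equal(normalize_firing(c(0.2, 0.2)), c(0.5, 0.5))
  set.seed(3)
  for (k in 1:50) {
    w <- runif(sample(2:6, 1))
    expect_equal(sum(normalize_firing(w)), 1, tolerance = 1e-12)
  }
  expect_equal(normalize_firing(c(1e-300, 1e-300) * 1e-20), c(0.5, 0.5))
  expect_error(normalize_firing(c(-0.1, 1)), "negative")
})

test_that("rule_output is the linear consequent", {
  expect_equal(rule_output(c(9, 9), c(0, 0), 2.5), 2.5)
  expect_equal(rule_output(c(0.25, 0.5), c(1, 1), 0), 0.75)
  set.seed(4)
  x1 <- runif(3); x2 <- runif(3); cf <- runif(3); b <- runif(1); al <- runif(1)
  expect_equal(rule_output(al * x1 + (1 - al) * x2, cf, b),
               al * rule_output(x1, cf, b) + (1 - al) * rule_output(x2, cf, b))
})

test_that("forward pass: single-rule identity, shared consequents, oracle", {
  set.seed(5)
  mod1 <- random_model(d = 3, c = 1)
  x <- runif(3)
  expect_equal(anfis_forward(x, mod1),
               rule_output(x, mod1$coef[1, ], mod1$bias[1]))

  # identical consequents -> premises become irrelevant
  mod <- random_model(d = 2, c = 3)
  mod$coef <- matrix(rep(c(1.5, -0.5), each = 3), 3, 2)
  mod$bias <- rep(0.25, 3)
  x2 <- runif(2)
  expect_equal(anfis_forward(x2, mod), rule_output(x2, c(1.5, -0.5), 0.25))

  # DERIVED: fixed 2-input, 2-rule model vs independent layer-by-layer oracle
  fixed <- anfis_model(rho = rbind(c(0.2, 0.8), c(0.7, 0.3)),
                       sigma = rbind(c(0.25, 0.4), c(0.3, 0.2)),
                       coef = rbind(c(1.0, -2.0), c(0.5, 0.75)),
                       bias = c(0.1, -0.3))
  for (x in list(c(0.2, 0.8), c(0.5, 0.5), c(0.95, 0.05))) {
    expect_equal(anfis_forward(x, fixed), naive_anfis_forward(x, fixed),
                 tolerance = 1e-12)
  }
})

test_that("forward output is a convex combination of rule outputs", {
  set.seed(6)
  for (k in 1:100) {
    mod <- random_model(d = sample(1:4, 1), c = sample(1:5, 1))
    x <- runif(mod$d, -0.5, 1.5)
    f <- as.numeric(mod$coef %*% x) + mod$bias
    out <- anfis_forward(x, mod)
    expect_gte(out, min(f) - 1e-12)
    expect_lte(out, max(f) + 1e-12)
  }
})

test_that("encode/decode round trip, length checks, sigma clamp", {
  expect_identical(anfis_n_par(2, 3), 21L)
  set.seed(7)
  for (k in 1:100) {
    mod <- random_model(d = sample(1:4, 1), c = sample(1:4, 1))
    back <- decode_anfis(encode_anfis(mod), mod$d, mod$c)
    expect_equal(back[c("rho", "sigma", "coef", "bias")],
                 mod[c("rho", "sigma", "coef", "bias")])
  }
  expect_error(decode_anfis(rep(0.1, 20), 2, 3), "expected 21")
  v <- encode_anfis(random_model(2, 1))
  v[3] <- -0.5  # sigma slot of rule 1, input 1
  expect_warning(mod <- decode_anfis(v, 2, 1, sigma_min = 1e-3), "clamped")
  expect_equal(mod$sigma[1, 1], 1e-3)
})

test_that("batch prediction equals looped scalar forward", {
  set.seed(8)
  mod <- random_model(d = 3, c = 4)
  X <- matrix(runif(150, -0.2, 1.2), 50, 3)
  batch <- anfis_predict(X, mod)
  loop <- apply(X, 1, anfis_forward, model = mod)
  expect_equal(batch, loop, tolerance = 1e-12)

  perm <- sample(50)
  expect_equal(anfis_predict(X[perm, ], mod), batch[perm])
  expect_equal(anfis_predict(X[1, , drop = FALSE], mod),
               anfis_forward(X[1, ], mod))
  expect_error(anfis_predict(X[, 1:2], mod), "feature count")
})

test_that("model serialization round trip is bit-exact", {
  set.seed(9)
  mod <- random_model(d = 5, c = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_anfis(mod, path)
  back <- read_anfis(path)
  expect_identical(encode_anfis(back), encode_anfis(mod))
})

test_that("anfis_model rejects invalid parameters", {
  expect_error(anfis_model(matrix(0, 2, 2), matrix(c(0.1, -1, 0.1, 0.1), 2, 2),
                           matrix(0, 2, 2), c(0, 0)), "positive")
  expect_error(anfis_model(matrix(0, 2, 2), matrix(0.1, 2, 2),
                           matrix(0, 2, 2), 0), "shapes")
})
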