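#' Construct a Sugeno ANFIS model
#'
#' A first-order Takagi–Sugeno fuzzy system with `c` rules over `d` inputs.
#' Each rule `i` carries one Gaussian membership function per input
#' (center `rho[i, j]`, width `sigma[i, j] > 0`) and a linear consequent
#' `f_i(x) = coef[i, ] . x + bias[i]`. The five-layer forward pass is:
#' layer 1 membership degrees, layer 2 firing strengths (product T-norm),
#' layer 3 normalized firing strengths, layer 4 weighted consequents,
#' layer 5 their sum.
#'
#' @param rho numeric `c x d` matrix of membership centers (normalized input
#'   units).
#' @param sigma numeric `c x d` matrix of membership widths, all `> 0`.
#' @param coef numeric `c x d` matrix of consequent coefficients.
#' @param bias numeric length-`c` vector of consequent biases.
#' @return object of class `anfis_model` with fields `rho`, `sigma`, `coef`,
#'   `bias`, `c`, `d`.
#' @export
anfis_model <- function(rho, sigma, coef, bias) {
  rho <- as.matrix(rho); sigma <- as.matrix(sigma); coef <- as.matrix(coef)
  c <- nrow(rho); d <- ncol(rho)
  abort_if(!all(dim(sigma) == c(c, d)) || !all(dim(coef) == c(c, d)) ||
             length(bias) != c,
           "inconsistent parameter shapes for c=%d rules, d=%d inputs", c, d)
  abort_if(any(!is.finite(rho)) || any(!is.finite(sigma)) ||
             any(!is.finite(coef)) || any(!is.finite(bias)),
           "non-finite model parameter")
  abort_if(any(sigma <= 0), "all premise sigma values must be positive")
  structure(list(rho = rho, sigma = sigma, coef = coef,
                 bias = as.numeric(bias),
                 c = as.integer(c), d = as.integer(d)),
            class = "anfis_model")
}

#' @export
print.anfis_model <- function(x, ...) {
  cat(sprintf("anfis_model: %d rules over %d inputs (%d free parameters)\n",
              x$c, x$d, anfis_n_par(x$d, x$c)))
  invisible(x)
}

#' Free parameter count of an ANFIS model
#' @param d input count.
#' @param c rule count.
#' @return `c * (3 d + 1)`.
#' @export
anfis_n_par <- function(d, c) as.integer(c * (3L * d + 1L))

#' Gaussian membership degree
#'
#' \eqn{\mu(x) = \exp(-((x - \rho)/\sigma)^2)}. Note there is deliberately no
#' factor 2 in the denominator; the conventional `2 sigma^2` parameterization
#' differs only by a rescaling of `sigma`.
#'
#' @param x input value(s).
#' @param rho membership center.
#' @param sigma membership width, `> 0`.
#' @return membership degree(s) in `(0, 1]`; exactly 1 at `x = rho`.
#' @export
membership_degree <- function(x, rho, sigma) {
  exp(-((x - rho) / sigma)^2)
}

#' Rule firing strengths (layer 2)
#'
#' The firing strength of rule `i` is the product of its `d` per-input
#' membership degrees (product T-norm).
#'
#' @param x numeric input vector of length `d`.
#' @param model an [anfis_model()].
#' @return numeric vector of `c` firing strengths, each in `(0, 1]`.
#' @export
rule_firing <- function(x, model) {
  abort_if(length(x) != model$d, "input length %d != model d=%d",
           length(x), model$d)
  xm <- matrix(x, model$c, model$d, byrow = TRUE)
  exp(-rowSums(((xm - model$rho) / model$sigma)^2))
}

#' Normalized firing strengths (layer 3)
#'
#' Rescales rule weights to sum to 1. If the total firing underflows below
#' `eps_floor` the division is undefined, so the uniform vector `1/c` is
#' returned instead (distant test points can drive every Gaussian to 0).
#'
#' @param w nonnegative firing strengths.
#' @param eps_floor total-firing floor below which the uniform fallback kicks
#'   in.
#' @return weights summing to 1.
#' @export
normalize_firing <- function(w, eps_floor = 1e-12) {
  abort_if(any(w < 0), "negative firing strength")
  s <- sum(w)
  if (s < eps_floor) return(rep(1 / length(w), length(w)))
  w / s
}

#' Rule consequent output (layer 4 input)
#'
#' First-order Sugeno consequent: `f(x) = coef . x + bias`, linear in `x`.
#'
#' @param x numeric input vector of length `d`.
#' @param coef numeric coefficient vector of length `d`.
#' @param bias scalar bias.
#' @return scalar consequent value.
#' @export
rule_output <- function(x, coef, bias) {
  abort_if(length(x) != length(coef), "input length %d != coefficient length %d",
           length(x), length(coef))
  sum(coef * x) + bias
}

#' ANFIS forward pass (layers 1-5) for one input vector
#'
#' The output is the normalized-firing-weighted sum of the rule consequents,
#' hence a convex combination: it always lies within
#' `[min_i f_i(x), max_i f_i(x)]`.
#'
#' @param x numeric input vector of length `d` (normalized scale).
#' @param model an [anfis_model()].
#' @param eps_floor see [normalize_firing()].
#' @return scalar model output (normalized scale).
#' @export
anfis_forward <- function(x, model, eps_floor = 1e-12) {
  wn <- normalize_firing(rule_firing(x, model), eps_floor)
  f <- as.numeric(model$coef %*% x) + model$bias
  sum(wn * f)
}

#' Batch ANFIS evaluation
#'
#' Vectorized forward pass over the rows of `X`; row `k` of the result equals
#' `anfis_forward(X[k, ], model)`.
#'
#' @param X numeric matrix `N x d` (normalized scale).
#' @param model an [anfis_model()].
#' @param eps_floor see [normalize_firing()].
#' @return numeric vector of `N` outputs.
#' @export
anfis_predict <- function(X, model, eps_floor = 1e-12) {
  X <- as.matrix(X)
  abort_if(ncol(X) != model$d, "feature count %d != model d=%d",
           ncol(X), model$d)
  N <- nrow(X)
  W <- matrix(0, N, model$c)
  for (i in seq_len(model$c)) {
    W[, i] <- exp(-rowSums(
      (sweep(sweep(X, 2, model$rho[i, ], "-"), 2, model$sigma[i, ], "/"))^2))
  }
  s <- rowSums(W)
  low <- s < eps_floor
  Wn <- W / ifelse(low, 1, s)
  if (any(low)) Wn[low, ] <- 1 / model$c
  F <- X %*% t(model$coef) + matrix(model$bias, N, model$c, byrow = TRUE)
  rowSums(Wn * F)
}

#' Flat parameter encoding for the optimizer
#'
#' Layout, per rule in order: the `d` centers, the `d` widths, the `d`
#' consequent coefficients, then the bias — `c * (3 d + 1)` numbers in total.
#' `decode_anfis()` is the exact inverse; widths at or below zero in an
#' arbitrary optimizer position are clamped up to `sigma_min` with a warning.
#'
#' @param model an [anfis_model()].
#' @return numeric vector of length `c * (3 d + 1)`.
#' @export
encode_anfis <- function(model) {
  as.numeric(t(cbind(model$rho, model$sigma, model$coef, model$bias)))
}

#' @rdname encode_anfis
#' @param vec flat parameter vector.
#' @param d input count.
#' @param c rule count.
#' @param sigma_min clamp floor for non-positive widths.
#' @param warn warn when clamping is needed.
#' @return an [anfis_model()].
#' @export
decode_anfis <- function(vec, d, c, sigma_min = 1e-3, warn = TRUE) {
  expected <- anfis_n_par(d, c)
  abort_if(length(vec) != expected,
           "parameter vector length %d, expected %d = c(3d+1) with c=%d, d=%d",
           length(vec), expected, c, d)
  block <- matrix(vec, nrow = c, byrow = TRUE)
  sigma <- block[, (d + 1):(2 * d), drop = FALSE]
  if (any(sigma <= 0)) {
    if (warn) warning(sprintf("clamped %d non-positive sigma entries to %g",
                              sum(sigma <= 0), sigma_min))
    sigma[sigma <= 0] <- sigma_min
  }
  anfis_model(rho = block[, 1:d, drop = FALSE],
              sigma = sigma,
              coef = block[, (2 * d + 1):(3 * d), drop = FALSE],
              bias = block[, 3 * d + 1])
}

#' Serialize / load an ANFIS model as versioned JSON text
#'
#' Stores `d`, `c`, the layout string and the full-precision parameter
#' vector; the round trip is bit-exact.
#'
#' @param model an [anfis_model()].
#' @param path output file path.
#' @return `path` invisibly (`write_anfis`); the model (`read_anfis`).
#' @export
write_anfis <- function(model, path) {
  obj <- list(format = "anfiswoa-model", version = 1L,
              d = model$d, c = model$c,
              layout = "per-rule: rho[1..d], sigma[1..d], coef[1..d], bias",
              parameters = num_to_chr(encode_anfis(model)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_anfis
#' @export
read_anfis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  abort_if(!identical(obj$format, "anfiswoa-model"),
           "not a model file: %s", path)
  decode_anfis(chr_to_num(obj$parameters), obj$d, obj$c, warn = FALSE)
}
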