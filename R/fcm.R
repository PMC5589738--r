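#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means: minimize \eqn{\sum_{i,k} u_{ik}^m \|x_k - c_i\|^2}
#' by alternating center and membership updates, starting from a seeded random
#' membership matrix. Used here to choose the number of fuzzy rules and to
#' seed the premise (membership-function) parameters of the rule base.
#'
#' Points that coincide exactly with one or more centers get their membership
#' split uniformly over those centers (tie-breaking, not failure).
#'
#' @param X numeric matrix `N x d`, normally normalized features.
#' @param c number of clusters, `1 <= c <= N`.
#' @param m fuzzifier, `> 1`.
#' @param tol convergence tolerance on the max absolute membership change.
#' @param max_iter iteration cap.
#' @param seed integer seed for the random initial memberships.
#' @return object of class `fcm_result` with `centers` (`c x d`),
#'   `membership` (`N x c`, rows sum to 1), `objective` (nonincreasing trace),
#'   `c`, `m`, and `iterations`.
#' @export
fcm_cluster <- function(X, c, m = 2, tol = 1e-5, max_iter = 200, seed = 1L) {
  X <- as.matrix(X)
  N <- nrow(X)
  abort_if(c < 1L || c > N, "need 1 <= c <= N, got c=%d, N=%d", c, N)
  abort_if(m <= 1, "fuzzifier m must exceed 1, got %g", m)

  if (c == 1L) {
    centers <- matrix(colMeans(X), 1L, ncol(X))
    u <- matrix(1, N, 1L)
    obj <- sum(rowSums(sweep(X, 2, centers[1L, ], "-")^2))
    return(structure(list(centers = centers, membership = u,
                          objective = obj, c = 1L, m = m, iterations = 1L),
                     class = "fcm_result"))
  }

  u <- with_seed(seed, {
    raw <- matrix(runif(N * c), N, c)
    raw / rowSums(raw)
  })
  obj <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    um <- u^m
    centers <- (t(um) %*% X) / colSums(um)
    # squared Euclidean distances, N x c
    d2 <- outer(rowSums(X^2), rep(1, c)) +
      outer(rep(1, N), rowSums(centers^2)) - 2 * X %*% t(centers)
    d2 <- pmax(d2, 0)
    obj <- c(obj, sum(um * d2))
    zero <- d2 < .Machine$double.eps
    inv <- d2^(-1 / (m - 1))
    u_new <- inv / rowSums(inv)
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      u_new[hit, ] <- zero[hit, , drop = FALSE] /
        rowSums(zero[hit, , drop = FALSE])
    }
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol || iter >= max_iter) break
  }
  structure(list(centers = centers, membership = u, objective = obj,
                 c = as.integer(c), m = m, iterations = iter),
            class = "fcm_result")
}

#' Fuzzy partition coefficient
#'
#' Mean of squared memberships, \eqn{\frac{1}{N}\sum_{k,i} u_{ik}^2}; 1 for a
#' crisp partition, `1/c` for a maximally fuzzy one.
#'
#' @param result an [fcm_cluster()] result.
#' @return scalar in `[1/c, 1]`.
#' @export
partition_coefficient <- function(result) {
  mean(rowSums(result$membership^2))
}

#' Select the rule count by fuzzy partition coefficient
#'
#' Runs fuzzy c-means for each candidate cluster count and returns the
#' candidate with the highest partition coefficient; ties break toward the
#' smaller count.
#'
#' @param X numeric matrix `N x d`.
#' @param c_candidates integer vector of candidate counts, each `>= 2`.
#' @inheritParams fcm_cluster
#' @return the selected integer rule count.
#' @export
select_rule_count <- function(X, c_candidates = 2:10, m = 2, tol = 1e-5,
                              max_iter = 200, seed = 1L) {
  abort_if(length(c_candidates) == 0L, "empty candidate list")
  c_candidates <- as.integer(c_candidates)
  abort_if(any(c_candidates < 2L), "rule-count candidates must be >= 2")
  c_candidates <- sort(unique(c_candidates))
  pc <- vapply(seq_along(c_candidates), function(i) {
    partition_coefficient(
      fcm_cluster(X, c_candidates[i], m = m, tol = tol, max_iter = max_iter,
                  seed = derive_seed(seed, i)))
  }, numeric(1))
  # which.max returns the first maximum; candidates are sorted ascending,
  # so ties already resolve toward smaller c
  c_candidates[which.max(pc)]
}

#' Initialize an ANFIS model from fuzzy c-means clusters
#'
#' One rule per cluster: premise centers are the cluster centers; premise
#' widths are membership-weighted standard deviations of each input column
#' about the center, floored at `sigma_min`. Consequent coefficients and
#' biases start at zero and are left to the optimizer.
#'
#' @param result an [fcm_cluster()] result computed on `X`.
#' @param X the same matrix the clustering was run on.
#' @param sigma_min positive floor for premise widths.
#' @return an [anfis_model()] with `c` rules over `d = ncol(X)` inputs.
#' @export
init_anfis_from_fcm <- function(result, X, sigma_min = 1e-3) {
  X <- as.matrix(X)
  abort_if(nrow(X) != nrow(result$membership),
           "X has %d rows but the clustering saw %d",
           nrow(X), nrow(result$membership))
  c <- result$c
  d <- ncol(X)
  sigma <- matrix(sigma_min, c, d)
  for (i in seq_len(c)) {
    w <- result$membership[, i]
    tw <- sum(w)
    if (tw <= .Machine$double.eps * nrow(X)) {
      warning(sprintf("degenerate cluster %d: sigma floored at %g", i, sigma_min))
      next
    }
    dev2 <- sweep(X, 2, result$centers[i, ], "-")^2
    sigma[i, ] <- pmax(sqrt(colSums(w * dev2) / tw), sigma_min)
  }
  anfis_model(rho = result$centers, sigma = sigma,
              coef = matrix(0, c, d), bias = rep(0, c))
}
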