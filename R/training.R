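#' Training configuration for the ANFIS pipeline
#'
#' @param rules `"auto"` (fuzzy-c-means partition-coefficient selection over
#'   `c_candidates`) or a fixed integer rule count.
#' @param optimizer one of `"woa"`, `"pso"`, `"ga"`.
#' @param pop,max_iter,b,tau_a,tol optimizer settings, see [woa_config()].
#' @param rho_margin premise centers are searched in
#'   `[-rho_margin, 1 + rho_margin]` (normalized input units).
#' @param sigma_min,sigma_max premise width search range, `sigma_min > 0`.
#' @param coef_cap consequent coefficients and biases searched in
#'   `[-coef_cap, coef_cap]` (normalized units).
#' @param fcm_m,fcm_tol,fcm_max_iter fuzzy c-means settings.
#' @param c_candidates candidate rule counts for `rules = "auto"`.
#' @param inject_fcm seed the optimizer population with the FCM-initialized
#'   parameter vector as member 1 (set `FALSE` for purely random
#'   initialization).
#' @param seed top-level integer seed; all stage sub-seeds derive from it.
#' @return a config list of class `training_config`.
#' @export
training_config <- function(rules = "auto", optimizer = c("woa", "pso", "ga"),
                            pop = 25L, max_iter = 100L, b = 1, tau_a = 1,
                            tol = NULL, rho_margin = 0.1, sigma_min = 1e-3,
                            sigma_max = 2, coef_cap = 10, fcm_m = 2,
                            fcm_tol = 1e-5, fcm_max_iter = 200,
                            c_candidates = 2:10, inject_fcm = TRUE,
                            seed = 1L) {
  optimizer <- match.arg(optimizer)
  abort_if(sigma_min <= 0, "sigma_min must be positive")
  abort_if(coef_cap <= 0, "coef_cap must be positive")
  structure(list(rules = rules, optimizer = optimizer, pop = as.integer(pop),
                 max_iter = as.integer(max_iter), b = b, tau_a = tau_a,
                 tol = tol, rho_margin = rho_margin, sigma_min = sigma_min,
                 sigma_max = sigma_max, coef_cap = coef_cap, fcm_m = fcm_m,
                 fcm_tol = fcm_tol, fcm_max_iter = fcm_max_iter,
                 c_candidates = c_candidates, inject_fcm = inject_fcm,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Sum-of-squared-errors fitness of a flat parameter vector
#'
#' The optimizer's objective: decode the vector into an ANFIS model and
#' return the squared Euclidean distance between the model outputs and the
#' target column over all training samples, on the normalized scale.
#' Non-finite predictions yield `+Inf`.
#'
#' @param vec flat parameter vector, length `c (3 d + 1)`.
#' @param Xn normalized feature matrix `N x d`.
#' @param yn normalized target vector, length `N`.
#' @param c rule count.
#' @param sigma_min decode clamp floor.
#' @return nonnegative scalar (or `+Inf`).
#' @export
fitness_sse <- function(vec, Xn, yn, c, sigma_min = 1e-3) {
  model <- decode_anfis(vec, ncol(Xn), c, sigma_min, warn = FALSE)
  pred <- anfis_predict(Xn, model)
  if (any(!is.finite(pred))) return(Inf)
  sum((yn - pred)^2)
}

#' Search-space box for the flat ANFIS parameter vector
#'
#' Centers in `[-rho_margin, 1 + rho_margin]`; widths in
#' `[sigma_min, sigma_max]`; consequent coefficients and biases in
#' `[-coef_cap, coef_cap]`. Order matches the [encode_anfis()] layout, so any
#' in-bounds vector decodes to a valid model.
#'
#' @param d input count.
#' @param c rule count.
#' @param config a [training_config()] (bounds policy fields are read).
#' @return list with numeric `lower` and `upper` of length `c (3 d + 1)`.
#' @export
make_bounds <- function(d, c, config = training_config()) {
  per_rule_lo <- c(rep(-config$rho_margin, d), rep(config$sigma_min, d),
                   rep(-config$coef_cap, d), -config$coef_cap)
  per_rule_hi <- c(rep(1 + config$rho_margin, d), rep(config$sigma_max, d),
                   rep(config$coef_cap, d), config$coef_cap)
  list(lower = rep(per_rule_lo, c), upper = rep(per_rule_hi, c))
}

opt_fn <- function(name) {
  switch(name, woa = woa_minimize, pso = pso_minimize, ga = ga_minimize,
         stop(sprintf("unknown optimizer '%s'", name), call. = FALSE))
}

#' Train per-target ANFIS models with a population optimizer
#'
#' End-to-end pipeline: fit a min-max normalizer on the table; cluster the
#' normalized features with fuzzy c-means to pick the rule count (if
#' `rules = "auto"`) and seed the premise parameters; build the search box;
#' then, independently for each target column, run the configured optimizer
#' minimizing [fitness_sse()] and decode the best vector. One single-output
#' model is fitted per target; all targets share the clustering (the inputs
#' are common). Deterministic for a fixed seed.
#'
#' @param table a [sample_table()] (training data, original scale).
#' @param config a [training_config()].
#' @return object of class `trained_anfis` with `models` (one
#'   [anfis_model()] per target), `normalizer`, `traces`, `fitness`
#'   (final per-target training fitness), `c`, `config`.
#' @export
train_anfis_wo <- function(table, config = training_config()) {
  n <- n_samples(table)
  normalizer <- fit_normalizer(table)
  Xn <- normalize_features(normalizer, table$features)
  Yn <- normalize_targets(normalizer, table$targets)
  d <- ncol(Xn)

  if (identical(config$rules, "auto")) {
    cand <- config$c_candidates[config$c_candidates <= n]
    abort_if(length(cand) == 0L, "no feasible rule-count candidate for N=%d", n)
    c <- select_rule_count(Xn, cand, m = config$fcm_m, tol = config$fcm_tol,
                           max_iter = config$fcm_max_iter,
                           seed = derive_seed(config$seed, 1L))
  } else {
    c <- as.integer(config$rules)
    abort_if(c > n, "rule count %d exceeds sample count %d", c, n)
  }

  fcm <- fcm_cluster(Xn, c, m = config$fcm_m, tol = config$fcm_tol,
                     max_iter = config$fcm_max_iter,
                     seed = derive_seed(config$seed, 2L))
  init_model <- init_anfis_from_fcm(fcm, Xn, sigma_min = config$sigma_min)
  x0 <- if (config$inject_fcm) encode_anfis(init_model) else NULL
  bounds <- make_bounds(d, c, config)
  minimize <- opt_fn(config$optimizer)

  models <- vector("list", ncol(Yn))
  traces <- vector("list", ncol(Yn))
  fitness <- numeric(ncol(Yn))
  for (j in seq_len(ncol(Yn))) {
    yn <- Yn[, j]
    spec <- objective_spec(function(v) fitness_sse(v, Xn, yn, c,
                                                   config$sigma_min),
                           bounds$lower, bounds$upper)
    ocfg <- woa_config(pop = config$pop, max_iter = config$max_iter,
                       b = config$b, tau_a = config$tau_a,
                       seed = derive_seed(config$seed, 100L + j),
                       tol = config$tol)
    res <- minimize(spec, ocfg, x0 = x0)
    abort_if(!is.finite(res$best_f),
             "optimizer diverged on target '%s': all fitness values non-finite",
             table$target_names[j])
    models[[j]] <- decode_anfis(res$best_x, d, c, config$sigma_min,
                                warn = FALSE)
    traces[[j]] <- res$trace
    fitness[j] <- res$best_f
  }
  names(models) <- names(traces) <- table$target_names
  structure(list(models = models, normalizer = normalizer, traces = traces,
                 fitness = stats::setNames(fitness, table$target_names),
                 c = c, d = d, feature_names = table$feature_names,
                 target_names = table$target_names, config = config),
            class = "trained_anfis")
}

#' @export
print.trained_anfis <- function(x, ...) {
  cat(sprintf("trained_anfis: %d rules, %d inputs, %d target model(s) [%s]\n",
              x$c, x$d, length(x$models), x$config$optimizer))
  invisible(x)
}

#' Predict amino-acid (target) concentrations on the original scale
#'
#' Normalizes the features with the stored transform, runs each per-target
#' model, and maps the outputs back to the original measurement scale.
#'
#' @param object a [train_anfis_wo()] result.
#' @param newdata a [sample_table()] or bare feature matrix with `d` columns.
#' @param ... unused.
#' @return numeric matrix `N x m` of predictions, columns named by target.
#' @export
predict.trained_anfis <- function(object, newdata, ...) {
  features <- if (inherits(newdata, "sample_table")) newdata$features
              else as.matrix(newdata)
  abort_if(ncol(features) != object$d,
           "feature count %d != model d=%d", ncol(features), object$d)
  Xn <- normalize_features(object$normalizer, features)
  out <- vapply(object$models, function(mod) anfis_predict(Xn, mod),
                numeric(nrow(Xn)))
  out <- matrix(out, nrow = nrow(Xn),
                dimnames = list(NULL, object$target_names))
  denormalize_targets(object$normalizer, out)
}

#' Serialize / load a trained model set as versioned JSON text
#'
#' Stores the layout, per-target parameter vectors, the normalization
#' transform and the rule count at full precision; the round trip is
#' bit-exact.
#'
#' @param trained a [train_anfis_wo()] result.
#' @param path output file path.
#' @return `path` invisibly (`write_trained_model`); a `trained_anfis`
#'   (`read_trained_model`).
#' @export
write_trained_model <- function(trained, path) {
  obj <- list(
    format = "anfiswoa-trained", version = 1L,
    d = trained$d, c = trained$c,
    layout = "per-rule: rho[1..d], sigma[1..d], coef[1..d], bias",
    feature_names = trained$feature_names,
    target_names = trained$target_names,
    parameters = lapply(trained$models, function(m) num_to_chr(encode_anfis(m))),
    normalizer = lapply(unclass(trained$normalizer), num_to_chr),
    fitness = num_to_chr(as.numeric(trained$fitness)),
    optimizer = trained$config$optimizer)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trained_model
#' @export
read_trained_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  abort_if(!identical(obj$format, "anfiswoa-trained"),
           "not a trained-model file: %s", path)
  models <- lapply(obj$parameters, function(p)
    decode_anfis(chr_to_num(p), d = obj$d, c = obj$c, warn = FALSE))
  names(models) <- obj$target_names
  nz <- obj$normalizer
  nz$feature_min <- stats::setNames(chr_to_num(nz$feature_min), obj$feature_names)
  nz$feature_max <- stats::setNames(chr_to_num(nz$feature_max), obj$feature_names)
  nz$target_min <- stats::setNames(chr_to_num(nz$target_min), obj$target_names)
  nz$target_max <- stats::setNames(chr_to_num(nz$target_max), obj$target_names)
  class(nz) <- "normalizer"
  structure(list(models = models, normalizer = nz, traces = NULL,
                 fitness = stats::setNames(chr_to_num(obj$fitness),
                                           obj$target_names),
                 c = obj$c, d = obj$d,
                 feature_names = obj$feature_names,
                 target_names = obj$target_names,
                 config = list(optimizer = obj$optimizer)),
            class = "trained_anfis")
}
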