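#' Specification for the synthetic seasonal hydrolysate dataset
#'
#' The generator emulates the structure of a year-long seasonal study of
#' fish-byproduct protein hydrolysates: monthly sampling, water temperature
#' cycling between roughly 12 and 38 degrees Celsius, proximate-composition
#' features (moisture, fat, ash, crude protein, in percent), and amino-acid
#' concentration targets that peak near 27-29 degrees and fall toward both
#' temperature extremes.
#'
#' Two ground-truth modes: `"peaked"` builds the targets from an explicit
#' Gaussian temperature response scaled by relative crude protein (model
#' mis-specification stress for the fitted rule base); `"explicit-anfis"`
#' draws them from a stored known Sugeno rule base evaluated on the
#' normalized features (so the fitted family matches the generator, enabling
#' function-recovery tests).
#'
#' @param n sample count (default 120, one seasonal cohort).
#' @param months months covered; samples are spread evenly across them.
#' @param temp_range numeric length-2, seasonal temperature minimum and
#'   maximum in degrees Celsius.
#' @param temp_jitter Gaussian jitter sd on temperature, degrees Celsius.
#' @param comp_noise_sd Gaussian sd on the composition columns, percent.
#' @param mode `"peaked"` or `"explicit-anfis"`.
#' @param target_noise_sd Gaussian sd added to the targets (target units).
#' @param t_opt,width optimum temperature and response width (degrees C),
#'   peaked mode.
#' @param scale peak target magnitude (concentration units), peaked mode.
#' @param n_targets number of target columns.
#' @param seed integer seed.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 120L, months = 12L, temp_range = c(12, 38),
                           temp_jitter = 1, comp_noise_sd = 1,
                           mode = c("peaked", "explicit-anfis"),
                           target_noise_sd = 0.5, t_opt = 28, width = 6,
                           scale = 20, n_targets = 1L, seed = 1L) {
  mode <- match.arg(mode)
  abort_if(temp_range[1] >= temp_range[2], "need temp min < temp max")
  abort_if(temp_jitter < 0 || comp_noise_sd < 0 || target_noise_sd < 0,
           "noise sds must be nonnegative")
  structure(list(n = as.integer(n), months = as.integer(months),
                 temp_range = as.numeric(temp_range),
                 temp_jitter = temp_jitter, comp_noise_sd = comp_noise_sd,
                 mode = mode, target_noise_sd = target_noise_sd,
                 t_opt = t_opt, width = width, scale = scale,
                 n_targets = as.integer(n_targets), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Seasonal month and temperature columns
#'
#' Temperature follows a sinusoid over the month index spanning exactly
#' `temp_range` (minimum at month 1, maximum mid-cycle) plus seeded Gaussian
#' jitter truncated at three standard deviations, so every value lies within
#' `[min - 3 jitter, max + 3 jitter]`.
#'
#' @param spec a [synthetic_spec()].
#' @return data frame with `month` and `temperature` columns, `n` rows.
#' @export
generate_environment <- function(spec) {
  month <- rep_len(seq_len(spec$months), spec$n)
  mid <- mean(spec$temp_range)
  amp <- diff(spec$temp_range) / 2
  base <- mid - amp * cos(2 * pi * (month - 1) / spec$months)
  # jitter truncated at +/- 3 sd so every value stays inside
  # [min - 3 jitter, max + 3 jitter]
  temp <- base + if (spec$temp_jitter > 0) {
    j <- with_seed(derive_seed(spec$seed, 1L),
                   rnorm(spec$n, 0, spec$temp_jitter))
    pmin(pmax(j, -3 * spec$temp_jitter), 3 * spec$temp_jitter)
  } else 0
  data.frame(month = month, temperature = temp)
}

#' Proximate-composition columns driven by temperature
#'
#' Crude protein is affinely coupled to temperature (warmer water, higher
#' byproduct protein) plus noise; moisture, fat and ash vary around fixed
#' plausible means. All columns are clamped strictly positive.
#'
#' @param spec a [synthetic_spec()].
#' @param temperature numeric temperature column.
#' @return data frame with `moisture`, `fat`, `ash`, `crude_protein`
#'   columns (percent).
#' @export
generate_composition <- function(spec, temperature) {
  n <- length(temperature)
  with_seed(derive_seed(spec$seed, 2L), {
    noise <- function() if (spec$comp_noise_sd > 0)
      rnorm(n, 0, spec$comp_noise_sd) else rep(0, n)
    out <- data.frame(
      moisture = 74 + noise(),
      fat = 8 + noise(),
      ash = 5 + noise(),
      crude_protein = 14 + 0.15 * temperature + noise())
    out[] <- lapply(out, pmax, 0.01)
    out
  })
}

# Fixed, smooth 2-rule ground-truth rule base on normalized inputs, one
# variant per target index. Chosen once as a realistic Sugeno surface.
truth_anfis_model <- function(d, target_index = 1L) {
  delta <- 0.03 * (target_index - 1L)
  anfis_model(
    rho = rbind(rep(0.3 + delta, d), rep(0.7 - delta, d)),
    sigma = matrix(0.3, 2L, d),
    coef = rbind(seq(0.4, 0.8, length.out = d),
                 seq(-0.5, -0.1, length.out = d)),
    bias = c(0.1, 0.9))
}

#' Amino-acid concentration targets with known ground truth
#'
#' Peaked mode: `scale * exp(-((T - t_opt)/width)^2) * (protein / mean
#' protein)` plus Gaussian noise — highest near `t_opt`, markedly lower at
#' 35-38 degrees and lowest at 12-15 degrees. Explicit-anfis mode: a stored
#' known rule base evaluated on min-max-normalized features, rescaled by
#' `scale`, plus noise.
#'
#' @param spec a [synthetic_spec()].
#' @param features data frame or matrix with columns `moisture`, `fat`,
#'   `ash`, `crude_protein`, `temperature`.
#' @return list with `targets` (matrix `n x n_targets`) and `truth`
#'   (generator description: mode, parameters, and for explicit-anfis the
#'   generating models and feature ranges).
#' @export
generate_targets <- function(spec, features) {
  features <- as.data.frame(features)
  n <- nrow(features)
  noise <- with_seed(derive_seed(spec$seed, 3L), {
    matrix(if (spec$target_noise_sd > 0)
      rnorm(n * spec$n_targets, 0, spec$target_noise_sd)
      else 0, n, spec$n_targets)
  })
  nm <- paste0("aa", seq_len(spec$n_targets))
  if (spec$mode == "peaked") {
    tt <- features$temperature
    prot <- features$crude_protein
    clean <- vapply(seq_len(spec$n_targets), function(j) {
      t_opt_j <- spec$t_opt + 0.5 * (j - 1L)
      spec$scale * exp(-((tt - t_opt_j) / spec$width)^2) * (prot / mean(prot))
    }, numeric(n))
    targets <- pmax(matrix(clean, n) + noise, 0.01)
    colnames(targets) <- nm
    truth <- list(mode = "peaked", t_opt = spec$t_opt, width = spec$width,
                  scale = spec$scale)
  } else {
    X <- as.matrix(features[, c("moisture", "fat", "ash", "crude_protein",
                                "temperature")])
    mn <- apply(X, 2, min); mx <- apply(X, 2, max)
    Xn <- scale_cols(X, mn, mx)
    models <- lapply(seq_len(spec$n_targets), truth_anfis_model,
                     d = ncol(X))
    clean <- vapply(models, function(mod) spec$scale * anfis_predict(Xn, mod),
                    numeric(n))
    targets <- matrix(clean, n) + noise
    colnames(targets) <- nm
    truth <- list(mode = "explicit-anfis", models = models,
                  feature_min = mn, feature_max = mx, scale = spec$scale)
  }
  list(targets = targets, truth = truth)
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_environment()], [generate_composition()] and
#' [generate_targets()] under one seed and assembles a [sample_table()] with
#' the five study features (moisture, fat, ash, crude_protein, temperature).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `table` (a [sample_table()]), `month` (integer column),
#'   and `truth` (ground-truth descriptor).
#' @export
simulate_dataset <- function(spec = synthetic_spec()) {
  env <- generate_environment(spec)
  comp <- generate_composition(spec, env$temperature)
  features <- cbind(comp, temperature = env$temperature)
  tg <- generate_targets(spec, features)
  list(table = sample_table(features, tg$targets),
       month = env$month, truth = tg$truth)
}

#' Write a synthetic fixture CSV plus ground-truth sidecar
#'
#' Emits a [read_table()]-compatible CSV (with a leading `month` column) and
#' a JSON sidecar `<path>.truth.json` describing the generator.
#' Byte-identical for identical spec and seed.
#'
#' @param spec a [synthetic_spec()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(spec, path) {
  sim <- simulate_dataset(spec)
  df <- cbind(data.frame(month = sim$month),
              as.data.frame(sim$table$features),
              as.data.frame(sim$table$targets))
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  truth <- sim$truth
  if (!is.null(truth$models)) {
    truth$models <- lapply(truth$models, function(m)
      list(d = m$d, c = m$c, parameters = encode_anfis(m)))
  }
  truth$spec <- unclass(spec)
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Noiseless-or-noisy samples from a known small rule base
#'
#' Draws `n` feature vectors uniformly on `[0, 1]^d` and evaluates a fixed
#' known `c`-rule Sugeno model (plus optional Gaussian noise), returning the
#' generating model for function-recovery experiments.
#'
#' @param n sample count.
#' @param d input count.
#' @param noise_sd Gaussian target noise sd (on the model-output scale,
#'   which spans roughly `[0, 1]`).
#' @param seed integer seed.
#' @return list with `table` (a [sample_table()], feature columns
#'   `x1..xd`, target `y`) and `model` (the generating [anfis_model()]).
#' @export
simulate_anfis_data <- function(n = 200L, d = 2L, noise_sd = 0, seed = 1L) {
  model <- truth_anfis_model(d)
  with_seed(seed, {
    X <- matrix(runif(n * d), n, d,
                dimnames = list(NULL, paste0("x", seq_len(d))))
    y <- anfis_predict(X, model) +
      if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    list(table = sample_table(X, matrix(y, ncol = 1,
                                        dimnames = list(NULL, "y"))),
         model = model)
  })
}
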