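#' Root mean square error
#'
#' \eqn{RMSE = \sqrt{\frac{1}{N}\sum_i (x_i - y_i)^2}} between predicted
#' `pred` and measured `actual`.
#'
#' @param pred,actual numeric vectors of equal length.
#' @return nonnegative scalar; 0 iff the vectors are equal.
#' @export
rmse <- function(pred, actual) {
  abort_if(length(pred) != length(actual),
           "length mismatch: %d vs %d", length(pred), length(actual))
  abort_if(length(pred) < 1L, "empty vectors")
  sqrt(mean((pred - actual)^2))
}

#' Average absolute percent relative error
#'
#' \eqn{AAPRE = \frac{100}{N}\sum_i |(x_i - y_i)/y_i|}, a scale-relative
#' percentage. Measured values of zero make the ratio undefined: by default
#' this is an error; with `zero_guard = TRUE`, terms with
#' `|actual| < eps_y` are excluded and the exclusion count attached as the
#' `"excluded"` attribute.
#'
#' @param pred,actual numeric vectors of equal length.
#' @param zero_guard exclude near-zero denominators instead of failing.
#' @param eps_y near-zero threshold for the guard.
#' @return nonnegative percentage.
#' @export
aapre <- function(pred, actual, zero_guard = FALSE, eps_y = 1e-9) {
  abort_if(length(pred) != length(actual),
           "length mismatch: %d vs %d", length(pred), length(actual))
  abort_if(length(pred) < 1L, "empty vectors")
  near0 <- abs(actual) < eps_y
  if (any(near0) && !zero_guard) {
    stop("zero measured value in AAPRE denominator; ",
         "rerun with zero_guard = TRUE to exclude such terms", call. = FALSE)
  }
  keep <- !near0
  abort_if(!any(keep), "all measured values are (near) zero")
  out <- 100 * mean(abs((pred[keep] - actual[keep]) / actual[keep]))
  attr(out, "excluded") <- sum(near0)
  out
}

metrics_by_target <- function(pred, actual, target_names, zero_guard = TRUE) {
  data.frame(
    target = target_names,
    rmse = vapply(seq_along(target_names),
                  function(j) rmse(pred[, j], actual[, j]), numeric(1)),
    aapre = vapply(seq_along(target_names),
                   function(j) as.numeric(aapre(pred[, j], actual[, j],
                                                zero_guard = zero_guard)),
                   numeric(1)),
    row.names = NULL)
}

make_report <- function(per_target, protocol, n_evaluated, details = NULL) {
  structure(list(per_target = per_target,
                 mean_rmse = mean(per_target$rmse),
                 mean_aapre = mean(per_target$aapre),
                 n_evaluated = n_evaluated,
                 protocol = protocol,
                 details = details),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report [%s]: %d predictions\n",
              x$protocol$descriptor, x$n_evaluated))
  print(x$per_target, row.names = FALSE)
  cat(sprintf("mean RMSE %.4f | mean AAPRE %.4f%%\n", x$mean_rmse, x$mean_aapre))
  invisible(x)
}

#' Repeated random-split evaluation protocol
#'
#' Runs `repeats` independent seeded 70/30 (by default) train/test splits;
#' each repeat trains a fresh model set on the training side and scores the
#' held-out side on the original measurement scale. Per-target RMSE and
#' AAPRE are averaged across repeats.
#'
#' @param table a [sample_table()].
#' @param config a [training_config()].
#' @param repeats number of independent splits.
#' @param train_fraction training fraction per split.
#' @param seed top-level seed; per-repeat split and training seeds derive
#'   from it.
#' @return an `evaluation_report`; `details$runs` holds the per-run metric
#'   tables.
#' @export
run_random_split_experiment <- function(table, config = training_config(),
                                        repeats = 10L, train_fraction = 0.7,
                                        seed = 1L) {
  m <- length(table$target_names)
  runs <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    sp <- random_split(table, train_fraction, seed = derive_seed(seed, 10L * r))
    cfg <- config
    cfg$seed <- derive_seed(seed, 10L * r + 1L)
    trained <- train_anfis_wo(sp$train, cfg)
    pred <- predict(trained, sp$test)
    runs[[r]] <- metrics_by_target(pred, sp$test$targets, table$target_names)
  }
  per_target <- runs[[1L]]
  if (repeats > 1L) {
    per_target$rmse <- rowMeans(
      matrix(vapply(runs, function(x) x$rmse, numeric(m)), nrow = m))
    per_target$aapre <- rowMeans(
      matrix(vapply(runs, function(x) x$aapre, numeric(m)), nrow = m))
  }
  n_test <- n_samples(table) - round(n_samples(table) * train_fraction)
  make_report(per_target,
              protocol = list(descriptor = sprintf(
                "random split %.0f/%.0f, %d repeat(s), seed %d",
                100 * train_fraction, 100 * (1 - train_fraction), repeats, seed),
                method = "split", repeats = repeats,
                train_fraction = train_fraction, seed = seed),
              n_evaluated = repeats * n_test,
              details = list(runs = runs))
}

#' K-fold cross-validation protocol
#'
#' Assigns samples to `K` folds (sizes differ by at most one); for each fold
#' trains on the remaining `K - 1` folds and predicts the held-out fold, so
#' every sample is predicted exactly once out-of-fold. Metrics are computed
#' per target on the pooled out-of-fold predictions, original scale.
#'
#' @param table a [sample_table()].
#' @param config a [training_config()].
#' @param K fold count.
#' @param seed top-level seed.
#' @return an `evaluation_report`; `details$oof` holds the pooled
#'   out-of-fold prediction matrix and `details$folds` the assignment.
#' @export
run_kfold_experiment <- function(table, config = training_config(), K = 10L,
                                 seed = 1L) {
  n <- n_samples(table)
  folds <- kfold_assign(n, K, seed = derive_seed(seed, 1L))
  oof <- matrix(NA_real_, n, length(table$target_names),
                dimnames = list(NULL, table$target_names))
  for (k in seq_len(K)) {
    test_idx <- which(folds$fold == k)
    train_idx <- which(folds$fold != k)
    cfg <- config
    cfg$seed <- derive_seed(seed, 20L * k)
    trained <- train_anfis_wo(subset_table(table, train_idx), cfg)
    oof[test_idx, ] <- predict(trained, subset_table(table, test_idx))
  }
  per_target <- metrics_by_target(oof, table$targets, table$target_names)
  make_report(per_target,
              protocol = list(descriptor = sprintf(
                "%d-fold cross-validation (pooled out-of-fold), seed %d",
                K, seed), method = "cv", K = K, seed = seed),
              n_evaluated = n,
              details = list(oof = oof, folds = folds))
}

#' Compare training configurations under identical splits or folds
#'
#' Every configuration is evaluated under byte-identical data partitions
#' (the protocol seed is shared), so differences reflect the algorithms
#' only. External learners are not reimplemented; their predictions can be
#' supplied as per-target prediction matrices via `external`.
#'
#' @param table a [sample_table()].
#' @param configs named list of [training_config()] objects (names become
#'   column prefixes).
#' @param protocol `"split"` or `"cv"`.
#' @param repeats,train_fraction split-protocol settings.
#' @param K cv-protocol setting.
#' @param seed shared protocol seed.
#' @param external optional named list of `N x m` prediction matrices on the
#'   original scale (same row order as `table`), scored as-is.
#' @return list with `table` (rows = targets, columns = algorithm x metric)
#'   and `reports` (the full per-algorithm `evaluation_report`s).
#' @export
compare_algorithms <- function(table, configs, protocol = c("split", "cv"),
                               repeats = 10L, train_fraction = 0.7, K = 10L,
                               seed = 1L, external = NULL) {
  protocol <- match.arg(protocol)
  abort_if(length(configs) < 1L, "need at least one configuration")
  if (is.null(names(configs)) || any(names(configs) == "")) {
    names(configs) <- paste0("alg", seq_along(configs))
  }
  reports <- lapply(configs, function(cfg) {
    if (protocol == "split") {
      run_random_split_experiment(table, cfg, repeats, train_fraction, seed)
    } else {
      run_kfold_experiment(table, cfg, K, seed)
    }
  })
  if (!is.null(external)) {
    for (nm in names(external)) {
      pred <- as.matrix(external[[nm]])
      abort_if(nrow(pred) != n_samples(table) ||
                 ncol(pred) != length(table$target_names),
               "external predictions '%s' do not match the table shape", nm)
      reports[[nm]] <- make_report(
        metrics_by_target(pred, table$targets, table$target_names),
        protocol = list(descriptor = sprintf("external predictions '%s'", nm),
                        method = "external", seed = seed),
        n_evaluated = n_samples(table))
    }
  }
  out <- data.frame(target = table$target_names, row.names = NULL)
  for (nm in names(reports)) {
    out[[paste0(nm, "_rmse")]] <- reports[[nm]]$per_target$rmse
    out[[paste0(nm, "_aapre")]] <- reports[[nm]]$per_target$aapre
  }
  list(table = out, reports = reports)
}

#' Write an evaluation report to CSV
#'
#' The protocol descriptor and seed are embedded as `#`-prefixed header
#' comment lines for reproducibility.
#'
#' @param report an `evaluation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# protocol: %s", report$protocol$descriptor), con)
  writeLines(sprintf("# n_evaluated: %d", report$n_evaluated), con)
  writeLines(sprintf("# mean_rmse: %.15g", report$mean_rmse), con)
  writeLines(sprintf("# mean_aapre: %.15g", report$mean_aapre), con)
  write.csv(report$per_target, con, row.names = FALSE)
  invisible(path)
}
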