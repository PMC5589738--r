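#' Construct a validated sample table
#'
#' A `sample_table` holds an `N x d` feature matrix and an `N x m` target
#' matrix with column names, the common container for every pipeline stage.
#' In the motivating use case the features are proximate composition
#' (moisture, fat, ash, crude protein, all in percent) plus water temperature
#' in degrees Celsius, and the targets are amino-acid concentrations.
#'
#' @param features numeric matrix or data frame, `N x d`.
#' @param targets numeric matrix or data frame, `N x m`.
#' @param feature_names,target_names optional character vectors; default to
#'   the column names of the inputs.
#' @return an object of class `sample_table` with fields `features`,
#'   `targets`, `feature_names`, `target_names`.
#' @export
sample_table <- function(features, targets, feature_names = NULL,
                         target_names = NULL) {
  features <- as.matrix(features)
  targets <- as.matrix(targets)
  if (!is.null(feature_names)) colnames(features) <- feature_names
  if (!is.null(target_names)) colnames(targets) <- target_names
  abort_if(is.null(colnames(features)) || is.null(colnames(targets)),
           "feature and target columns must be named")
  abort_if(nrow(features) != nrow(targets),
           "row count mismatch: %d feature rows vs %d target rows",
           nrow(features), nrow(targets))
  abort_if(nrow(features) < 2L, "need at least 2 samples, got %d", nrow(features))
  abort_if(ncol(features) < 1L || ncol(targets) < 1L,
           "need at least one feature and one target column")
  for (nm in colnames(features)) {
    abort_if(!is.numeric(features[, nm]) || anyNA(features[, nm]),
             "feature column '%s' contains missing or non-numeric values", nm)
  }
  for (nm in colnames(targets)) {
    abort_if(!is.numeric(targets[, nm]) || anyNA(targets[, nm]),
             "target column '%s' contains missing or non-numeric values", nm)
  }
  storage.mode(features) <- "double"
  storage.mode(targets) <- "double"
  structure(list(features = features, targets = targets,
                 feature_names = colnames(features),
                 target_names = colnames(targets)),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("sample_table: %d samples, %d features (%s), %d targets (%s)\n",
              nrow(x$features), ncol(x$features),
              paste(x$feature_names, collapse = ", "),
              ncol(x$targets), paste(x$target_names, collapse = ", ")))
  invisible(x)
}

#' Number of samples in a sample table
#' @param table a [sample_table()].
#' @return integer sample count.
#' @export
n_samples <- function(table) nrow(table$features)

#' Read a sample table from CSV
#'
#' The CSV must have a header row containing every requested feature and
#' target column; extra columns are ignored. Comma separator, `.` decimal,
#' UTF-8.
#'
#' @param path CSV file path.
#' @param feature_names,target_names column names to use as features/targets,
#'   in the desired order.
#' @return a [sample_table()].
#' @export
read_table <- function(path, feature_names, target_names) {
  abort_if(!file.exists(path), "file not found: %s", path)
  df <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  abort_if(nrow(df) == 0L, "empty table in %s", path)
  for (nm in c(feature_names, target_names)) {
    abort_if(!nm %in% names(df), "column '%s' not found in %s", nm, path)
    bad <- which(!is.na(df[[nm]]) & is.na(suppressWarnings(as.numeric(df[[nm]]))))
    if (is.character(df[[nm]]) || is.factor(df[[nm]])) {
      bad2 <- which(is.na(suppressWarnings(as.numeric(as.character(df[[nm]])))))
      abort_if(length(bad2) > 0L,
               "non-numeric cell in column '%s', row %d of %s", nm, bad2[1], path)
      df[[nm]] <- as.numeric(as.character(df[[nm]]))
    }
    miss <- which(is.na(df[[nm]]))
    abort_if(length(miss) > 0L,
             "missing value in column '%s', row %d of %s", nm, miss[1], path)
    abort_if(length(bad) > 0L,
             "non-numeric cell in column '%s', row %d of %s", nm, bad[1], path)
  }
  sample_table(df[feature_names], df[target_names])
}

#' Write a sample table to CSV
#' @param table a [sample_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  df <- cbind(as.data.frame(table$features), as.data.frame(table$targets))
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Fit a per-column min-max normalization transform
#'
#' Records per-column minima and maxima of all feature and target columns so
#' columns can be mapped onto `[0, 1]` (on the fitting table) and back.
#' Fitted on the training portion only; applying the transform to unseen data
#' can legitimately produce values outside `[0, 1]` (no clipping).
#'
#' @param table a [sample_table()] (typically the training split).
#' @return an object of class `normalizer`.
#' @export
fit_normalizer <- function(table) {
  rng <- function(mat, what) {
    mn <- apply(mat, 2, min)
    mx <- apply(mat, 2, max)
    flat <- which(mx - mn <= 0)
    abort_if(length(flat) > 0L, "constant %s column '%s' cannot be normalized",
             what, colnames(mat)[flat[1]])
    list(min = mn, max = mx)
  }
  f <- rng(table$features, "feature")
  t <- rng(table$targets, "target")
  structure(list(feature_min = f$min, feature_max = f$max,
                 target_min = t$min, target_max = t$max),
            class = "normalizer")
}

scale_cols <- function(mat, mn, mx) {
  sweep(sweep(mat, 2, mn, "-"), 2, mx - mn, "/")
}

unscale_cols <- function(mat, mn, mx) {
  sweep(sweep(mat, 2, mx - mn, "*"), 2, mn, "+")
}

#' Apply / invert a normalization transform
#'
#' @param normalizer a [fit_normalizer()] result.
#' @param features,targets numeric matrices on the original scale
#'   (`normalize_*`) or normalized scale (`denormalize_*`).
#' @return matrix of the same shape on the other scale.
#' @export
normalize_features <- function(normalizer, features) {
  scale_cols(as.matrix(features), normalizer$feature_min, normalizer$feature_max)
}

#' @rdname normalize_features
#' @export
normalize_targets <- function(normalizer, targets) {
  scale_cols(as.matrix(targets), normalizer$target_min, normalizer$target_max)
}

#' @rdname normalize_features
#' @export
denormalize_features <- function(normalizer, features) {
  unscale_cols(as.matrix(features), normalizer$feature_min, normalizer$feature_max)
}

#' @rdname normalize_features
#' @export
denormalize_targets <- function(normalizer, targets) {
  unscale_cols(as.matrix(targets), normalizer$target_min, normalizer$target_max)
}

#' Normalize a whole sample table
#' @param normalizer a [fit_normalizer()] result.
#' @param table a [sample_table()].
#' @return a [sample_table()] with normalized feature and target columns.
#' @export
normalize_table <- function(normalizer, table) {
  sample_table(normalize_features(normalizer, table$features),
               normalize_targets(normalizer, table$targets),
               table$feature_names, table$target_names)
}

# Internal row subset; skips the N >= 2 dataset invariant so single held-out
# rows (e.g. leave-one-out folds) remain representable.
subset_table <- function(table, idx) {
  structure(list(features = table$features[idx, , drop = FALSE],
                 targets = table$targets[idx, , drop = FALSE],
                 feature_names = table$feature_names,
                 target_names = table$target_names),
            class = "sample_table")
}

#' Seeded random train/test split
#'
#' Splits the samples into disjoint, exhaustive train and test index sets;
#' the train size is `round(N * train_fraction)`. Reproducible by seed.
#'
#' @param table a [sample_table()].
#' @param train_fraction fraction of samples for the training set, in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` sample tables and the 1-based
#'   `train_idx` / `test_idx`.
#' @export
random_split <- function(table, train_fraction = 0.7, seed = 1L) {
  abort_if(train_fraction <= 0 || train_fraction >= 1,
           "train_fraction must be in (0, 1), got %g", train_fraction)
  n <- n_samples(table)
  n_train <- round(n * train_fraction)
  abort_if(n_train < 1L || n_train >= n,
           "split of %d samples at fraction %g leaves an empty side",
           n, train_fraction)
  train_idx <- with_seed(seed, sort(sample.int(n, n_train)))
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = subset_table(table, train_idx),
       test = subset_table(table, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Seeded k-fold assignment
#'
#' Assigns each of `N` samples to one of `K` folds so that fold sizes differ
#' by at most one; folds partition the sample index set.
#'
#' @param N sample count.
#' @param K fold count, `2 <= K <= N`.
#' @param seed integer seed.
#' @return object of class `fold_assignment` with integer vector `fold`
#'   (values in `1..K`), `K`, and `seed`.
#' @export
kfold_assign <- function(N, K, seed = 1L) {
  abort_if(K < 2L || K > N, "need 2 <= K <= N, got K=%d, N=%d", K, N)
  fold <- with_seed(seed, sample(rep_len(seq_len(K), N)))
  structure(list(fold = as.integer(fold), K = as.integer(K),
                 seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Write a fold assignment to a two-column CSV
#' @param assignment a [kfold_assign()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_folds <- function(assignment, path) {
  write.csv(data.frame(sample_index = seq_along(assignment$fold),
                       fold = assignment$fold),
            path, row.names = FALSE)
  invisible(path)
}
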