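# Regression metrics and dataset splitting.

#' Regression evaluation metrics
#'
#' Mean squared error, Pearson correlation of the pooled actual vs
#' predicted values (sample standard deviations, n - 1), and mean
#' absolute percentage error. Per-output values are reported alongside
#' the pooled ones.
#'
#' MAPE excludes elements whose |actual| is at or below `eps` (the
#' relative error is undefined there); the number of exclusions is
#' reported and a warning emitted. R is flagged `NA` (undefined), never
#' forced to zero, when either pooled vector is constant.
#'
#' @param actual Numeric matrix (or vector) of observed values.
#' @param predicted Numeric matrix (or vector) of predictions, same shape.
#' @param eps Magnitude floor for MAPE denominators (default 1e-8).
#' @return An `nn_metrics` list: `mse`, `r`, `mape` (pooled), `per_output`
#'   data.frame, `n`, `mape_excluded`.
#' @export
#' @examples
#' m <- nn_metrics(c(1, 2, 3), c(1, 3, 2))
#' c(m$mse, m$mape, m$r)  # 2/3, 27.78, 0.5
nn_metrics <- function(actual, predicted, eps = 1e-8) {
  actual <- as.matrix(actual); predicted <- as.matrix(predicted)
  if (!all(dim(actual) == dim(predicted))) {
    stop("actual and predicted must have identical shapes")
  }
  a <- as.numeric(actual); p <- as.numeric(predicted)
  n <- length(a)
  if (n == 0) stop("empty inputs")
  mse <- mean((a - p)^2)
  r <- pearson_r(a, p)
  ok <- abs(a) > eps
  excluded <- sum(!ok)
  if (excluded > 0) {
    warning(excluded, " element(s) excluded from MAPE (|actual| <= eps)")
  }
  mape <- if (any(ok)) mean(abs((a[ok] - p[ok]) / a[ok])) * 100 else NA_real_
  per_output <- NULL
  if (ncol(actual) > 1) {
    per_output <- data.frame(
      output = if (!is.null(colnames(actual))) colnames(actual)
               else paste0("y", seq_len(ncol(actual))),
      mse = vapply(seq_len(ncol(actual)), function(j)
        mean((actual[, j] - predicted[, j])^2), 0),
      r = vapply(seq_len(ncol(actual)), function(j)
        pearson_r(actual[, j], predicted[, j]), 0),
      mape = vapply(seq_len(ncol(actual)), function(j) {
        aj <- actual[, j]; pj <- predicted[, j]; okj <- abs(aj) > eps
        if (any(okj)) mean(abs((aj[okj] - pj[okj]) / aj[okj])) * 100
        else NA_real_
      }, 0),
      stringsAsFactors = FALSE
    )
  }
  structure(list(mse = mse, r = r, mape = mape, per_output = per_output,
                 n = n, mape_excluded = excluded),
            class = "nn_metrics")
}

# Pearson correlation via the standardized-product form with sample sds;
# NA (undefined) for constant vectors.
pearson_r <- function(a, p) {
  n <- length(a)
  if (n < 2) return(NA_real_)
  sa <- stats::sd(a); sp <- stats::sd(p)
  if (sa == 0 || sp == 0) return(NA_real_)
  sum((a - mean(a)) / sa * (p - mean(p)) / sp) / (n - 1)
}

#' @export
print.nn_metrics <- function(x, ...) {
  cat(sprintf("MSE %.6g | R %s | MAPE %s%% (n = %d)\n", x$mse,
              ifelse(is.na(x$r), "undefined", sprintf("%.5f", x$r)),
              ifelse(is.na(x$mape), "undefined", sprintf("%.2f", x$mape)),
              x$n))
  invisible(x)
}

#' Split a dataset into training, validation and test sets
#'
#' Defaults mirror the study protocol: 100 test rows carved from the full
#' dataset, with 15% of the remaining training rows held out as a
#' validation set for early stopping. `"random"` splits are seeded;
#' `"sequential"` takes the last `n_test` rows as the test set and the
#' last `validation_fraction` of the remainder as validation.
#'
#' @param features A `feature_matrices` object (or a list with numeric
#'   matrices `A` and `B`).
#' @param n_test Number of test rows (default 100).
#' @param validation_fraction Fraction of non-test rows used for
#'   validation (default 0.15).
#' @param method `"random"` (default) or `"sequential"`.
#' @param seed Integer seed for the random split.
#' @return A `data_split`: list of matrices `X_train`, `Y_train`,
#'   `X_val`, `Y_val`, `X_test`, `Y_test` plus the index vectors, method
#'   and seed.
#' @export
split_dataset <- function(features, n_test = 100L, validation_fraction = 0.15,
                          method = c("random", "sequential"), seed = 1L) {
  method <- match.arg(method)
  A <- as.matrix(features$A); B <- as.matrix(features$B)
  n <- nrow(A)
  if (n_test >= n) stop("n_test must be smaller than the row count")
  if (validation_fraction < 0 || validation_fraction >= 1) {
    stop("validation_fraction must lie in [0, 1)")
  }
  if (method == "random") {
    set.seed(seed)
    test_idx <- sort(sample.int(n, n_test))
    rest <- setdiff(seq_len(n), test_idx)
    n_val <- floor(length(rest) * validation_fraction)
    val_idx <- if (n_val > 0) sort(sample(rest, n_val)) else integer(0)
  } else {
    test_idx <- seq.int(n - n_test + 1L, n)
    rest <- seq_len(n - n_test)
    n_val <- floor(length(rest) * validation_fraction)
    val_idx <- if (n_val > 0) seq.int(length(rest) - n_val + 1L, length(rest))
               else integer(0)
  }
  train_idx <- setdiff(seq_len(n), c(test_idx, val_idx))
  structure(list(
    X_train = A[train_idx, , drop = FALSE],
    Y_train = B[train_idx, , drop = FALSE],
    X_val = A[val_idx, , drop = FALSE],
    Y_val = B[val_idx, , drop = FALSE],
    X_test = A[test_idx, , drop = FALSE],
    Y_test = B[test_idx, , drop = FALSE],
    train_idx = train_idx, val_idx = val_idx, test_idx = test_idx,
    method = method, seed = as.integer(seed)
  ), class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("data split (%s, seed %d): %d train / %d validation / %d test\n",
              x$method, x$seed, length(x$train_idx), length(x$val_idx),
              length(x$test_idx)))
  invisible(x)
}
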