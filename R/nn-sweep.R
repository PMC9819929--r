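# Architecture grid and the size x algorithm sweep.

#' Candidate hidden-layer sizes
#'
#' Empirical sizing rule `n = ceil(sqrt(n_in + n_out)) + a` evaluated over
#' a range of integer offsets, deduplicated and sorted. With 8 inputs,
#' 12 outputs and a in 1..10 this yields the sizes 6 through 15.
#'
#' @param n_in Input-unit count.
#' @param n_out Output-unit count.
#' @param a_values Integer offsets (default 1:10).
#' @return Sorted integer vector of candidate sizes.
#' @export
#' @examples
#' hidden_size_candidates(8, 12)  # 6:15
hidden_size_candidates <- function(n_in, n_out, a_values = 1:10) {
  if (n_in < 1 || n_out < 1) stop("unit counts must be positive")
  if (length(a_values) == 0) stop("a_values must be nonempty")
  sort(unique(as.integer(ceiling(sqrt(n_in + n_out)) + a_values)))
}

#' Sweep hidden sizes and training algorithms
#'
#' Trains one network per (hidden size, algorithm) grid cell on a common
#' data split, evaluates each on the test set, and reports the grid with
#' the argmin-test-MAPE network. Per-cell weight seeds are derived as
#' `seed + cell index` so the sweep is reproducible cell by cell. A cell
#' whose training aborts is marked failed and the sweep continues.
#'
#' @param features A `feature_matrices` object (inputs already reduced to
#'   the retained predictors).
#' @param sizes Hidden-layer sizes, e.g. [hidden_size_candidates()].
#' @param algorithms Training algorithms (default all five).
#' @param config Base [training_config()]; its `algorithm` field is
#'   overridden per cell.
#' @param n_test,validation_fraction,split_method Passed to
#'   [split_dataset()].
#' @param seed Base seed for the split and the per-cell weight draws.
#' @param keep_models Retain every trained model (default FALSE: only the
#'   best model is kept).
#' @return A `sweep_result`: list with `grid` (data.frame network,
#'   hidden_size, algorithm, mape, mse, r, status), `best` (row of the
#'   grid), `best_model`, `split`, and optionally `models`.
#' @export
sweep_networks <- function(features, sizes = hidden_size_candidates(8, 12),
                           algorithms = BK_ALGORITHMS,
                           config = training_config(),
                           n_test = 100L, validation_fraction = 0.15,
                           split_method = "random", seed = 1L,
                           keep_models = FALSE) {
  if (length(sizes) < 1 || length(algorithms) < 1) {
    stop("need at least one size and one algorithm")
  }
  algorithms <- vapply(algorithms, function(a)
    match.arg(toupper(a), BK_ALGORITHMS), "")
  split <- split_dataset(features, n_test = n_test,
                         validation_fraction = validation_fraction,
                         method = split_method, seed = seed)
  n_in <- ncol(split$X_train); n_out <- ncol(split$Y_train)
  cells <- expand.grid(algorithm = algorithms, hidden_size = sizes,
                       stringsAsFactors = FALSE)
  # network ids run across algorithms within a size, then down sizes
  cells <- cells[order(match(cells$hidden_size, sizes)), ]
  grid <- data.frame(network = paste0("N", seq_len(nrow(cells))),
                     hidden_size = cells$hidden_size,
                     algorithm = cells$algorithm,
                     mape = NA_real_, mse = NA_real_, r = NA_real_,
                     status = "ok", stringsAsFactors = FALSE)
  models <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell_cfg <- config
    cell_cfg$algorithm <- grid$algorithm[i]
    net <- network_model(n_in, grid$hidden_size[i], n_out,
                         seed = seed + i,
                         input_labels = colnames(split$X_train),
                         output_labels = colnames(split$Y_train))
    fit <- tryCatch(train_network(net, split, cell_cfg),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      grid$status[i] <- paste("failed:", conditionMessage(fit))
      next
    }
    m <- nn_metrics(split$Y_test, forward(fit$net, split$X_test))
    grid$mape[i] <- m$mape
    grid$mse[i] <- m$mse
    grid$r[i] <- m$r
    if (keep_models) models[[i]] <- fit$net
    else models[[i]] <- NULL
    if (!keep_models) {
      ok <- grid$status == "ok" & !is.na(grid$mape)
      if (which.min(replace(grid$mape, !ok, Inf)) == i) models[["best"]] <- fit$net
    }
  }
  ok <- grid$status == "ok" & !is.na(grid$mape)
  if (!any(ok)) stop("every sweep cell failed")
  best_i <- which.min(replace(grid$mape, !ok, Inf))
  best_model <- if (keep_models) models[[best_i]] else models[["best"]]
  structure(list(grid = grid, best = grid[best_i, ],
                 best_model = best_model,
                 models = if (keep_models) models[seq_len(nrow(grid))] else NULL,
                 split = split, seed = as.integer(seed)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep of %d networks (%d sizes x %d algorithms)\n",
              nrow(x$grid), length(unique(x$grid$hidden_size)),
              length(unique(x$grid$algorithm))))
  cat(sprintf("best: %s (%d hidden, %s) test MAPE %.2f%%\n",
              x$best$network, x$best$hidden_size, x$best$algorithm,
              x$best$mape))
  invisible(x)
}

#' Render a sweep grid in the published wide layout
#'
#' Rows are hidden sizes, columns training algorithms, entries the test
#' MAPE (%) of each network.
#'
#' @param sweep A `sweep_result`.
#' @return A data.frame, one row per hidden size.
#' @export
sweep_grid_table <- function(sweep) {
  g <- sweep$grid
  sizes <- sort(unique(g$hidden_size))
  algs <- unique(g$algorithm)
  out <- data.frame(hidden_size = sizes)
  for (a in algs) {
    out[[a]] <- vapply(sizes, function(s) {
      v <- g$mape[g$hidden_size == s & g$algorithm == a]
      if (length(v) == 1) v else NA_real_
    }, 0)
  }
  out
}
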