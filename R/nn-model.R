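# Single-hidden-layer feedforward network: logsig hidden, purelin output.
#
# Weight naming follows the closed-form predictor b = w1 %*% logsig(w2 %*% c
# + b1) + b2: w2/b1 are input-to-hidden, w1/b2 hidden-to-output.

#' Logistic sigmoid
#'
#' `logsig(y) = 1 / (1 + exp(-y))`, applied elementwise.
#'
#' @param y Numeric vector or matrix.
#' @return Values strictly in (0, 1).
#' @export
logsig <- function(y) 1 / (1 + exp(-y))

#' Construct a network model
#'
#' A single-hidden-layer feedforward regression network with logistic
#' sigmoid hidden units and a linear output layer. Weights are
#' initialized uniformly in +/- sqrt(6 / (fan_in + fan_out)), seeded.
#'
#' @param n_in Input count.
#' @param n_hidden Hidden-unit count.
#' @param n_out Output count.
#' @param seed Integer seed for the initial weights.
#' @param input_labels,output_labels Optional column labels.
#' @return A `network_model`: list with `w2` (n_hidden x n_in), `b1`
#'   (n_hidden), `w1` (n_out x n_hidden), `b2` (n_out), dims, labels and
#'   an optional `standardization` element (set by the trainers).
#' @export
network_model <- function(n_in, n_hidden, n_out, seed = 1L,
                          input_labels = NULL, output_labels = NULL) {
  stopifnot(n_in >= 1, n_hidden >= 1, n_out >= 1)
  set.seed(seed)
  lim2 <- sqrt(6 / (n_in + n_hidden))
  lim1 <- sqrt(6 / (n_hidden + n_out))
  structure(list(
    n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
    n_out = as.integer(n_out),
    w2 = matrix(stats::runif(n_hidden * n_in, -lim2, lim2), n_hidden, n_in),
    b1 = stats::runif(n_hidden, -lim2, lim2),
    w1 = matrix(stats::runif(n_out * n_hidden, -lim1, lim1), n_out, n_hidden),
    b2 = stats::runif(n_out, -lim1, lim1),
    activation = c(hidden = "logsig", output = "purelin"),
    input_labels = input_labels, output_labels = output_labels,
    standardization = NULL
  ), class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("network_model %d-%d-%d (logsig/purelin)%s\n",
              x$n_in, x$n_hidden, x$n_out,
              if (!is.null(x$standardization)) ", standardized io" else ""))
  invisible(x)
}

# forward pass on the network's internal (possibly standardized) scale;
# X is n x n_in, returns n x n_out
forward_raw <- function(net, X) {
  H <- logsig(tcrossprod(X, net$w2) +
                matrix(net$b1, nrow(X), net$n_hidden, byrow = TRUE))
  tcrossprod(H, net$w1) + matrix(net$b2, nrow(X), net$n_out, byrow = TRUE)
}

#' Forward pass / prediction
#'
#' Computes `b = w1 %*% logsig(w2 %*% c + b1) + b2` for one input vector
#' or a matrix of row-wise inputs. If the model carries standardization
#' parameters (set during training) the input is standardized and the
#' output de-standardized transparently.
#'
#' @param net A `network_model`.
#' @param x Numeric vector of length `n_in`, or an n x n_in matrix.
#' @return Numeric vector of length `n_out` (vector input) or an
#'   n x n_out matrix.
#' @export
#' @examples
#' net <- network_model(2, 3, 1, seed = 42)
#' forward(net, c(0.5, -0.2))
forward <- function(net, x) {
  single <- is.null(dim(x))
  X <- if (single) matrix(as.numeric(x), 1) else as.matrix(x)
  if (ncol(X) != net$n_in) {
    stop(sprintf("input has %d column(s), network expects %d",
                 ncol(X), net$n_in))
  }
  st <- net$standardization
  if (!is.null(st)) {
    X <- sweep(sweep(X, 2, st$x_center, "-"), 2, st$x_scale, "/")
  }
  Y <- forward_raw(net, X)
  if (!is.null(st)) {
    Y <- sweep(sweep(Y, 2, st$y_scale, "*"), 2, st$y_center, "+")
  }
  if (!is.null(net$output_labels)) colnames(Y) <- net$output_labels
  if (single) drop(Y) else Y
}

#' Load a network from printed weight tables
#'
#' Builds a `network_model` from two delimited tables: the input-to-hidden
#' table (one row per hidden unit: n_in weights then a trailing bias
#' column) and the hidden-to-output table (one row per output unit:
#' n_hidden weights then a trailing bias column). Dimensions are taken
#' from the tables themselves; if `expected_hidden` is supplied and
#' disagrees, the mismatch is reported and loading stops unless
#' `override = TRUE`.
#'
#' The shipped reference tables are self-consistent at 11 hidden units
#' even though the accompanying text describes the selected network as
#' having 12; the loader surfaces this rather than resolving it silently.
#'
#' @param w2_b1_path CSV of input-to-hidden weights + bias (default: the
#'   shipped reference table).
#' @param w1_b2_path CSV of hidden-to-output weights + bias (default: the
#'   shipped reference table).
#' @param expected_hidden Optional hidden-unit count to validate against.
#' @param override Proceed despite an `expected_hidden` mismatch
#'   (default FALSE).
#' @return A `network_model` without standardization (the printed weights
#'   act on raw units).
#' @export
load_weight_tables <- function(w2_b1_path = bk_fixture("table5_weights.csv"),
                               w1_b2_path = bk_fixture("table6_weights.csv"),
                               expected_hidden = NULL, override = FALSE) {
  t5 <- as.matrix(utils::read.csv(w2_b1_path))
  t6 <- as.matrix(utils::read.csv(w1_b2_path))
  if (!is.numeric(t5) || !is.numeric(t6)) stop("weight tables must be numeric")
  n_hidden <- nrow(t5)
  n_in <- ncol(t5) - 1L
  n_out <- nrow(t6)
  hidden_from_t6 <- ncol(t6) - 1L
  if (hidden_from_t6 != n_hidden) {
    stop(sprintf(paste0(
      "inconsistent weight tables: input-to-hidden table implies %d hidden ",
      "unit(s) but hidden-to-output table implies %d"),
      n_hidden, hidden_from_t6))
  }
  if (!is.null(expected_hidden) && expected_hidden != n_hidden) {
    msg <- sprintf(paste0(
      "weight tables imply %d hidden unit(s), expected %d ",
      "(tables: %d x %d and %d x %d)"),
      n_hidden, expected_hidden, nrow(t5), ncol(t5), nrow(t6), ncol(t6))
    if (!override) stop(msg, "; pass override = TRUE to load anyway")
    warning(msg)
  }
  net <- network_model(n_in, n_hidden, n_out, seed = 0L)
  net$w2 <- unname(t5[, seq_len(n_in), drop = FALSE])
  net$b1 <- unname(t5[, n_in + 1L])
  net$w1 <- unname(t6[, seq_len(n_hidden), drop = FALSE])
  net$b2 <- unname(t6[, n_hidden + 1L])
  net
}

#' Save / load a network model as structured text
#'
#' JSON round-trip of dimensions, labels, standardization parameters,
#' weights and activation names.
#'
#' @param net A `network_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns
#'   the restored `network_model`.
#' @export
save_model <- function(net, path) {
  jsonlite::write_json(unclass(net), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- network_model(obj$n_in, obj$n_hidden, obj$n_out, seed = 0L)
  net$w2 <- matrix(as.numeric(t(obj$w2)), obj$n_hidden, obj$n_in,
                   byrow = TRUE)
  net$b1 <- as.numeric(obj$b1)
  net$w1 <- matrix(as.numeric(t(obj$w1)), obj$n_out, obj$n_hidden,
                   byrow = TRUE)
  net$b2 <- as.numeric(obj$b2)
  net$input_labels <- if (is.null(obj$input_labels)) NULL else obj$input_labels
  net$output_labels <- if (is.null(obj$output_labels)) NULL else obj$output_labels
  if (!is.null(obj$standardization) && length(obj$standardization) > 0) {
    net$standardization <- lapply(obj$standardization, as.numeric)
  }
  net
}
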