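# Full-batch backpropagation training: shared gradient core plus five
# update rules (GDBP, MOBP, VLN, RPROP, CGBP).

BK_ALGORITHMS <- c("GDBP", "MOBP", "VLN", "RPROP", "CGBP")

#' Training configuration
#'
#' Hyperparameters for the five backpropagation variants. Defaults are
#' the classical published constants for each rule.
#'
#' @param algorithm One of `"GDBP"` (plain gradient descent), `"MOBP"`
#'   (momentum), `"VLN"` (variable learning rate), `"RPROP"` (resilient,
#'   sign-based step adaptation) or `"CGBP"` (Fletcher-Reeves conjugate
#'   gradient with restarts and a backtracking line search).
#' @param learning_rate Step size for GDBP/MOBP and the initial rate for
#'   VLN (default 0.01).
#' @param momentum MOBP momentum coefficient (default 0.9).
#' @param vln_increase,vln_decrease,vln_max_perf_inc VLN rate schedule:
#'   grow by 1.05 after an improving epoch, shrink by 0.7 and reject the
#'   step when the loss grows by more than 4%.
#' @param rprop_eta_plus,rprop_eta_minus,rprop_delta0,rprop_delta_max
#'   RPROP constants (1.2, 0.5, 0.07, 50).
#' @param max_epochs Epoch budget (default 1000).
#' @param patience Early-stop patience on validation MSE, epochs
#'   (default 6).
#' @param grad_floor Stop when the max |gradient| falls below this
#'   (default 1e-10).
#' @param standardize Z-score inputs and outputs internally
#'   (default TRUE); the inverse transform is applied at prediction.
#' @param seed Seed used when the trainer must draw (fresh nets).
#' @return A `training_config` list.
#' @export
training_config <- function(algorithm = c("VLN", "GDBP", "MOBP", "RPROP",
                                          "CGBP"),
                            learning_rate = 0.01,
                            momentum = 0.9,
                            vln_increase = 1.05,
                            vln_decrease = 0.7,
                            vln_max_perf_inc = 1.04,
                            rprop_eta_plus = 1.2,
                            rprop_eta_minus = 0.5,
                            rprop_delta0 = 0.07,
                            rprop_delta_max = 50,
                            max_epochs = 1000L,
                            patience = 6L,
                            grad_floor = 1e-10,
                            standardize = TRUE,
                            seed = 1L) {
  algorithm <- match.arg(toupper(algorithm[1]), BK_ALGORITHMS)
  stopifnot(learning_rate > 0, momentum >= 0, vln_increase > 1,
            vln_decrease > 0, vln_decrease < 1, rprop_eta_plus > 1,
            rprop_eta_minus > 0, rprop_eta_minus < 1, rprop_delta0 > 0,
            rprop_delta_max > 0, max_epochs >= 0, patience >= 1)
  structure(list(
    algorithm = algorithm, learning_rate = learning_rate,
    momentum = momentum,
    vln_increase = vln_increase, vln_decrease = vln_decrease,
    vln_max_perf_inc = vln_max_perf_inc,
    rprop_eta_plus = rprop_eta_plus, rprop_eta_minus = rprop_eta_minus,
    rprop_delta0 = rprop_delta0, rprop_delta_max = rprop_delta_max,
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    grad_floor = grad_floor, standardize = isTRUE(standardize),
    seed = as.integer(seed)
  ), class = "training_config")
}

# --- flat-parameter machinery ------------------------------------------

net_dims <- function(net) {
  c(n_in = net$n_in, n_hidden = net$n_hidden, n_out = net$n_out)
}

n_params <- function(dims) {
  unname(dims[2] * dims[1] + dims[2] + dims[3] * dims[2] + dims[3])
}

# flatten order: w2 row-major, b1, w1 row-major, b2
flatten_net <- function(net) {
  c(as.vector(t(net$w2)), net$b1, as.vector(t(net$w1)), net$b2)
}

set_net_weights <- function(net, theta) {
  d <- net_dims(net)
  if (length(theta) != n_params(d)) {
    stop(sprintf("weight vector length %d, expected %d",
                 length(theta), n_params(d)))
  }
  i <- 0L
  take <- function(k) {
    out <- theta[(i + 1L):(i + k)]; i <<- i + k; out
  }
  net$w2 <- matrix(take(d[2] * d[1]), d[2], d[1], byrow = TRUE)
  net$b1 <- take(d[2])
  net$w1 <- matrix(take(d[3] * d[2]), d[3], d[2], byrow = TRUE)
  net$b2 <- take(d[3])
  net
}

# MSE loss (mean over samples and outputs) and its gradient w.r.t. the
# flat parameter vector, on the standardized scale.
nn_loss_grad <- function(theta, X, Y, dims, want_grad = TRUE) {
  n_in <- dims[1]; n_h <- dims[2]; n_out <- dims[3]
  n <- nrow(X)
  i <- 0L
  w2 <- matrix(theta[(i + 1L):(i + n_h * n_in)], n_h, n_in, byrow = TRUE)
  i <- i + n_h * n_in
  b1 <- theta[(i + 1L):(i + n_h)]; i <- i + n_h
  w1 <- matrix(theta[(i + 1L):(i + n_out * n_h)], n_out, n_h, byrow = TRUE)
  i <- i + n_out * n_h
  b2 <- theta[(i + 1L):(i + n_out)]

  H <- logsig(tcrossprod(X, w2) + matrix(b1, n, n_h, byrow = TRUE))
  Yhat <- tcrossprod(H, w1) + matrix(b2, n, n_out, byrow = TRUE)
  E <- Yhat - Y
  loss <- mean(E^2)
  if (!want_grad) return(list(loss = loss))
  dY <- 2 * E / (n * n_out)                 # n x n_out
  g_w1 <- crossprod(dY, H)                  # n_out x n_h
  g_b2 <- colSums(dY)
  dH <- (dY %*% w1) * H * (1 - H)           # n x n_h
  g_w2 <- crossprod(dH, X)                  # n_h x n_in
  g_b1 <- colSums(dH)
  grad <- c(as.vector(t(g_w2)), g_b1, as.vector(t(g_w1)), g_b2)
  list(loss = loss, grad = grad)
}

standardize_fit <- function(X, Y) {
  xs <- apply(X, 2, stats::sd); xs[xs == 0] <- 1
  ys <- apply(Y, 2, stats::sd); ys[ys == 0] <- 1
  list(x_center = colMeans(X), x_scale = xs,
       y_center = colMeans(Y), y_scale = ys)
}

standardize_apply <- function(M, center, scale) {
  sweep(sweep(M, 2, center, "-"), 2, scale, "/")
}

# --- trainer -------------------------------------------------------------

#' Train a network by backpropagation
#'
#' Full-batch training minimizing the training MSE under one of the five
#' update rules. Training stops at the epoch budget, when the gradient
#' falls below `grad_floor`, or when the validation MSE has not improved
#' for `patience` consecutive epochs; the weights with the best
#' validation MSE seen are returned (final weights when there is no
#' validation set). A non-finite loss aborts with a diagnostic.
#'
#' @param net A `network_model` whose input/output sizes match the split.
#' @param split A `data_split` (see [split_dataset()]).
#' @param config A [training_config()].
#' @return A list: `net` (trained model, carrying standardization),
#'   `history` (data.frame epoch/train_mse/val_mse/lr), `stopped`
#'   (reason), `best_train_mse`, `best_theta_train` (weights with lowest
#'   training MSE, flat).
#' @export
train_network <- function(net, split, config = training_config()) {
  if (net$n_in != ncol(split$X_train) || net$n_out != ncol(split$Y_train)) {
    stop("network dimensions do not match the data split")
  }
  if (config$max_epochs == 0L) {
    return(list(net = net,
                history = data.frame(epoch = integer(), train_mse = numeric(),
                                     val_mse = numeric(), lr = numeric()),
                stopped = "max_epochs", best_train_mse = NA_real_,
                best_theta_train = flatten_net(net)))
  }
  st <- net$standardization
  if (config$standardize && is.null(st)) {
    st <- standardize_fit(split$X_train, split$Y_train)
  }
  Xtr <- split$X_train; Ytr <- split$Y_train
  Xva <- split$X_val; Yva <- split$Y_val
  if (!is.null(st)) {
    Xtr <- standardize_apply(Xtr, st$x_center, st$x_scale)
    Ytr <- standardize_apply(Ytr, st$y_center, st$y_scale)
    if (nrow(Xva) > 0) {
      Xva <- standardize_apply(Xva, st$x_center, st$x_scale)
      Yva <- standardize_apply(Yva, st$y_center, st$y_scale)
    }
  }
  dims <- net_dims(net)
  theta <- flatten_net(net)
  np <- length(theta)
  has_val <- nrow(Xva) > 0

  lg <- nn_loss_grad(theta, Xtr, Ytr, dims)
  loss <- lg$loss; grad <- lg$grad
  lr <- config$learning_rate
  velocity <- numeric(np)
  rp_delta <- rep(config$rprop_delta0, np)
  rp_gprev <- numeric(np)
  cg_dir <- -grad; cg_gprev <- grad; cg_iter <- 0L; cg_alpha <- 1

  best_val <- Inf; best_theta <- theta; fail <- 0L
  best_train <- loss; best_theta_train <- theta
  hist_epoch <- integer(0); hist_train <- numeric(0)
  hist_val <- numeric(0); hist_lr <- numeric(0)
  stopped <- "max_epochs"

  for (epoch in seq_len(config$max_epochs)) {
    if (!is.finite(loss)) {
      stop(sprintf("training diverged at epoch %d (loss %s, algorithm %s)",
                   epoch, format(loss), config$algorithm))
    }
    if (max(abs(grad)) < config$grad_floor) { stopped <- "grad_floor"; break }

    if (config$algorithm == "GDBP") {
      theta <- theta - lr * grad
      lg <- nn_loss_grad(theta, Xtr, Ytr, dims)
      loss <- lg$loss; grad <- lg$grad
    } else if (config$algorithm == "MOBP") {
      velocity <- config$momentum * velocity - lr * grad
      theta <- theta + velocity
      lg <- nn_loss_grad(theta, Xtr, Ytr, dims)
      loss <- lg$loss; grad <- lg$grad
    } else if (config$algorithm == "VLN") {
      cand <- theta - lr * grad
      lg_new <- nn_loss_grad(cand, Xtr, Ytr, dims)
      if (lg_new$loss > config$vln_max_perf_inc * loss) {
        lr <- lr * config$vln_decrease        # reject step, shrink rate
      } else {
        if (lg_new$loss < loss) lr <- lr * config$vln_increase
        theta <- cand; loss <- lg_new$loss; grad <- lg_new$grad
      }
    } else if (config$algorithm == "RPROP") {
      s <- grad * rp_gprev
      rp_delta[s > 0] <- pmin(rp_delta[s > 0] * config$rprop_eta_plus,
                              config$rprop_delta_max)
      rp_delta[s < 0] <- pmax(rp_delta[s < 0] * config$rprop_eta_minus,
                              1e-9)
      g_eff <- grad
      g_eff[s < 0] <- 0                       # iRprop-: skip after sign flip
      theta <- theta - sign(g_eff) * rp_delta
      rp_gprev <- g_eff
      lg <- nn_loss_grad(theta, Xtr, Ytr, dims)
      loss <- lg$loss; grad <- lg$grad
    } else {                                  # CGBP, Fletcher-Reeves
      gd <- sum(grad * cg_dir)
      if (gd >= 0) { cg_dir <- -grad; gd <- sum(grad * cg_dir) }
      alpha <- max(cg_alpha * 2, 1e-8)
      accepted <- FALSE
      for (bt in 1:40) {
        cand <- theta + alpha * cg_dir
        l_new <- nn_loss_grad(cand, Xtr, Ytr, dims, want_grad = FALSE)$loss
        if (is.finite(l_new) && l_new <= loss + 1e-4 * alpha * gd) {
          accepted <- TRUE; break
        }
        alpha <- alpha / 2
      }
      if (accepted) {
        cg_alpha <- alpha
        theta <- theta + alpha * cg_dir
        lg <- nn_loss_grad(theta, Xtr, Ytr, dims)
        gnew <- lg$grad
        cg_iter <- cg_iter + 1L
        beta <- if (cg_iter %% np == 0L) 0 else
          sum(gnew^2) / max(sum(cg_gprev^2), .Machine$double.eps)
        cg_dir <- -gnew + beta * cg_dir
        cg_gprev <- gnew
        loss <- lg$loss; grad <- gnew
      } else {                                # restart steepest descent
        cg_dir <- -grad; cg_gprev <- grad; cg_alpha <- 1e-4; cg_iter <- 0L
      }
    }

    if (loss < best_train) { best_train <- loss; best_theta_train <- theta }

    val_loss <- NA_real_
    if (has_val) {
      val_loss <- nn_loss_grad(theta, Xva, Yva, dims, want_grad = FALSE)$loss
      if (val_loss < best_val) {
        best_val <- val_loss; best_theta <- theta; fail <- 0L
      } else {
        fail <- fail + 1L
        if (fail >= config$patience) {
          hist_epoch <- c(hist_epoch, epoch)
          hist_train <- c(hist_train, loss)
          hist_val <- c(hist_val, val_loss)
          hist_lr <- c(hist_lr, lr)
          stopped <- "patience"
          break
        }
      }
    }
    hist_epoch <- c(hist_epoch, epoch)
    hist_train <- c(hist_train, loss)
    hist_val <- c(hist_val, val_loss)
    hist_lr <- c(hist_lr, lr)
  }

  final_theta <- if (has_val) best_theta else theta
  out_net <- set_net_weights(net, final_theta)
  out_net$standardization <- st
  list(net = out_net,
       history = data.frame(epoch = hist_epoch, train_mse = hist_train,
                            val_mse = hist_val, lr = hist_lr),
       stopped = stopped,
       best_train_mse = best_train,
       best_theta_train = best_theta_train)
}

#' Evaluate a trained network on a data split
#'
#' @param net A trained `network_model`.
#' @param split A `data_split`.
#' @return List of `nn_metrics` for `train`, `validation` (NULL if
#'   empty) and `test`, computed on the original measurement scale.
#' @export
evaluate_network <- function(net, split) {
  list(
    train = nn_metrics(split$Y_train, forward(net, split$X_train)),
    validation = if (nrow(split$X_val) > 0)
      nn_metrics(split$Y_val, forward(net, split$X_val)) else NULL,
    test = nn_metrics(split$Y_test, forward(net, split$X_test))
  )
}
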