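# Particle swarm optimization over the flattened weight vector, and the
# PSO-seeded hybrid trainer.

#' PSO configuration
#'
#' Classical global-best PSO constants: swarm of 30, cognitive and social
#' accelerations of 2.0, inertia decaying linearly from 0.9 to 0.4 over
#' the run, velocities clamped to 20% of the search range, positions
#' reflected at the +/- 10 bounds.
#'
#' @param swarm_size Particles (default 30, >= 2).
#' @param inertia_start,inertia_end Linear inertia schedule (0.9 -> 0.4).
#' @param c1,c2 Cognitive and social acceleration (default 2.0 each).
#' @param velocity_clamp Max |velocity| as a fraction of the search range
#'   (default 0.2).
#' @param bound Symmetric position bound per coordinate (default 10).
#' @param init_range Symmetric range for the initial particle positions
#'   (default 1, velocities start in one tenth of it). For sigmoidal
#'   network weights the trainable region is small-scale; initializing
#'   the swarm there (while the wider bounds still act as hard
#'   constraints during the search) avoids starting every particle in
#'   saturated, flat-fitness territory.
#' @param max_iterations Iteration budget (default 200).
#' @param seed Integer seed.
#' @return A `pso_config` list.
#' @export
pso_config <- function(swarm_size = 30L, inertia_start = 0.9,
                       inertia_end = 0.4, c1 = 2, c2 = 2,
                       velocity_clamp = 0.2, bound = 10,
                       init_range = 1,
                       max_iterations = 200L, seed = 1L) {
  stopifnot(swarm_size >= 2, max_iterations >= 1, is.finite(bound),
            bound > 0, velocity_clamp > 0, init_range > 0,
            init_range <= bound)
  structure(list(swarm_size = as.integer(swarm_size),
                 inertia_start = inertia_start, inertia_end = inertia_end,
                 c1 = c1, c2 = c2, velocity_clamp = velocity_clamp,
                 bound = bound, init_range = init_range,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "pso_config")
}

#' Flatten / restore network weights
#'
#' Bijection between a `network_model`'s weights and a single numeric
#' vector, ordered w2 row-major, b1, w1 row-major, b2.
#'
#' @param net A `network_model`.
#' @return `flatten_weights` returns the numeric vector;
#'   `unflatten_weights` the network with weights replaced.
#' @export
#' @examples
#' net <- network_model(1, 1, 1)
#' length(flatten_weights(net))  # 4
flatten_weights <- function(net) flatten_net(net)

#' @rdname flatten_weights
#' @param theta Numeric vector of length
#'   `n_hidden * n_in + n_hidden + n_out * n_hidden + n_out`.
#' @export
unflatten_weights <- function(theta, net) set_net_weights(net, theta)

#' Particle swarm optimization
#'
#' Standard global-best PSO: velocities update as
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with per-coordinate
#' uniform r1, r2, velocity clamping, and reflection at the position
#' bounds. Non-finite objective values mark that evaluation infeasible
#' (fitness +Inf) and the run continues.
#'
#' @param objective Function: numeric vector -> scalar fitness
#'   (minimized).
#' @param dim Search-space dimension (>= 1).
#' @param config A [pso_config()].
#' @param init_positions Optional swarm_size x dim matrix of initial
#'   particle positions (e.g. to seed the swarm at a known point);
#'   default: uniform in +/- `init_range`.
#' @return A list: `best` (vector), `fitness`, `history` (best fitness
#'   per iteration, non-increasing), `iterations`.
#' @export
pso_optimize <- function(objective, dim, config = pso_config(),
                         init_positions = NULL) {
  stopifnot(dim >= 1)
  set.seed(config$seed)
  ns <- config$swarm_size
  lo <- -config$bound; hi <- config$bound
  vmax <- config$velocity_clamp * (hi - lo)
  ir <- config$init_range
  X <- if (is.null(init_positions)) {
    matrix(stats::runif(ns * dim, -ir, ir), ns, dim)
  } else {
    if (!all(dim(as.matrix(init_positions)) == c(ns, dim))) {
      stop("init_positions must be swarm_size x dim")
    }
    as.matrix(init_positions)
  }
  V <- matrix(stats::runif(ns * dim, -ir / 10, ir / 10), ns, dim)
  evaluate <- function(M) {
    vapply(seq_len(nrow(M)), function(i) {
      f <- objective(M[i, ])
      if (!is.finite(f)) Inf else f
    }, 0)
  }
  fit <- evaluate(X)
  P <- X; pfit <- fit
  g <- which.min(pfit)
  gbest <- P[g, ]; gfit <- pfit[g]
  history <- numeric(config$max_iterations)
  for (iter in seq_len(config$max_iterations)) {
    w <- config$inertia_start + (config$inertia_end - config$inertia_start) *
      (iter - 1) / max(config$max_iterations - 1, 1)
    r1 <- matrix(stats::runif(ns * dim), ns, dim)
    r2 <- matrix(stats::runif(ns * dim), ns, dim)
    V <- w * V + config$c1 * r1 * (P - X) +
      config$c2 * r2 * (matrix(gbest, ns, dim, byrow = TRUE) - X)
    V <- pmin(pmax(V, -vmax), vmax)
    X <- X + V
    over <- X > hi; under <- X < lo
    X[over] <- 2 * hi - X[over]; V[over] <- -V[over]
    X[under] <- 2 * lo - X[under]; V[under] <- -V[under]
    X <- pmin(pmax(X, lo), hi)              # guard pathological overshoot
    fit <- evaluate(X)
    improved <- fit < pfit
    P[improved, ] <- X[improved, ]
    pfit[improved] <- fit[improved]
    g <- which.min(pfit)
    if (pfit[g] < gfit) { gfit <- pfit[g]; gbest <- P[g, ] }
    history[iter] <- gfit
  }
  list(best = gbest, fitness = gfit, history = history,
       iterations = config$max_iterations)
}

#' Hybrid PSO-seeded backpropagation training
#'
#' Phase 1 runs PSO over the flattened weight vector, minimizing the
#' training MSE on the standardized scale (the global search). Phase 2
#' seeds gradient training from the swarm's global best (the local
#' refinement; variable-learning-rate backpropagation by default).
#' Refinement is accepted only if it improves the training MSE, so the
#' final training MSE never exceeds the phase-1 best.
#'
#' @param features A `feature_matrices` with the retained predictors.
#' @param n_hidden Hidden-layer size.
#' @param pso A [pso_config()].
#' @param refine A [training_config()] for phase 2, or `NULL` to skip
#'   refinement (pure PSO).
#' @param n_test,validation_fraction,split_method,seed Passed to
#'   [split_dataset()]; `seed` also drives the weight standardization
#'   draw.
#' @return A list: `net`, `metrics` (train/validation/test), `history`
#'   (data.frame phase/iteration/train_mse), `pso_fitness`,
#'   `refined` (logical: did phase 2 improve).
#' @export
pso_bp_train <- function(features, n_hidden = 12L,
                         pso = pso_config(),
                         refine = training_config(algorithm = "VLN"),
                         n_test = 100L, validation_fraction = 0.15,
                         split_method = "random", seed = 1L) {
  split <- split_dataset(features, n_test = n_test,
                         validation_fraction = validation_fraction,
                         method = split_method, seed = seed)
  n_in <- ncol(split$X_train); n_out <- ncol(split$Y_train)
  st <- standardize_fit(split$X_train, split$Y_train)
  Xtr <- standardize_apply(split$X_train, st$x_center, st$x_scale)
  Ytr <- standardize_apply(split$Y_train, st$y_center, st$y_scale)
  template <- network_model(n_in, n_hidden, n_out, seed = seed,
                            input_labels = colnames(split$X_train),
                            output_labels = colnames(split$Y_train))
  dims <- net_dims(template)
  objective <- function(theta) {
    nn_loss_grad(theta, Xtr, Ytr, dims, want_grad = FALSE)$loss
  }
  phase1 <- tryCatch(
    pso_optimize(objective, n_params(dims), pso),
    error = function(e) stop("PSO phase failed: ", conditionMessage(e)))
  net <- set_net_weights(template, phase1$best)
  net$standardization <- st
  best_mse <- phase1$fitness
  history <- data.frame(phase = "pso",
                        iteration = seq_along(phase1$history),
                        train_mse = phase1$history,
                        stringsAsFactors = FALSE)
  refined <- FALSE
  if (!is.null(refine)) {
    fit <- tryCatch(train_network(net, split, refine),
                    error = function(e) stop("refinement phase failed: ",
                                             conditionMessage(e)))
    if (nrow(fit$history) > 0) {
      history <- rbind(history, data.frame(
        phase = refine$algorithm,
        iteration = fit$history$epoch,
        train_mse = fit$history$train_mse,
        stringsAsFactors = FALSE))
    }
    # accept refinement only on improvement of the training objective
    if (is.finite(fit$best_train_mse) && fit$best_train_mse < best_mse) {
      cand <- set_net_weights(template, fit$best_theta_train)
      cand$standardization <- st
      # prefer the early-stopped (best-validation) weights when they also
      # improve on phase 1; fall back to the best-training weights
      val_theta_mse <- nn_loss_grad(flatten_net(fit$net), Xtr, Ytr, dims,
                                    want_grad = FALSE)$loss
      if (val_theta_mse < best_mse) {
        net <- fit$net; best_mse <- val_theta_mse
      } else {
        net <- cand; best_mse <- fit$best_train_mse
      }
      refined <- TRUE
    }
  }
  list(net = net,
       metrics = evaluate_network(net, split),
       history = history,
       pso_fitness = phase1$fitness,
       train_mse = best_mse,
       refined = refined,
       split = split)
}

#' Write an optimization history for convergence plots
#'
#' @param history Data.frame as returned in `pso_bp_train()$history` or
#'   a numeric vector of per-iteration best fitness.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  if (is.numeric(history)) {
    history <- data.frame(iteration = seq_along(history),
                          fitness = history)
  }
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
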