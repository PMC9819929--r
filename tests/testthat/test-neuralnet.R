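test_that("hidden-size rule reproduces the published 6..15 grid", {
  expect_equal(hidden_size_candidates(8, 12, 1:10), 6:15)
  expect_equal(hidden_size_candidates(8, 12, 1), 6L)
  expect_equal(hidden_size_candidates(2, 2, 1:3), c(3L, 4L, 5L))
  expect_error(hidden_size_candidates(8, 12, integer(0)), "nonempty")
  expect_error(hidden_size_candidates(0, 12), "positive")
})

test_that("logsig is a proper sigmoid", {
  expect_equal(logsig(0), 0.5)
  y <- seq(-20, 20, by = 0.37)
  expect_true(all(logsig(y) > 0 & logsig(y) < 1))
  expect_equal(logsig(-y), 1 - logsig(y), tolerance = 1e-15)
})

test_that("forward computes the closed-form prediction", {
  net <- network_model(3, 4, 2, seed = 1)
  net$w2[] <- 0; net$b1[] <- 0; net$w1[] <- 0; net$b2 <- c(1, 1)
  expect_equal(unname(forward(net, c(5, -3, 2))), c(1, 1))

  one <- network_model(1, 1, 1, seed = 1)
  one$w2[] <- 1; one$b1 <- 0; one$w1[] <- 2; one$b2 <- 1
  expect_equal(unname(forward(one, 0)), 2)    # 2 * logsig(0) + 1

  expect_error(forward(net, c(1, 2)), "expects 3")
})

test_that("forward with the reference weight tables matches a matrix oracle", {
  net <- load_weight_tables()
  expect_equal(c(net$n_in, net$n_hidden, net$n_out), c(8L, 11L, 12L))

  t5 <- as.matrix(utils::read.csv(bk_fixture("table5_weights.csv")))
  t6 <- as.matrix(utils::read.csv(bk_fixture("table6_weights.csv")))
  set.seed(17)
  for (i in 1:5) {
    x <- runif(8, 10, 100)
    h <- 1 / (1 + exp(-(t5[, 1:8] %*% x + t5[, 9])))
    oracle <- drop(t6[, 1:11] %*% h + t6[, 12])
    expect_equal(unname(forward(net, x)), unname(oracle), tolerance = 1e-10)
  }
})

test_that("the weight loader surfaces the hidden-size discrepancy", {
  # the reference tables are self-consistent at 11 hidden units although
  # the selected network was described as having 12
  expect_error(load_weight_tables(expected_hidden = 12), "11.*12|12.*11")
  expect_warning(net <- load_weight_tables(expected_hidden = 12,
                                           override = TRUE), "11")
  expect_equal(net$n_hidden, 11L)
})

test_that("hand-built 2-2-1 weight tables forward as computed by hand", {
  p5 <- withr::local_tempfile(fileext = ".csv")
  p6 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("w_1,w_2,bias", "1,0,0", "0,1,0"), p5)
  writeLines(c("w_1,w_2,bias", "1,1,0.5"), p6)
  net <- load_weight_tables(p5, p6)
  x <- c(0, 0)
  expect_equal(unname(forward(net, x)), 0.5 + 0.5 + 0.5)  # two logsig(0) + bias
})

test_that("models round-trip through the structured-text file", {
  net <- network_model(4, 6, 3, seed = 8,
                       input_labels = paste0("in", 1:4),
                       output_labels = paste0("out", 1:3))
  net$standardization <- list(x_center = rep(1, 4), x_scale = rep(2, 4),
                              y_center = rep(0, 3), y_scale = rep(3, 3))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(net, path)
  back <- load_model(path)
  set.seed(3)
  X <- matrix(rnorm(400), 100, 4)
  expect_equal(forward(back, X), forward(net, X), tolerance = 1e-12)
})

test_that("metrics reproduce hand computations and algebraic identities", {
  perfect <- nn_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$mape, 0)

  m <- nn_metrics(c(1, 2, 3), c(1, 3, 2))
  expect_equal(m$mse, 2 / 3)
  expect_equal(m$mape, 100 * (0 + 1 / 2 + 1 / 3) / 3)
  expect_equal(m$r, 0.5)

  set.seed(19)
  a <- rnorm(40, 10); p <- a + rnorm(40, sd = 0.5)
  base <- nn_metrics(a, p)
  scaled <- nn_metrics(10 * a, 10 * p)
  expect_equal(scaled$r, base$r, tolerance = 1e-12)
  expect_equal(scaled$mse, 100 * base$mse, tolerance = 1e-12)
  expect_equal(scaled$mape, base$mape, tolerance = 1e-12)
  # cross-check against the reference correlation implementation
  expect_equal(base$r, cor(a, p), tolerance = 1e-10)

  expect_true(is.na(nn_metrics(c(1, 2), c(5, 5))$r))
  expect_warning(out <- nn_metrics(c(0, 1, 2), c(0, 1, 2)), "excluded")
  expect_equal(out$mape_excluded, 1)
})

test_that("dataset splits honour sizes, conventions and determinism", {
  fm <- feature_matrices(matrix(seq_len(4400 * 2), 4400, 2),
                         matrix(runif(4400), 4400, 1))
  sp <- split_dataset(fm, n_test = 100, seed = 4)
  expect_length(sp$test_idx, 100)
  expect_equal(length(sp$train_idx) + length(sp$val_idx), 4300)
  expect_equal(length(sp$val_idx), floor(4300 * 0.15))

  sp2 <- split_dataset(fm, n_test = 100, seed = 4)
  expect_identical(sp$test_idx, sp2$test_idx)
  expect_identical(sp$train_idx, sp2$train_idx)

  small <- feature_matrices(matrix(1:10, 10, 1), matrix(1:10, 10, 1))
  seq_sp <- split_dataset(small, n_test = 2, validation_fraction = 0,
                          method = "sequential")
  expect_equal(seq_sp$test_idx, c(9L, 10L))

  expect_error(split_dataset(small, n_test = 10), "smaller")
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(99)
  X <- matrix(rnorm(30), 10, 3)
  Y <- matrix(rnorm(20), 10, 2)
  net <- network_model(3, 5, 2, seed = 5)
  theta <- flatten_weights(net)
  dims <- c(3L, 5L, 2L)
  lg <- breastkin:::nn_loss_grad(theta, X, Y, dims)
  h <- 1e-6
  fd <- vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (breastkin:::nn_loss_grad(tp, X, Y, dims, FALSE)$loss -
       breastkin:::nn_loss_grad(tm, X, Y, dims, FALSE)$loss) / (2 * h)
  }, 0)
  expect_lt(max(abs(fd - lg$grad)), 1e-6)
})

test_that("a zero-epoch budget returns the network unchanged", {
  fm <- make_teacher_dataset(60, 1, n_in = 3, n_hidden = 4, n_out = 2)
  sp <- split_dataset(fm, n_test = 10, seed = 1)
  net <- network_model(3, 4, 2, seed = 2)
  fit <- train_network(net, sp, training_config(max_epochs = 0))
  expect_identical(fit$net, net)
  expect_equal(nrow(fit$history), 0)
})

test_that("gradient descent with a small rate never increases the loss", {
  fm <- make_teacher_dataset(120, 3, n_in = 4, n_hidden = 5, n_out = 3)
  sp <- split_dataset(fm, n_test = 20, validation_fraction = 0, seed = 3)
  fit <- train_network(network_model(4, 5, 3, seed = 4), sp,
                       training_config(algorithm = "GDBP",
                                       learning_rate = 0.05,
                                       max_epochs = 300))
  expect_true(all(diff(fit$history$train_mse) <= 1e-12))
})

test_that("every algorithm recovers a noiseless teacher to under 1% of initial loss", {
  fm <- make_teacher_dataset(200, 1)
  sp <- split_dataset(fm, n_test = 50, validation_fraction = 0, seed = 1)
  st <- breastkin:::standardize_fit(sp$X_train, sp$Y_train)
  Xtr <- breastkin:::standardize_apply(sp$X_train, st$x_center, st$x_scale)
  Ytr <- breastkin:::standardize_apply(sp$Y_train, st$y_center, st$y_scale)
  init <- breastkin:::nn_loss_grad(
    flatten_weights(network_model(8, 12, 12, seed = 3)),
    Xtr, Ytr, c(8L, 12L, 12L), FALSE)$loss
  rates <- c(GDBP = 2, MOBP = 0.2, VLN = 0.05, RPROP = 0.01, CGBP = 0.01)
  for (alg in names(rates)) {
    fit <- train_network(network_model(8, 12, 12, seed = 3), sp,
                         training_config(algorithm = alg,
                                         learning_rate = rates[[alg]],
                                         max_epochs = 1000))
    expect_lt(min(fit$history$train_mse) / init, 0.01)
    m <- evaluate_network(fit$net, sp)
    expect_gt(m$test$r, 0.99)
  }
})

test_that("training aborts with a diagnostic when it diverges", {
  fm <- make_teacher_dataset(60, 2, n_in = 3, n_hidden = 4, n_out = 2)
  sp <- split_dataset(fm, n_test = 10, validation_fraction = 0, seed = 2)
  expect_error(
    train_network(network_model(3, 4, 2, seed = 1), sp,
                  training_config(algorithm = "GDBP", learning_rate = 1e4,
                                  max_epochs = 50)),
    "diverged")
})

test_that("a 1x1 sweep equals a direct train-and-evaluate", {
  fm <- make_teacher_dataset(150, 5, n_in = 4, n_hidden = 6, n_out = 3)
  cfg <- training_config(algorithm = "RPROP", max_epochs = 120)
  sw <- sweep_networks(fm, sizes = 6, algorithms = "RPROP", config = cfg,
                       n_test = 30, seed = 9)
  expect_equal(nrow(sw$grid), 1)

  sp <- split_dataset(fm, n_test = 30, seed = 9)
  net <- network_model(4, 6, 3, seed = 10,
                       input_labels = colnames(sp$X_train),
                       output_labels = colnames(sp$Y_train))
  fit <- train_network(net, sp, cfg)
  m <- nn_metrics(sp$Y_test, forward(fit$net, sp$X_test))
  expect_equal(sw$grid$mape, m$mape, tolerance = 1e-12)
  expect_equal(sw$grid$r, m$r, tolerance = 1e-12)
})

test_that("the sweep grid covers every cell and tracks its argmin", {
  fm <- make_teacher_dataset(150, 6, n_in = 4, n_hidden = 6, n_out = 3)
  sw <- sweep_networks(fm, sizes = c(4, 6), algorithms = c("VLN", "RPROP"),
                       config = training_config(max_epochs = 120),
                       n_test = 30, seed = 2)
  expect_equal(nrow(sw$grid), 4)
  expect_equal(sw$grid$network, paste0("N", 1:4))
  expect_equal(sw$grid$hidden_size, c(4, 4, 6, 6))
  expect_true(all(sw$grid$status == "ok"))
  expect_equal(sw$best$mape, min(sw$grid$mape))
  expect_lte(sw$best$mape, median(sw$grid$mape))
  expect_equal(sw$best_model$n_hidden, sw$best$hidden_size)

  wide <- sweep_grid_table(sw)
  expect_equal(wide$hidden_size, c(4, 6))
  expect_equal(names(wide), c("hidden_size", "VLN", "RPROP"))
})
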