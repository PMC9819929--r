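test_that("normalization dialects behave as documented", {
  m <- cbind(a = c(5, 5, 5), b = c(1, 2, 3))
  expect_equal(normalize_sequences(m, "mean")[, "a"], rep(1, 3),
               ignore_attr = TRUE)
  expect_equal(normalize_sequences(m, "minmax")[, "b"], c(0, 0.5, 1),
               ignore_attr = TRUE)
  expect_identical(normalize_sequences(m, "none"), m)
  expect_equal(normalize_sequences(m, "initial")[, "b"], c(1, 2, 3),
               ignore_attr = TRUE)

  set.seed(3)
  r <- matrix(runif(60, 1, 9), 20, 3)
  expect_equal(colMeans(normalize_sequences(r, "mean")), rep(1, 3),
               tolerance = 1e-12, ignore_attr = TRUE)

  z <- cbind(bad = c(-1, 1), ok = c(1, 2))
  expect_error(normalize_sequences(z, "mean"), "bad")
  expect_error(normalize_sequences(cbind(bad = c(0, 1)), "initial"), "bad")
})

test_that("relational coefficients match the hand oracle and bounds", {
  # identical sequences: all coefficients exactly 1
  expect_equal(unname(drop(relational_coefficients(c(2, 4, 6), c(2, 4, 6)))),
               rep(1, 3))

  # hand oracle: deltas (2, 0, 2), dmin 0, dmax 2, rho 0.5
  xi <- relational_coefficients(c(1, 2, 3), c(3, 2, 1))
  expect_equal(unname(drop(xi)), c(1 / 3, 1, 1 / 3))
  expect_equal(correlation_grade(xi), 5 / 9)

  # with dmin = 0 all coefficients lie in [rho / (1 + rho), 1]
  set.seed(7)
  for (i in 1:20) {
    ref <- runif(15)
    comp <- matrix(runif(45), 15, 3)
    k <- sample(15, 1); j <- sample(3, 1)
    comp[k, j] <- ref[k]                 # force a zero delta
    rho <- runif(1, 0.05, 1)
    xi <- relational_coefficients(ref, comp, gra_config(rho = rho))
    expect_true(all(xi >= rho / (1 + rho) - 1e-12 & xi <= 1 + 1e-12))
  }

  expect_error(relational_coefficients(1:3, matrix(1, 4, 2)), "length")
})

test_that("coefficients increase strictly with rho where delta is positive", {
  ref <- c(1, 2, 3, 4)
  comp <- c(1, 3, 2, 4)                  # dmin = 0 at two samples
  lo <- relational_coefficients(ref, comp, gra_config(rho = 0.3))
  hi <- relational_coefficients(ref, comp, gra_config(rho = 0.8))
  pos <- abs(comp - ref) > 0
  expect_true(all(hi[pos] > lo[pos]))
  expect_equal(hi[!pos], lo[!pos])
})

test_that("correlation grade is the sample mean of coefficients", {
  expect_equal(correlation_grade(c(1 / 3, 1, 1 / 3)), 5 / 9)
  expect_equal(correlation_grade(rep(1, 9)), 1)
  expect_equal(correlation_grade(0.4), 0.4)
  expect_error(correlation_grade(numeric(0)), "empty")
})

test_that("grade matrix equals the naive double-loop oracle", {
  set.seed(21)
  for (dims in list(c(5, 4, 3), c(50, 3, 2))) {
    A <- matrix(runif(dims[1] * dims[2], 1, 10), dims[1], dims[2])
    B <- matrix(runif(dims[1] * dims[3], 1, 10), dims[1], dims[3])
    for (nm in c("minmax", "mean", "none")) {
      got <- grade_matrix(A, B, gra_config(normalization = nm))
      expect_equal(unclass(got)[seq_len(dims[2]), ],
                   naive_grade_matrix(A, B, 0.5, nm),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("an output copied from an input earns grade 1 on that row", {
  set.seed(2)
  A <- matrix(runif(40, 1, 5), 20, 2)
  B <- cbind(A[, 1], runif(20, 1, 5))
  g <- grade_matrix(A, B)
  expect_equal(unclass(g)[1, 1], 1)
  expect_true(all(unclass(g) > 0 & unclass(g) <= 1))
})

test_that("grades under mean normalization are scale invariant", {
  set.seed(13)
  A <- matrix(runif(60, 1, 9), 20, 3)
  B <- matrix(runif(40, 1, 9), 20, 2)
  g1 <- grade_matrix(A, B, gra_config(normalization = "mean"))
  A2 <- A; A2[, 2] <- A2[, 2] * 37.5
  B2 <- B; B2[, 1] <- B2[, 1] * 0.004
  g2 <- grade_matrix(A2, B2, gra_config(normalization = "mean"))
  expect_equal(unclass(g1), unclass(g2), tolerance = 1e-12)
})

test_that("selection on the published grade table retains the eight variables", {
  g <- load_grade_matrix()
  expect_equal(dim(g), c(14, 12))
  sel <- select_variables(g, threshold = 0.49)
  expect_setequal(sel$selected,
                  c("underbust_girth", "breast_circumference",
                    "left_across_cup", "shoulder_to_lbn", "npsn_to_lbn",
                    "lbn_to_rbn", "left_shoulder_angle", "abduction_angle"))
  expect_equal(sel$ranking$variable[1], "abduction_angle")
})

test_that("selection tie-breaks and overrides are canonical", {
  flat <- matrix(0.5, 4, 3,
                 dimnames = list(c("v1", "v2", "v3", "v4"), NULL))
  flat <- structure(flat, mean_grade = rowMeans(flat),
                    class = c("grade_matrix", "matrix"))
  sel <- select_variables(flat, k = 3)
  expect_equal(sel$selected, c("v1", "v2", "v3"))

  set.seed(31)
  rnd <- matrix(runif(48), 12, 4,
                dimnames = list(paste0("x", 1:12), NULL))
  rnd <- structure(rnd, mean_grade = rowMeans(rnd),
                   class = c("grade_matrix", "matrix"))
  sel2 <- select_variables(rnd, threshold = 0)
  oracle <- rownames(rnd)[order(-rowMeans(rnd))]
  expect_equal(sel2$ranking$variable, oracle)

  none <- select_variables(rnd, threshold = 1.1)
  expect_length(none$selected, 0)
})

test_that("grade matrices round-trip through the labelled table format", {
  g <- load_grade_matrix()
  path <- withr::local_tempfile(fileext = ".csv")
  write_grade_matrix(g, path)
  again <- load_grade_matrix(path)
  expect_equal(unclass(again), unclass(g), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rownames(again), rownames(g))
})
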