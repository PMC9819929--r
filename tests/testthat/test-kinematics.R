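test_that("abduction angle follows the vertical-reference convention", {
  expect_equal(abduction_angle(c(0, 0, 0), c(0, 0, 10)), 0)
  expect_equal(abduction_angle(c(0, 0, 0), c(3, 4, 0)), 90)
  # dot-product oracle against the +z axis
  d <- c(1, 0, 1)
  oracle <- acos(sum(d * c(0, 0, 1)) / sqrt(sum(d^2))) * 180 / pi
  expect_equal(abduction_angle(c(0, 0, 0), d), oracle)
  expect_equal(abduction_angle(c(0, 0, 0), d), 45)

  expect_equal(abduction_angle(c(0, 0, 0), c(0, 0, 10),
                               convention = "horizontal-reference"), 90)
  expect_equal(abduction_angle(c(0, 0, 0), c(3, 4, 0),
                               convention = "horizontal-reference"), 0)
  expect_error(abduction_angle(c(1, 2, 3), c(1, 2, 3)), "coincident")
})

test_that("abduction angle is invariant to vertical-axis rotation and translation", {
  set.seed(5)
  for (i in 1:10) {
    O <- rnorm(3, sd = 100); A <- O + rnorm(3, sd = 50)
    base <- abduction_angle(O, A)
    phi <- runif(1, 0, 2 * pi)
    Rz <- matrix(c(cos(phi), sin(phi), 0, -sin(phi), cos(phi), 0, 0, 0, 1),
                 3, 3)
    shift <- rnorm(3, sd = 500)
    expect_equal(abduction_angle(drop(Rz %*% O) + shift,
                                 drop(Rz %*% A) + shift),
                 base, tolerance = 1e-9)
  }
})

test_that("line lengths are Euclidean distances in canonical order", {
  defs <- line_definitions()
  expect_equal(nrow(defs), 12)
  expect_equal(defs$name[11], "MID4-MID3")

  labels <- unique(c(defs$from, defs$to))
  pos <- matrix(0, length(labels), 3, dimnames = list(labels, NULL))
  expect_equal(unname(line_lengths(pos)), rep(0, 12))

  pos2 <- pos
  pos2["UP1", ] <- c(3, 4, 12)                   # Pythagorean quadruple
  expect_equal(line_lengths(pos2)[["LBN-UP1"]], 13)

  set.seed(9)
  pos3 <- matrix(rnorm(length(labels) * 3, sd = 40), length(labels), 3,
                 dimnames = list(labels, NULL))
  got <- line_lengths(pos3)
  oracle <- vapply(seq_len(12), function(i)
    sqrt(sum((pos3[defs$to[i], ] - pos3[defs$from[i], ])^2)), 0)
  expect_equal(unname(got), oracle, tolerance = 1e-12)

  expect_error(line_lengths(pos3[-1, , drop = FALSE]), "LBN")
})

test_that("line lengths are rigid-motion invariant", {
  defs <- line_definitions()
  labels <- unique(c(defs$from, defs$to))
  set.seed(11)
  pos <- matrix(rnorm(length(labels) * 3, sd = 40), length(labels), 3,
                dimnames = list(labels, NULL))
  base <- line_lengths(pos)
  ang <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                 0, -sin(ang[1]), cos(ang[1])), 3, 3)
  Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0,
                 -sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, 3)
  moved <- t(Rz %*% Rx %*% t(pos)) +
    matrix(rnorm(3, sd = 300), length(labels), 3, byrow = TRUE)
  rownames(moved) <- labels
  expect_equal(line_lengths(moved), base, tolerance = 1e-9)
})

test_that("feature assembly produces canonical matrices with provenance", {
  profs <- consistent_cohort(2)
  cfg <- generator_config(n_subjects = 2, frames_per_trial = 3)
  trials <- lapply(1:2, function(i) simulate_trial(profs[i, ], cfg, seed = i))
  fm <- assemble_features(trials, profs)
  expect_equal(dim(fm$A), c(6, 14))
  expect_equal(dim(fm$B), c(6, 12))
  expect_equal(fm$provenance$subject_id, rep(c("C01", "C02"), each = 3))
  expect_equal(fm$provenance$frame, rep(1:3, 2))
  # inputs 1-13 constant within a subject, copied from the profile
  expect_equal(unname(fm$A[1, "weight"]), profs$weight_kg[1])
  expect_equal(unname(fm$A[4, "bra_cup"]), match("D", LETTERS))

  # permutation invariance: shuffled trials give identical matrices
  fm2 <- assemble_features(rev(trials), profs)
  expect_identical(fm$A, fm2$A)
  expect_identical(fm$B, fm2$B)

  expect_error(assemble_features(trials, profs[1, ]), "C02")
})

test_that("trajectories round-trip through the long text format", {
  prof <- consistent_cohort(1)
  cfg <- generator_config(n_subjects = 1, frames_per_trial = 4)
  tr <- simulate_trial(prof, cfg, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$subject_id, "C01")
  expect_equal(dim(back$markers), dim(tr$markers))
  expect_equal(back$markers[, dimnames(tr$markers)[[2]], ],
               tr$markers, tolerance = 1e-6)
  # 90 Hz sampling: time increments of 1/90 s
  expect_equal(diff(back$time_s), rep(1 / 90, 3), tolerance = 1e-8)

  df <- utils::read.csv(path)
  df$z_mm <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_trajectory(path), "z_mm")
})

test_that("strain transform is zero at baseline and dimensionless", {
  B <- cbind(c(10, 11, 12), c(20, 20, 22))
  s <- line_strain(B)
  expect_equal(s[1, ], c(0, 0))
  expect_equal(s[3, ], c(0.2, 0.1))
  expect_error(line_strain(cbind(c(0, 1))), "zero")
})
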