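# Shared test helpers: teacher-student data and a naive GRA oracle.

# Noiseless teacher-student dataset: inputs N(0,1), outputs from a fixed
# random teacher network, shifted away from zero so MAPE is defined.
make_teacher_dataset <- function(n, seed, n_in = 8, n_hidden = 12,
                                 n_out = 12, shift = 5) {
  set.seed(seed)
  X <- matrix(rnorm(n * n_in), n, n_in)
  teacher <- network_model(n_in, n_hidden, n_out, seed = seed + 500)
  feature_matrices(X, forward(teacher, X) + shift)
}

# Brute-force double-loop gray relational grade matrix (independent of the
# vectorized implementation): normalize columns, then per (j, i) pair
# compute coefficients with the two-level extrema over all comparatives.
naive_grade_matrix <- function(A, B, rho = 0.5, normalization = "minmax") {
  norm_col <- function(col) {
    switch(normalization,
           minmax = {
             r <- range(col)
             if (r[1] == r[2]) rep(0, length(col))
             else (col - r[1]) / (r[2] - r[1])
           },
           mean = col / mean(col),
           initial = col / col[1],
           none = col)
  }
  An <- apply(A, 2, norm_col)
  Bn <- apply(B, 2, norm_col)
  out <- matrix(NA_real_, ncol(A), ncol(B))
  for (j in seq_len(ncol(A))) {
    deltas <- matrix(NA_real_, nrow(A), ncol(B))
    for (i in seq_len(ncol(B))) deltas[, i] <- abs(An[, j] - Bn[, i])
    dmin <- min(deltas); dmax <- max(deltas)
    for (i in seq_len(ncol(B))) {
      xi <- if (dmax == 0) rep(1, nrow(A))
            else (dmin + rho * dmax) / (deltas[, i] + rho * dmax)
      out[j, i] <- mean(xi)
    }
  }
  out
}

# small internally consistent cohort for validation tests
consistent_cohort <- function(n = 3) {
  h <- c(155, 160, 150)[seq_len(n)]
  w <- c(60, 65, 55)[seq_len(n)]
  structure(data.frame(
    subject_id = sprintf("C%02d", seq_len(n)),
    age = c(60, 65, 58)[seq_len(n)],
    height_cm = h, weight_kg = w,
    bmi = round(w / (h / 100)^2, 1),
    cup_size = c("C", "D", "E")[seq_len(n)],
    underbust_girth_cm = c(78, 82, 76)[seq_len(n)],
    breast_circumference_cm = c(92, 97, 90)[seq_len(n)],
    left_across_cup_cm = c(20, 22, 19)[seq_len(n)],
    shoulder_to_lbn_cm = c(25, 26, 24)[seq_len(n)],
    npsn_to_lbn_cm = c(21, 22, 20)[seq_len(n)],
    lbn_to_rbn_cm = c(17, 18, 16)[seq_len(n)],
    left_shoulder_angle_deg = c(28, 30, 27)[seq_len(n)],
    stringsAsFactors = FALSE
  ), class = c("subject_profiles", "data.frame"))
}
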