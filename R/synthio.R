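# Seeded synthetic cohorts and abduction trials.
#
# The generator emulates the study conditions the downstream stages were
# designed for: 22 subjects, 200 frames each at 90 Hz (4400 frames total),
# a smooth monotone abduction ramp from 10 to 150 degrees followed by a
# hold, and twelve breast-line lengths that respond linearly to the
# abduction angle with per-line sensitivities, strongest on the mid/inner
# lines, plus millimetre-scale Gaussian measurement noise.

BK_DEFAULT_SENSITIVITY <- c(
  "LBN-UP1" = 0.15, "UP1-UP2" = 0.15, "UP2-UP3" = 0.15,
  "LBN-OUT1" = 0.15, "OUT1-OUT2" = 0.15, "OUT2-OUT3" = 0.15,
  "LBN-IN1" = 0.25, "IN1-IN2" = 0.25, "IN2-MID" = 0.22,
  "LBN-MID4" = 0.25, "MID4-MID3" = 0.30, "MID3-UP2" = 0.15
)

#' Synthetic-trial generator configuration
#'
#' Defaults reproduce the study conditions: 22 subjects x 200 frames at
#' 90 Hz (4400 frames), abduction ramp 10 -> 150 degrees with the final
#' quarter of the trial held at the peak, per-line sensitivities with the
#' mid/inner lines most responsive, and 0.5 mm Gaussian noise.
#'
#' @param n_subjects Cohort size (default 22).
#' @param frames_per_trial Frames per subject (default 200).
#' @param sampling_rate Hz (default 90).
#' @param theta_start,theta_end Abduction ramp endpoints, degrees
#'   (defaults 10, 150).
#' @param hold_fraction Fraction of frames held at the peak (default 0.25).
#' @param line_sensitivity Named vector of 12 unitless slopes s_k; the
#'   fractional length increase of line k over the full ramp.
#' @param noise_sd Measurement noise on each line length, mm (default 0.5).
#' @param covariate_coupling Unitless weight linking baseline line lengths
#'   to across-cup and breast circumference (default 0.1: a few percent of
#'   baseline geometry tracks anthropometry, keeping the abduction ramp
#'   the dominant source of within-dataset line-length variation).
#' @param seed Integer seed; all sampling is deterministic given it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_subjects = 22L,
                             frames_per_trial = 200L,
                             sampling_rate = 90,
                             theta_start = 10,
                             theta_end = 150,
                             hold_fraction = 0.25,
                             line_sensitivity = BK_DEFAULT_SENSITIVITY,
                             noise_sd = 0.5,
                             covariate_coupling = 0.1,
                             seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (frames_per_trial < 2) stop("frames_per_trial must be >= 2")
  if (theta_end <= theta_start) stop("theta_end must exceed theta_start")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (hold_fraction < 0 || hold_fraction >= 1) stop("hold_fraction in [0, 1)")
  ls <- rep_len(line_sensitivity, 12)
  if (is.null(names(line_sensitivity))) names(ls) <- BK_OUTPUT_LINES
  else ls <- line_sensitivity[BK_OUTPUT_LINES]
  if (anyNA(ls)) stop("line_sensitivity must name all 12 canonical lines")
  structure(list(
    n_subjects = as.integer(n_subjects),
    frames_per_trial = as.integer(frames_per_trial),
    sampling_rate = sampling_rate,
    theta_start = theta_start, theta_end = theta_end,
    hold_fraction = hold_fraction,
    line_sensitivity = ls,
    noise_sd = noise_sd,
    covariate_coupling = covariate_coupling,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Truncated-normal draw by rejection; bounds from the reference cohort.
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Sample a synthetic cohort
#'
#' Draws each anthropometric variable from a truncated normal matched to
#' the shipped reference cohort's mean, sd, min and max; cup grades are
#' drawn from the reference frequencies; BMI is recomputed from the drawn
#' height and weight (synthetic cohorts are internally consistent).
#'
#' @param config A [generator_config()].
#' @return A `subject_profiles` data.frame with `n_subjects` rows.
#' @export
sample_subjects <- function(config = generator_config()) {
  ref <- load_subjects(bk_fixture("table1_subjects.csv"))
  set.seed(config$seed)
  n <- config$n_subjects
  draw <- function(col, digits = 1) {
    s <- summary_stats(ref, col)
    round(rtruncnorm1(n, s$mean, s$sd, s$min, s$max), digits)
  }
  age <- draw("age", 0)
  height <- draw("height_cm", 0)
  weight <- draw("weight_kg", 1)
  out <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    age = age, height_cm = height, weight_kg = weight,
    bmi = round(bmi(weight, height), 1),
    cup_size = sample(ref$cup_size, n, replace = TRUE),
    underbust_girth_cm = draw("underbust_girth_cm"),
    breast_circumference_cm = draw("breast_circumference_cm"),
    left_across_cup_cm = draw("left_across_cup_cm"),
    shoulder_to_lbn_cm = draw("shoulder_to_lbn_cm"),
    npsn_to_lbn_cm = draw("npsn_to_lbn_cm"),
    lbn_to_rbn_cm = draw("lbn_to_rbn_cm"),
    left_shoulder_angle_deg = draw("left_shoulder_angle_deg"),
    stringsAsFactors = FALSE
  )
  # keep the girth ordering invariant: circumference strictly above underbust
  swap <- out$breast_circumference_cm <= out$underbust_girth_cm
  out$breast_circumference_cm[swap] <- out$underbust_girth_cm[swap] + 10
  structure(out, class = c("subject_profiles", "data.frame"))
}

# smoothstep ramp + hold: angle per frame, non-decreasing
abduction_profile <- function(config) {
  n <- config$frames_per_trial
  n_hold <- floor(n * config$hold_fraction)
  n_ramp <- n - n_hold
  t <- if (n_ramp > 1) (seq_len(n_ramp) - 1) / (n_ramp - 1) else 1
  s <- 3 * t^2 - 2 * t^3
  theta <- config$theta_start + (config$theta_end - config$theta_start) * s
  c(theta, rep(config$theta_end, n_hold))
}

# Fixed chain directions from LBN (unit vectors). The UP and MID chains are
# orthogonal so the cross-chain line MID3-UP2 grows monotonically with both.
BK_CHAIN_DIRS <- list(
  UP = c(0, 0, 1),
  OUT = c(-0.9411, 0.2353, 0.2425),
  IN = c(0.9701, 0.2425, 0),
  MID = c(1, 0, 0)
)

# Baseline (theta = theta_start) length of each chain segment, mm. Affine in
# across-cup and breast circumference around the reference cohort centre.
baseline_lengths <- function(profile, coupling) {
  base <- c(
    "LBN-UP1" = 90, "UP1-UP2" = 30, "UP2-UP3" = 30,
    "LBN-OUT1" = 90, "OUT1-OUT2" = 30, "OUT2-OUT3" = 30,
    "LBN-IN1" = 30, "IN1-IN2" = 30, "IN2-MID" = 30,
    "LBN-MID4" = 60, "MID4-MID3" = 30, "MID3-UP2" = 30
  )
  scale <- 1 + coupling * ((profile$left_across_cup_cm - 20.9) / 20.9 +
                             (profile$breast_circumference_cm - 95) / 95) / 2
  base * scale
}

#' Simulate one abduction trial
#'
#' The abduction angle follows a smoothstep ramp from `theta_start` to
#' `theta_end`, then holds. Each chain-segment line k has length
#' `L0_k * (1 + s_k * (theta - theta_start) / (theta_end - theta_start))`
#' plus Gaussian noise; `L0_k` is an affine function of the subject's
#' across-cup and breast circumference. Markers are laid out along four
#' collinear chains from LBN (UP, OUT, IN, MID) so that every stored length
#' equals the Euclidean distance between its endpoint markers exactly; the
#' cross-chain line MID3-UP2 is the geometric distance between the two
#' orthogonal chains and therefore also grows monotonically with the ramp.
#' Elbow (O) and shoulder (A) markers are placed so the vertical-reference
#' abduction angle reproduces the driving angle.
#'
#' @param profile One-row `subject_profiles` slice.
#' @param config A [generator_config()].
#' @param seed Optional trial seed; defaults to the config seed.
#' @return A `trial_record`: list with `subject_id`, `time_s`,
#'   `angle_deg`, `lengths` (frames x 12), `markers`
#'   (frames x markers x xyz array).
#' @export
simulate_trial <- function(profile, config = generator_config(),
                           seed = config$seed) {
  set.seed(seed)
  n <- config$frames_per_trial
  theta <- abduction_profile(config)
  x <- (theta - config$theta_start) / (config$theta_end - config$theta_start)
  L0 <- baseline_lengths(profile, config$covariate_coupling)
  s <- config$line_sensitivity

  seg_names <- setdiff(BK_OUTPUT_LINES, "MID3-UP2")
  seg <- matrix(NA_real_, n, length(seg_names),
                dimnames = list(NULL, seg_names))
  for (k in seg_names) {
    seg[, k] <- L0[[k]] * (1 + s[[k]] * x) +
      stats::rnorm(n, 0, config$noise_sd)
  }
  if (any(seg <= 0)) stop("non-positive segment length generated; reduce noise_sd")

  lbn <- c(0, profile$npsn_to_lbn_cm * 10, 1200)  # subject-specific anchor
  chains <- list(
    UP = c("UP1", "UP2", "UP3"),
    OUT = c("OUT1", "OUT2", "OUT3"),
    IN = c("IN1", "IN2", "MID"),
    MID = c("MID4", "MID3")
  )
  chain_lines <- list(
    UP = c("LBN-UP1", "UP1-UP2", "UP2-UP3"),
    OUT = c("LBN-OUT1", "OUT1-OUT2", "OUT2-OUT3"),
    IN = c("LBN-IN1", "IN1-IN2", "IN2-MID"),
    MID = c("LBN-MID4", "MID4-MID3")
  )
  marker_labels <- c("LBN", unname(unlist(chains)), "MID1", "MID2", "O", "A")
  arr <- array(NA_real_, dim = c(n, length(marker_labels), 3),
               dimnames = list(NULL, marker_labels, c("x", "y", "z")))
  arr[, "LBN", ] <- matrix(lbn, n, 3, byrow = TRUE)
  for (ch in names(chains)) {
    u <- BK_CHAIN_DIRS[[ch]] / sqrt(sum(BK_CHAIN_DIRS[[ch]]^2))
    cum <- 0
    for (i in seq_along(chains[[ch]])) {
      cum <- cum + seg[, chain_lines[[ch]][i]]
      for (d in 1:3) arr[, chains[[ch]][i], d] <- lbn[d] + cum * u[d]
    }
  }
  # MID1/MID2 sit 30 and 60 mm along the UP chain beyond UP1 direction proxy;
  # not part of the 12 canonical lines.
  u_up <- BK_CHAIN_DIRS$UP
  for (d in 1:3) {
    arr[, "MID1", d] <- arr[, "UP1", d] + 30 * u_up[d]
    arr[, "MID2", d] <- arr[, "UP1", d] + 60 * u_up[d]
  }
  # arm markers: shoulder fixed, elbow swings through theta
  shoulder <- c(150, profile$npsn_to_lbn_cm * 10, 1400)
  arm <- 300
  rad <- theta * pi / 180
  arr[, "O", 1] <- shoulder[1] + arm * sin(rad)
  arr[, "O", 2] <- shoulder[2]
  arr[, "O", 3] <- shoulder[3] - arm * cos(rad)
  arr[, "A", ] <- matrix(shoulder, n, 3, byrow = TRUE)

  lengths <- matrix(NA_real_, n, 12, dimnames = list(NULL, BK_OUTPUT_LINES))
  lengths[, seg_names] <- seg
  d_mu <- arr[, "MID3", ] - arr[, "UP2", ]
  lengths[, "MID3-UP2"] <- sqrt(rowSums(d_mu^2))

  structure(list(
    subject_id = profile$subject_id,
    time_s = (seq_len(n) - 1) / config$sampling_rate,
    angle_deg = theta,
    lengths = lengths,
    markers = arr
  ), class = "trial_record")
}

#' Build the full synthetic dataset
#'
#' Samples a cohort, simulates one trial per subject (per-subject seeds
#' derived from the config seed) and assembles the paired feature
#' matrices: under defaults A is 4400 x 14 and B is 4400 x 12.
#'
#' @param config A [generator_config()].
#' @param profiles Optional pre-drawn cohort; defaults to
#'   [sample_subjects()] under `config`.
#' @return A `feature_matrices` object.
#' @export
#' @examples
#' fm <- build_dataset(generator_config(n_subjects = 2, frames_per_trial = 5))
#' dim(fm$A)
build_dataset <- function(config = generator_config(), profiles = NULL) {
  if (is.null(profiles)) profiles <- sample_subjects(config)
  trials <- lapply(seq_len(nrow(profiles)), function(i) {
    simulate_trial(profiles[i, ], config, seed = config$seed + 1000L + i)
  })
  assemble_features(trials, profiles)
}

#' Write a generated dataset with its manifest
#'
#' Persists matrices A and B as CSV plus a JSON manifest echoing the full
#' generator configuration and seed, so a run is self-describing.
#'
#' @param fm A `feature_matrices` object.
#' @param dir Output directory (created if needed).
#' @param config The [generator_config()] used, echoed into the manifest.
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(fm, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a_path <- file.path(dir, "matrix_A.csv")
  b_path <- file.path(dir, "matrix_B.csv")
  utils::write.csv(fm$A, a_path, row.names = FALSE)
  utils::write.csv(fm$B, b_path, row.names = FALSE)
  man_path <- file.path(dir, "manifest.json")
  manifest <- list(rows = nrow(fm$A),
                   inputs = colnames(fm$A), outputs = colnames(fm$B))
  if (!is.null(config)) manifest$generator <- unclass(config)
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  invisible(c(A = a_path, B = b_path, manifest = man_path))
}
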