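# Marker kinematics: abduction angle, line lengths, feature assembly,
# trajectory text IO.
#
# Coordinates are right-handed, z vertical up, millimetres; angles degrees.

#' Arm abduction angle from elbow and shoulder markers
#'
#' Angle of the elbow-to-shoulder vector. Under the default
#' `"vertical-reference"` convention the angle is
#' `acos((z_A - z_O) / ||A - O||)`: 0 degrees with the arm hanging
#' (shoulder directly above the elbow), 90 degrees horizontal, 180 degrees
#' overhead. The `"horizontal-reference"` convention reports the elevation
#' relative to the horizontal plane, `|90 - vertical|`.
#'
#' @param O Lateral epicondyle (elbow) position, numeric xyz in mm.
#' @param A Acromion (shoulder) position, numeric xyz in mm.
#' @param convention `"vertical-reference"` (default) or
#'   `"horizontal-reference"`.
#' @return Angle in degrees.
#' @export
#' @examples
#' abduction_angle(c(0, 0, 0), c(0, 0, 10))  # 0
#' abduction_angle(c(0, 0, 0), c(3, 4, 0))   # 90
abduction_angle <- function(O, A,
                            convention = c("vertical-reference",
                                           "horizontal-reference")) {
  convention <- match.arg(convention)
  O <- as.numeric(O); A <- as.numeric(A)
  stopifnot(length(O) == 3L, length(A) == 3L)
  d <- A - O
  len <- sqrt(sum(d^2))
  if (len == 0) stop("coincident elbow/shoulder markers: angle undefined")
  cosang <- min(1, max(-1, d[3] / len))
  ang <- acos(cosang) * 180 / pi
  if (convention == "horizontal-reference") ang <- abs(90 - ang)
  ang
}

#' Lengths of the twelve breast lines in one marker frame
#'
#' Euclidean distance between the endpoint markers of each canonical line,
#' in canonical output-column order.
#'
#' @param positions Numeric matrix of marker positions, rows named by
#'   marker label, columns x/y/z in mm.
#' @param lines Line definition table, default [line_definitions()].
#' @return Named numeric vector of 12 lengths, mm.
#' @export
line_lengths <- function(positions, lines = line_definitions()) {
  if (is.null(rownames(positions))) stop("positions must have marker-label rownames")
  needed <- unique(c(lines$from, lines$to))
  missing <- setdiff(needed, rownames(positions))
  if (length(missing) > 0) {
    stop("missing marker(s): ", paste(missing, collapse = ", "))
  }
  out <- numeric(nrow(lines))
  for (i in seq_len(nrow(lines))) {
    d <- positions[lines$to[i], ] - positions[lines$from[i], ]
    out[i] <- sqrt(sum(d^2))
  }
  names(out) <- lines$name
  out
}

# Numeric encoding of inputs 1-13 from a profile row (canonical order).
# Cup letters map to their alphabet position (C=3 ... F=6); underband size
# is the underbust girth banded to the nearest 5 cm, the standard metric
# band ladder.
profile_inputs <- function(profile) {
  c(
    age = profile$age,
    height = profile$height_cm,
    weight = profile$weight_kg,
    bmi = profile$bmi,
    bra_underband = 5 * round(profile$underbust_girth_cm / 5),
    bra_cup = match(profile$cup_size, LETTERS),
    underbust_girth = profile$underbust_girth_cm,
    breast_circumference = profile$breast_circumference_cm,
    left_across_cup = profile$left_across_cup_cm,
    shoulder_to_lbn = profile$shoulder_to_lbn_cm,
    npsn_to_lbn = profile$npsn_to_lbn_cm,
    lbn_to_rbn = profile$lbn_to_rbn_cm,
    left_shoulder_angle = profile$left_shoulder_angle_deg
  )
}

#' Construct a feature-matrix pair
#'
#' @param A Numeric matrix, frames x 14 inputs (canonical column order).
#' @param B Numeric matrix, frames x 12 line lengths (canonical order).
#' @param provenance Optional data.frame with `subject_id` and `frame`
#'   per row.
#' @return A `feature_matrices` object.
#' @export
feature_matrices <- function(A, B, provenance = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("A and B must have equal row counts")
  if (is.null(colnames(A))) colnames(A) <- BK_INPUT_VARS[seq_len(ncol(A))]
  if (is.null(colnames(B))) colnames(B) <- BK_OUTPUT_LINES[seq_len(ncol(B))]
  if (!is.null(provenance) && nrow(provenance) != nrow(A)) {
    stop("provenance must have one row per frame")
  }
  structure(list(A = A, B = B, provenance = provenance),
            class = "feature_matrices")
}

#' @export
print.feature_matrices <- function(x, ...) {
  cat(sprintf("feature matrices: A %d x %d, B %d x %d\n",
              nrow(x$A), ncol(x$A), nrow(x$B), ncol(x$B)))
  invisible(x)
}

#' Assemble feature matrices from trials and profiles
#'
#' Builds the paired input/output matrices: per frame, inputs 1-13 are the
#' subject's body variables (canonical order), input 14 is the abduction
#' angle computed from the O and A markers, and the outputs are the twelve
#' canonical line lengths. Rows are ordered by (subject_id, frame).
#'
#' @param trials List of `trial_record` objects (see [simulate_trial()]).
#' @param profiles `subject_profiles` covering every trial's subject.
#' @return A `feature_matrices` object with row provenance.
#' @export
assemble_features <- function(trials, profiles) {
  ids <- vapply(trials, function(tr) tr$subject_id, "")
  trials <- trials[order(ids)]
  lines <- line_definitions()
  A_rows <- list(); B_rows <- list(); prov <- list()
  for (tr in trials) {
    hit <- which(profiles$subject_id == tr$subject_id)
    if (length(hit) == 0) stop("no profile for subject '", tr$subject_id, "'")
    body <- profile_inputs(profiles[hit[1], ])
    nfr <- dim(tr$markers)[1]
    Ai <- matrix(NA_real_, nfr, 14)
    Bi <- matrix(NA_real_, nfr, 12)
    for (f in seq_len(nfr)) {
      pos <- tr$markers[f, , ]
      ang <- abduction_angle(pos["O", ], pos["A", ])
      Ai[f, ] <- c(body, ang)
      Bi[f, ] <- line_lengths(pos, lines)
    }
    A_rows[[length(A_rows) + 1L]] <- Ai
    B_rows[[length(B_rows) + 1L]] <- Bi
    prov[[length(prov) + 1L]] <- data.frame(
      subject_id = tr$subject_id, frame = seq_len(nfr),
      stringsAsFactors = FALSE)
  }
  A <- do.call(rbind, A_rows); colnames(A) <- BK_INPUT_VARS
  B <- do.call(rbind, B_rows); colnames(B) <- BK_OUTPUT_LINES
  feature_matrices(A, B, do.call(rbind, prov))
}

#' Read / write marker trajectories
#'
#' Long-format delimited text with columns
#' `subject_id, frame, time_s, marker, x_mm, y_mm, z_mm`; lossless at six
#' significant digits.
#'
#' @param path File path.
#' @return `read_trajectory` returns a list with `subject_id`, `time_s`
#'   and a `markers` array (frame x marker x xyz); `write_trajectory`
#'   returns `path` invisibly.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "frame", "time_s", "marker", "x_mm", "y_mm", "z_mm")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("trajectory file missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in c("frame", "time_s", "x_mm", "y_mm", "z_mm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      stop(sprintf("malformed trajectory row (line %d): non-numeric '%s'",
                   which(is.na(v))[1] + 1L, col))
    }
    df[[col]] <- v
  }
  frames <- sort(unique(df$frame))
  markers <- unique(df$marker)
  arr <- array(NA_real_, dim = c(length(frames), length(markers), 3),
               dimnames = list(NULL, markers, c("x", "y", "z")))
  fidx <- match(df$frame, frames)
  midx <- match(df$marker, markers)
  arr[cbind(fidx, midx, 1L)] <- df$x_mm
  arr[cbind(fidx, midx, 2L)] <- df$y_mm
  arr[cbind(fidx, midx, 3L)] <- df$z_mm
  time_s <- vapply(frames, function(f) df$time_s[df$frame == f][1], 0)
  list(subject_id = df$subject_id[1], time_s = time_s, markers = arr)
}

#' @rdname read_trajectory
#' @param trial A `trial_record` (or a list with `subject_id`, `time_s`,
#'   `markers` as produced by [read_trajectory()]).
#' @export
write_trajectory <- function(trial, path) {
  arr <- trial$markers
  nfr <- dim(arr)[1]; labs <- dimnames(arr)[[2]]
  rows <- expand.grid(frame = seq_len(nfr), marker = labs,
                      stringsAsFactors = FALSE)
  df <- data.frame(
    subject_id = trial$subject_id,
    frame = rows$frame,
    time_s = signif(trial$time_s[rows$frame], 9),
    marker = rows$marker,
    x_mm = signif(arr[cbind(rows$frame, match(rows$marker, labs), 1L)], 9),
    y_mm = signif(arr[cbind(rows$frame, match(rows$marker, labs), 2L)], 9),
    z_mm = signif(arr[cbind(rows$frame, match(rows$marker, labs), 3L)], 9),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$frame, match(df$marker, labs)), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Strain transform of a line-length matrix
#'
#' Optional convenience: converts raw lengths L to engineering strain
#' (L - L0) / L0 with L0 the first-frame length per column. The pipeline
#' models raw distances by default; this transform is provided for studies
#' that prefer dimensionless deformation.
#'
#' @param B Frames x lines length matrix, mm.
#' @return Matrix of strains, same shape.
#' @export
line_strain <- function(B) {
  B <- as.matrix(B)
  L0 <- B[1, ]
  if (any(L0 == 0)) stop("zero first-frame length: strain undefined")
  sweep(sweep(B, 2, L0, "-"), 2, L0, "/")
}
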