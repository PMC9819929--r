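# Cohort data model: subject profiles, BMI, summary statistics, validation.

BK_SUBJECT_COLS <- c(
  "subject_id", "age", "height_cm", "weight_kg", "bmi", "cup_size",
  "underbust_girth_cm", "breast_circumference_cm", "left_across_cup_cm",
  "shoulder_to_lbn_cm", "npsn_to_lbn_cm", "lbn_to_rbn_cm",
  "left_shoulder_angle_deg"
)

BK_CUP_GRADES <- c("C", "D", "E", "F")

#' Load subject anthropometry profiles
#'
#' Reads a comma-separated table of per-subject body measurements. Values
#' are preserved verbatim; in particular the printed BMI column is never
#' recomputed on load (see [validate_profiles()] for the audit that compares
#' it against height and weight).
#'
#' @param path Path to a CSV file with one header row and the columns
#'   `subject_id, age, height_cm, weight_kg, bmi, cup_size,
#'   underbust_girth_cm, breast_circumference_cm, left_across_cup_cm,
#'   shoulder_to_lbn_cm, npsn_to_lbn_cm, lbn_to_rbn_cm,
#'   left_shoulder_angle_deg`.
#' @return A data.frame of class `subject_profiles`, one row per subject.
#'   Duplicated `subject_id` values trigger a warning naming the ids.
#' @export
#' @examples
#' subjects <- load_subjects(bk_fixture("table1_subjects.csv"))
#' nrow(subjects)
load_subjects <- function(path) {
  if (!file.exists(path)) stop("subject table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing <- setdiff(BK_SUBJECT_COLS, names(raw))
  if (length(missing) > 0) {
    stop("subject table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  raw <- raw[BK_SUBJECT_COLS]
  num_cols <- setdiff(BK_SUBJECT_COLS, c("subject_id", "cup_size"))
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & nzchar(trimws(raw[[col]])))
    if (length(bad) == 0) bad <- which(is.na(vals))
    if (nrow(raw) > 0 && anyNA(vals)) {
      stop(sprintf("non-numeric value in column '%s' at data row %d: '%s'",
                   col, bad[1], raw[[col]][bad[1]]))
    }
    raw[[col]] <- vals
  }
  dup <- unique(raw$subject_id[duplicated(raw$subject_id)])
  if (length(dup) > 0) {
    warning("duplicated subject_id(s): ", paste(dup, collapse = ", "))
  }
  structure(raw, class = c("subject_profiles", "data.frame"))
}

#' Write subject profiles
#'
#' Inverse of [load_subjects()]; round-trips every field at the printed
#' precision.
#'
#' @param profiles A `subject_profiles` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(profiles, path) {
  utils::write.csv(as.data.frame(profiles)[BK_SUBJECT_COLS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Body mass index
#'
#' BMI in kg/m^2 from weight in kilograms and height in centimetres. The
#' raw value is returned; cohort summaries display it rounded to one
#' decimal.
#'
#' @param weight_kg Body weight, kg (> 0).
#' @param height_cm Stature, cm (> 0). Vectorised.
#' @return Numeric BMI, kg/m^2.
#' @export
#' @examples
#' round(bmi(61.2, 161), 1)  # 23.6
bmi <- function(weight_kg, height_cm) {
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_cm)) ||
      any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop("bmi() requires strictly positive, finite weight and height")
  }
  weight_kg / (height_cm / 100)^2
}

#' Cohort summary statistics for one variable
#'
#' Mean, sample standard deviation (n - 1 denominator), minimum and maximum
#' of a numeric profile field. With a single profile the sd is reported as
#' `NA` (undefined), never zero.
#'
#' @param profiles A `subject_profiles` data.frame.
#' @param variable Name of a numeric column, e.g. `"weight_kg"`.
#' @return A list with `variable`, `n`, `mean`, `sd`, `min`, `max`.
#' @export
#' @examples
#' s <- summary_stats(load_subjects(bk_fixture("table1_subjects.csv")), "weight_kg")
#' round(c(s$mean, s$sd), 1)  # 60.2 5.6
summary_stats <- function(profiles, variable) {
  if (!variable %in% names(profiles)) stop("unknown variable: ", variable)
  x <- profiles[[variable]]
  if (!is.numeric(x)) stop("variable is not numeric: ", variable)
  n <- length(x)
  if (n < 1) stop("no profiles")
  list(
    variable = variable,
    n = n,
    mean = mean(x),
    sd = if (n >= 2) stats::sd(x) else NA_real_,
    min = min(x),
    max = max(x)
  )
}

#' Audit subject profiles for internal consistency
#'
#' Advisory checks, never mutating: flags rows whose printed BMI differs
#' from the value recomputed from height and weight by more than
#' `bmi_tolerance`, and rows violating the type invariants (positive
#' lengths and girths, age in \[18, 120\], breast circumference exceeding
#' underbust girth, admissible cup grade).
#'
#' @param profiles A `subject_profiles` data.frame.
#' @param bmi_tolerance Maximum tolerated |printed - recomputed| BMI,
#'   kg/m^2. Default 0.2 (one rounding step plus slack).
#' @return A data.frame of findings with columns `subject_id`, `check`,
#'   `detail`; zero rows when the cohort is internally consistent.
#' @export
validate_profiles <- function(profiles, bmi_tolerance = 0.2) {
  findings <- list()
  add <- function(id, check, detail) {
    findings[[length(findings) + 1L]] <<- data.frame(
      subject_id = id, check = check, detail = detail,
      stringsAsFactors = FALSE)
  }
  positive_cols <- c("height_cm", "weight_kg", "underbust_girth_cm",
                     "breast_circumference_cm", "left_across_cup_cm",
                     "shoulder_to_lbn_cm", "npsn_to_lbn_cm", "lbn_to_rbn_cm",
                     "left_shoulder_angle_deg")
  for (i in seq_len(nrow(profiles))) {
    row <- profiles[i, ]
    bad_pos <- positive_cols[
      !vapply(positive_cols, function(cl) isTRUE(row[[cl]] > 0), logical(1))]
    for (cl in bad_pos) {
      add(row$subject_id, "nonpositive",
          sprintf("%s = %s must be > 0", cl, format(row[[cl]])))
    }
    if (!isTRUE(row$age >= 18 && row$age <= 120)) {
      add(row$subject_id, "age_range",
          sprintf("age %s outside [18, 120]", format(row$age)))
    }
    if (!row$cup_size %in% BK_CUP_GRADES) {
      add(row$subject_id, "cup_grade",
          sprintf("cup size '%s' not in {%s}", row$cup_size,
                  paste(BK_CUP_GRADES, collapse = ",")))
    }
    if (isTRUE(row$underbust_girth_cm > 0) &&
        isTRUE(row$breast_circumference_cm > 0) &&
        !isTRUE(row$breast_circumference_cm > row$underbust_girth_cm)) {
      add(row$subject_id, "girth_order",
          sprintf("breast circumference %s not greater than underbust %s",
                  format(row$breast_circumference_cm),
                  format(row$underbust_girth_cm)))
    }
    if (isTRUE(row$weight_kg > 0) && isTRUE(row$height_cm > 0)) {
      recomputed <- bmi(row$weight_kg, row$height_cm)
      if (abs(recomputed - row$bmi) > bmi_tolerance) {
        add(row$subject_id, "bmi_mismatch",
            sprintf("printed BMI %.1f vs recomputed %.1f",
                    row$bmi, recomputed))
      }
    }
  }
  if (length(findings) == 0) {
    return(data.frame(subject_id = character(), check = character(),
                      detail = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}
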