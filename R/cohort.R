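# Synthetic cohort generator.
#
# Stands in for the private clinic data: per-patient periodontal charts
# (universal tooth numbering 1-32), medical histories matching the published
# descriptives of the extracted note variables, and stage/grade labels that
# are consistent by construction with the package's staging/grading rules
# (measurements are rejection-sampled until the rule engine reproduces the
# requested label).

# Scalar/vector rule cores shared by assign_stage/assign_grade and the
# generator's rejection sampler.
stage_code <- function(max_cal, lost, n_present) {
  ifelse(max_cal >= 5,
         ifelse(lost >= 5 | n_present < 20, 4L, 3L),
         ifelse(max_cal >= 3, 2L, ifelse(lost == 0, 1L, 2L)))
}

grade_code <- function(bone_loss_percent, age, smoker, diabetic) {
  r <- bone_loss_percent / age
  base <- ifelse(r < 0.25, 1L, ifelse(r <= 1, 2L, 3L))
  pmin(base + as.integer(smoker | diabetic), 3L)
}

# Truncated-normal draw by resampling; returns integers.
draw_trunc_norm <- function(n, mean, sd, lo, hi) {
  x <- round(rnorm(n, mean, sd))
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- which(x < lo | x > hi)
  }
  as.integer(x)
}

#' Reference class distributions
#'
#' Stage and grade class counts of the 309-patient reference cohort the
#' package emulates (stage I/II/III/IV = 6/36/206/61; grade A/B/C =
#' 17/202/87). The grade counts sum to 306, not 309, in the source
#' description; [generate_cohort()] therefore rescales them to the requested
#' cohort size by largest-remainder apportionment.
#'
#' @return Named integer vector of class counts.
#' @export
#' @examples
#' reference_stage_counts()
reference_stage_counts <- function() {
  c(`1` = 6L, `2` = 36L, `3` = 206L, `4` = 61L)
}

#' @rdname reference_stage_counts
#' @export
reference_grade_counts <- function() {
  c(`1` = 17L, `2` = 202L, `3` = 87L)
}

# One patient's teeth for a target stage: returns list(teeth, lost).
draw_teeth_for_stage <- function(s) {
  if (s == 1L) {
    lost <- 0L
    n_present <- sample(24:32, 1)
    max_cal <- sample(1:2, 1)
  } else if (s == 2L) {
    lost <- sample(0:2, 1)
    n_present <- sample(20:(32 - lost), 1)
    max_cal <- sample(3:4, 1)
  } else if (s == 3L) {
    lost <- sample(0:4, 1)
    n_present <- sample(20:(32 - lost), 1)
    max_cal <- sample(5:8, 1)
  } else {
    max_cal <- sample(5:9, 1)
    if (runif(1) < 0.5) {
      lost <- sample(5:10, 1)
      n_present <- sample(8:(32 - lost), 1)
    } else {
      lost <- sample(0:4, 1)
      n_present <- sample(8:19, 1)
    }
  }
  ids <- sort(sample(1:32, n_present))
  # Severity profile: most teeth mildly affected, at least one at the maximum.
  cal <- sample(0:max_cal, n_present, replace = TRUE,
                prob = exp(-0.45 * (0:max_cal)))
  cal[sample.int(n_present, 1)] <- max_cal
  ppd <- pmin(cal + sample(1:3, n_present, replace = TRUE), 12L)
  teeth <- tibble::tibble(
    tooth_id = 1:32,
    present  = 1:32 %in% ids,
    ppd_mm   = NA_integer_, cal_mm = NA_integer_,
    bleeding = NA, plaque = NA, mobile = NA
  )
  teeth$ppd_mm[teeth$present] <- as.integer(ppd)
  teeth$cal_mm[teeth$present] <- as.integer(cal)
  teeth$bleeding[teeth$present] <- runif(n_present) < (0.15 + 0.12 * s)
  teeth$plaque[teeth$present] <- runif(n_present) < (0.25 + 0.10 * s)
  teeth$mobile[teeth$present] <- runif(n_present) < (0.04 * s)
  list(teeth = teeth, lost = as.integer(lost))
}

# Progression indicators for a target grade: list(age, smoker, diabetic, bl).
draw_history_for_grade <- function(g) {
  for (i in 1:1000) {
    age <- sample(30:79, 1)
    if (g == 1L) {
      smoker <- FALSE
      diabetic <- FALSE
    } else {
      smoker <- runif(1) < 0.30
      diabetic <- runif(1) < 0.20
    }
    base <- g - as.integer(smoker || diabetic)
    if (base < 1) next
    r <- switch(base, runif(1, 0.05, 0.24), runif(1, 0.26, 0.99),
                runif(1, 1.02, 1.50))
    bl <- round(r * age, 1)
    if (bl > 90) next
    if (grade_code(bl, age, smoker, diabetic) == g) {
      return(list(age = age, smoker = smoker, diabetic = diabetic, bl = bl))
    }
  }
  abort("internal: grade rejection sampler failed to converge")
}

#' Generate a synthetic periodontal cohort
#'
#' Returns one tibble row per patient with medical history, radiographic
#' bone loss, stage/grade labels, and a `teeth` list-column holding the
#' per-tooth periodontal chart (probing pocket depth, clinical attachment
#' loss, bleeding/plaque/mobility flags over universal tooth numbers 1--32).
#' Requested stage and grade histograms are matched exactly: per-patient
#' measurements are rejection-sampled until [assign_stage()] and
#' [assign_grade()] reproduce the requested labels, so stored labels and
#' measurements are mutually consistent for every record. Identical
#' arguments yield byte-identical cohorts.
#'
#' @param n Number of patients.
#' @param stage_counts Named integer vector of counts for stages 1--4 summing
#'   to `n`; default rescales the reference cohort's stage histogram.
#' @param grade_counts Counts for grades 1--3 summing to `n`; default
#'   rescales the reference grade histogram.
#' @param seed Integer seed; all randomness is local to this call.
#' @return A `perio_cohort` tibble with columns `chart_number`, `visit_date`,
#'   `age`, `systolic_bp`, `diastolic_bp`, `heart_rate`, `smoker`,
#'   `diabetic`, `allergies`, `prior_surgery`, `stain`, `calculus`, `plaque`,
#'   `bone_loss_percent`, `teeth_lost_perio`, `stage`, `grade`, `teeth`.
#' @export
#' @examples
#' cohort <- generate_cohort(12, seed = 7)
#' table(cohort$stage)
generate_cohort <- function(n, stage_counts = NULL, grade_counts = NULL,
                            seed = 1L) {
  assert_count(n, "n")
  stage_counts <- stage_counts %||% scale_counts(reference_stage_counts(), n)
  grade_counts <- grade_counts %||% scale_counts(reference_grade_counts(), n)
  if (length(stage_counts) != 4 || sum(stage_counts) != n) {
    abort("`stage_counts` must have 4 entries summing to `n`",
          class = "periodx_config_error")
  }
  if (length(grade_counts) != 3 || sum(grade_counts) != n) {
    abort("`grade_counts` must have 3 entries summing to `n`",
          class = "periodx_config_error")
  }
  with_seed(seed, {
    stages <- sample(rep(1:4, times = stage_counts))
    grades <- sample(rep(1:3, times = grade_counts))
    dates <- as.Date("2017-01-01") + sample(0:1825, n, replace = TRUE)

    sys <- dia <- integer(n)
    for (i in seq_len(n)) {
      repeat {
        s <- draw_trunc_norm(1, 129.3, 15.5, 79, 187)
        d <- draw_trunc_norm(1, 78.1, 40.32, 43, 120)
        if (s > d + 5) break
      }
      sys[i] <- s
      dia[i] <- d
    }

    charts <- purrr::map(stages, draw_teeth_for_stage)
    hist_g <- purrr::map(grades, draw_history_for_grade)

    cohort <- tibble::tibble(
      chart_number = 1000L + seq_len(n),
      visit_date = dates,
      age = purrr::map_int(hist_g, "age"),
      systolic_bp = sys,
      diastolic_bp = dia,
      heart_rate = draw_trunc_norm(n, 72.4, 10.45, 44, 118),
      smoker = purrr::map_lgl(hist_g, "smoker"),
      diabetic = purrr::map_lgl(hist_g, "diabetic"),
      allergies = runif(n) < 0.25,
      prior_surgery = runif(n) < 0.15,
      stain = sample(0:3, n, replace = TRUE, prob = c(0.2, 0.3, 0.3, 0.2)),
      calculus = sample(0:3, n, replace = TRUE, prob = c(0.15, 0.3, 0.3, 0.25)),
      plaque = sample(0:3, n, replace = TRUE, prob = c(0.15, 0.3, 0.3, 0.25)),
      bone_loss_percent = purrr::map_dbl(hist_g, "bl"),
      teeth_lost_perio = purrr::map_int(charts, "lost"),
      stage = as.integer(stages),
      grade = as.integer(grades),
      teeth = purrr::map(charts, "teeth")
    )
    # Consistency gate: stored labels must equal the rule engine's output.
    stopifnot(all(assign_stage(cohort) == cohort$stage),
              all(assign_grade(cohort) == cohort$grade))
    class(cohort) <- c("perio_cohort", class(cohort))
    attr(cohort, "seed") <- as.integer(seed)
    cohort
  })
}

#' Label-determining feature sets
#'
#' Column names of [cohort_features()] that deterministically fix the stage
#' (maximum CAL, periodontal tooth loss, residual dentition) and the grade
#' (bone loss, age, their ratio, smoking, diabetes). Parameter-recovery
#' experiments train on exactly these columns, so any test error is
#' attributable to the learner, not to missing information.
#'
#' @return Character vector of column names.
#' @export
stage_determinants <- function() {
  c("max_cal_mm", "teeth_lost_perio", "n_present")
}

#' @rdname stage_determinants
#' @export
grade_determinants <- function() {
  c("bone_loss_percent", "age", "bone_loss_per_age", "smoker", "diabetic")
}

#' Structured ground-truth feature table of a cohort
#'
#' The chart- and record-derived determinants of stage and grade (maximum
#' CAL, teeth lost to periodontitis, teeth present, bone-loss percentage,
#' age, smoking, diabetes) together with the coded history covariates. Labels
#' are an exact deterministic function of these columns, which makes this
#' table the right input for parameter-recovery experiments with the tabular
#' classifier; the pattern-extracted note table (see [extract_notes()]) is a
#' degraded view of it.
#'
#' @param cohort A `perio_cohort` tibble.
#' @return Tibble with `chart_number`, `stage`, `grade` and numeric feature
#'   columns.
#' @export
cohort_features <- function(cohort) {
  stopifnot(is.data.frame(cohort), "teeth" %in% names(cohort))
  present <- purrr::map(cohort$teeth, ~ .x[.x$present, , drop = FALSE])
  tibble::tibble(
    chart_number = cohort$chart_number,
    stage = cohort$stage,
    grade = cohort$grade,
    max_cal_mm = purrr::map_int(present, ~ max(.x$cal_mm)),
    max_ppd_mm = purrr::map_int(present, ~ max(.x$ppd_mm)),
    n_present = purrr::map_int(present, nrow),
    teeth_lost_perio = cohort$teeth_lost_perio,
    bone_loss_percent = cohort$bone_loss_percent,
    age = cohort$age,
    # Progression index: the bone-loss/age ratio clinicians grade by.
    bone_loss_per_age = cohort$bone_loss_percent / cohort$age,
    smoker = as.integer(cohort$smoker),
    diabetic = as.integer(cohort$diabetic),
    systolic_bp = cohort$systolic_bp,
    diastolic_bp = cohort$diastolic_bp,
    heart_rate = cohort$heart_rate,
    stain = cohort$stain,
    calculus = cohort$calculus,
    plaque = cohort$plaque,
    allergies = as.integer(cohort$allergies),
    prior_surgery = as.integer(cohort$prior_surgery),
    n_teeth_bleeding = purrr::map_int(present, ~ sum(.x$bleeding)),
    n_teeth_plaque = purrr::map_int(present, ~ sum(.x$plaque))
  )
}
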