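# Shared fixtures, built once per test run.

# Small cohort reused across files (memoized).
fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(fixture_env$cohort)) {
    fixture_env$cohort <- generate_cohort(40, seed = 101L)
  }
  fixture_env$cohort
}

small_notes <- function() {
  if (is.null(fixture_env$notes)) {
    fixture_env$notes <- render_notes(small_cohort(), omission_rate = 0,
                                      case_jitter = TRUE, seed = 102L)
  }
  fixture_env$notes
}

default_schema <- function() {
  if (is.null(fixture_env$schema)) {
    fixture_env$schema <- load_extraction_schema()
  }
  fixture_env$schema
}

# A one-row record with fully specified measurements, for rule-table tests.
make_record <- function(max_cal, n_present = 28, lost = 0, bone_loss = 20,
                        age = 50, smoker = FALSE, diabetic = FALSE) {
  teeth <- tibble::tibble(
    tooth_id = 1:32, present = 1:32 <= n_present,
    ppd_mm = NA_integer_, cal_mm = NA_integer_,
    bleeding = NA, plaque = NA, mobile = NA
  )
  teeth$cal_mm[teeth$present] <- 1L
  teeth$cal_mm[1] <- as.integer(max_cal)
  teeth$ppd_mm[teeth$present] <- teeth$cal_mm[teeth$present] + 1L
  teeth$bleeding[teeth$present] <- FALSE
  teeth$plaque[teeth$present] <- FALSE
  teeth$mobile[teeth$present] <- FALSE
  tibble::tibble(
    teeth = list(teeth), teeth_lost_perio = as.integer(lost),
    bone_loss_percent = bone_loss, age = age,
    smoker = smoker, diabetic = diabetic
  )
}

# Ground-truth comparison of extracted rows against the generator's truth.
# Returns a logical matrix notes x fields: TRUE when the field was recovered
# exactly.
recovery_matrix <- function(feats, truth) {
  sapply(names(truth), function(nm) {
    t_ <- truth[[nm]]
    f_ <- feats[[nm]]
    if (nm == "date") t_ <- as.character(t_)
    !is.na(f_) & f_ == t_
  })
}

quiet_run <- function(...) suppressMessages(perio_run(...))
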