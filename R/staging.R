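# Staging/grading rule engine.
#
# The 2017 World Workshop criteria are a clinical framework, not a formula;
# the rules here are a deliberately simplified, testable approximation used as
# the generator's internal ground-truth oracle: severity by maximum clinical
# attachment loss (CAL), complexity by periodontitis-attributed tooth loss and
# residual dentition, progression rate by the bone-loss/age ratio with
# smoking/diabetes modifiers. They are NOT validated against the workshop text
# and must not be used for clinical decision making.

#' Assign periodontitis stage from chart measurements
#'
#' Applies the package's staging rule to each record of a cohort: stage I if
#' maximum CAL is at most 2 mm and no tooth has been lost to periodontitis,
#' stage II if maximum CAL is 3--4 mm, stage III if maximum CAL is 5 mm or
#' more with at most 4 teeth lost, and stage IV if maximum CAL is 5 mm or
#' more and either 5 or more teeth were lost or fewer than 20 teeth remain.
#' A record with mild severity (CAL <= 2 mm) but periodontal tooth loss falls
#' outside the rule table; it is escalated to stage II (loss implies history
#' of destruction beyond stage I).
#'
#' @param records A cohort tibble (see [generate_cohort()]) or any data frame
#'   with a `teeth` list-column (per-tooth tibbles with `present` and
#'   `cal_mm`) and a `teeth_lost_perio` column.
#' @return Integer vector of stages, coded 1--4 (I--IV).
#' @seealso [assign_grade()], [generate_cohort()]
#' @export
#' @examples
#' cohort <- generate_cohort(8, seed = 1)
#' all(assign_stage(cohort) == cohort$stage)
assign_stage <- function(records) {
  stopifnot(is.data.frame(records), "teeth" %in% names(records),
            "teeth_lost_perio" %in% names(records))
  purrr::map2_int(records$teeth, records$teeth_lost_perio, function(teeth, lost) {
    present <- teeth[teeth$present, , drop = FALSE]
    if (nrow(present) == 0) {
      abort("invalid record: no present teeth", class = "periodx_invalid_record")
    }
    max_cal <- max(present$cal_mm)
    n_present <- nrow(present)
    if (max_cal >= 5) {
      if (lost >= 5 || n_present < 20) 4L else 3L
    } else if (max_cal >= 3) {
      2L
    } else if (lost == 0) {
      1L
    } else {
      2L
    }
  })
}

#' Assign periodontitis grade from progression indicators
#'
#' Base grade from the radiographic bone-loss / age ratio
#' `r = bone_loss_percent / age`: grade A (1) when `r < 0.25`, grade B (2)
#' when `0.25 <= r <= 1`, grade C (3) when `r > 1`. Smoking or diabetes then
#' raises the grade by one level, capped at C.
#'
#' @param records A cohort tibble or data frame with numeric
#'   `bone_loss_percent` and `age` columns and logical `smoker` and
#'   `diabetic` columns.
#' @return Integer vector of grades, coded 1--3 (A--C).
#' @export
#' @examples
#' df <- tibble::tibble(bone_loss_percent = c(10, 10, 60), age = c(50, 50, 40),
#'                      smoker = c(FALSE, TRUE, FALSE), diabetic = FALSE)
#' assign_grade(df) # 1, 2, 3
assign_grade <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("bone_loss_percent", "age", "smoker", "diabetic") %in% names(records)))
  if (any(records$age <= 0)) {
    abort("invalid record: age must be positive", class = "periodx_invalid_record")
  }
  r <- records$bone_loss_percent / records$age
  base <- ifelse(r < 0.25, 1L, ifelse(r <= 1, 2L, 3L))
  out <- base + as.integer(records$smoker | records$diabetic)
  as.integer(pmin(out, 3L))
}
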