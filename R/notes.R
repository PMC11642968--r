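# Templated free-text note rendering.
#
# Emulates the unstructured clinician notes the pipeline consumes: each of
# the 16 extractable variables is phrased through randomly chosen synonym
# templates, optionally omitted, and optionally case-jittered to exercise
# case-insensitive extraction. Blood pressure (systolic + diastolic) forms
# one phrase, as does the stage/grade diagnosis sentence.

ordinal_words <- c("no", "light", "medium", "heavy")
roman_stages <- c("I", "II", "III", "IV")
grade_letters <- c("A", "B", "C")

#' Default note template bank
#'
#' A named list of synonym phrase templates, one element per extractable
#' note variable (boolean variables carry `yes`/`no` sub-lists), plus
#' neutral `filler` sentences. Placeholders use [glue::glue()] syntax and are
#' filled from the patient record. Users can supply their own bank to
#' [render_note()] to emulate local note styles; the shipped extraction
#' schema covers this default bank.
#'
#' @return Named list of character vectors (or two-element lists for
#'   booleans).
#' @export
default_template_bank <- function() {
  list(
    header = c("Chart number: {chart}. Visit date: {date}.",
               "Patient chart #{chart}, seen on {date}.",
               "Chart no. {chart} - intake visit {date}."),
    blood_pressure = c("BP: {sys}/{dia} mmHg.",
                       "Blood pressure {sys}/{dia}.",
                       "Blood pressure was {sys} over {dia} mmHg."),
    heart_rate = c("HR {hr} bpm.", "Heart rate of {hr} bpm.", "Pulse {hr}."),
    stain = c("{word} stain on teeth.", "Tooth stain: {word}.",
              "{word} staining noted."),
    smoking = list(
      yes = c("Patient is a current smoker.", "Positive smoking history.",
              "Smokes daily."),
      no = c("Non-smoker.", "Denies smoking.", "No smoking history.")
    ),
    plaque = c("{word} plaque.", "Plaque: {word}.", "{word} plaque deposits."),
    calculus = c("{word} calculus.", "Calculus: {word}.",
                 "{word} calculus deposits."),
    bone_loss = list(
      yes = c("Radiographic bone loss evident.",
              "Generalized bone loss on radiographs.", "Bone loss present."),
      no = c("No radiographic bone loss.", "No bone loss evident.")
    ),
    tooth_mobility = list(
      yes = c("Tooth mobility noted.", "Mobile teeth present.",
              "Mobility detected on probing."),
      no = c("No tooth mobility.", "No mobile teeth.")
    ),
    allergies = list(
      yes = c("Allergies: yes.", "Known drug allergies.",
              "Patient reports allergies."),
      no = c("No known allergies.", "NKDA.", "Denies allergies.")
    ),
    prior_surgery = list(
      yes = c("History of periodontal surgery (FGG).",
              "Previous GTR surgery.", "Prior GBR procedure."),
      no = c("No history of periodontal surgery.",
             "No previous FGG, GTR or GBR.")
    ),
    diabetes = list(
      yes = c("Diabetic patient.", "Type 2 diabetes.",
              "Diabetes mellitus present."),
      no = c("Non-diabetic.", "No diabetes.", "Denies diabetes.")
    ),
    diagnosis = c(
      "Diagnosis: generalized periodontitis stage {stage} grade {grade}.",
      "Periodontitis, stage {stage}, grade {grade}.",
      "Dx: stage {stage} grade {grade} periodontitis."
    ),
    filler = c(
      "Patient presented for comprehensive periodontal evaluation.",
      "Full mouth probing completed at six sites per tooth.",
      "Oral hygiene instructions reviewed with the patient.",
      "Scaling and root planing discussed as initial therapy.",
      "Recall interval of three months recommended.",
      "Treatment options and prognosis discussed in detail.",
      "Radiographs reviewed with the patient at chairside.",
      "Patient tolerated the examination well.",
      "Informed consent obtained prior to examination.",
      "Occlusion evaluated; no interferences detected."
    )
  )
}

# Ground-truth values of the 16 note variables for one cohort.
#' Ground-truth note variables of a cohort
#'
#' The values the note renderer embeds and that extraction should recover:
#' one row per patient with the 16 note variables (chart number, date, stage,
#' grade, vitals, coded history flags). The bone-loss flag codes whether
#' radiographic bone loss reaches 10% of root length; tooth mobility codes
#' whether any present tooth is mobile.
#'
#' @param cohort A `perio_cohort` tibble.
#' @return Tibble with one row per patient, columns named as in the feature
#'   table.
#' @export
note_truth <- function(cohort) {
  tibble::tibble(
    chart_number = cohort$chart_number,
    date = as.character(cohort$visit_date),
    stage = cohort$stage,
    grade = cohort$grade,
    systolic_bp = cohort$systolic_bp,
    diastolic_bp = cohort$diastolic_bp,
    heart_rate = cohort$heart_rate,
    stain = cohort$stain,
    smoking = as.integer(cohort$smoker),
    plaque = cohort$plaque,
    calculus = cohort$calculus,
    bone_loss = as.integer(cohort$bone_loss_percent >= 10),
    tooth_mobility = purrr::map_int(cohort$teeth,
                                    ~ as.integer(any(.x$mobile[.x$present]))),
    allergies = as.integer(cohort$allergies),
    prior_surgery = as.integer(cohort$prior_surgery),
    diabetes = as.integer(cohort$diabetic)
  )
}

pick <- function(x) if (length(x) == 1) x else x[sample.int(length(x), 1)]

jitter_case <- function(sentences) {
  u <- runif(length(sentences))
  sentences[u < 0.25] <- toupper(sentences[u < 0.25])
  sentences[u > 0.85] <- tolower(sentences[u > 0.85])
  sentences
}

# Renders one note; assumes an active RNG stream (callers seed it).
render_note_impl <- function(truth, bank, omission_rate, case_jitter) {
  keep <- function() runif(1) >= omission_rate
  env <- list(
    chart = truth$chart_number, date = truth$date,
    sys = truth$systolic_bp, dia = truth$diastolic_bp,
    hr = truth$heart_rate,
    stage = roman_stages[truth$stage], grade = grade_letters[truth$grade]
  )
  g <- function(template, word = NULL) {
    glue::glue_data(c(env, list(word = word)), template)
  }
  yn <- function(entry, flag) pick(if (flag == 1) entry$yes else entry$no)
  body <- character(0)
  if (keep()) body <- c(body, g(pick(bank$blood_pressure)))
  if (keep()) body <- c(body, g(pick(bank$heart_rate)))
  if (keep()) body <- c(body, g(pick(bank$stain),
                                ordinal_words[truth$stain + 1]))
  if (keep()) body <- c(body, yn(bank$smoking, truth$smoking))
  if (keep()) body <- c(body, g(pick(bank$plaque),
                                ordinal_words[truth$plaque + 1]))
  if (keep()) body <- c(body, g(pick(bank$calculus),
                                ordinal_words[truth$calculus + 1]))
  if (keep()) body <- c(body, yn(bank$bone_loss, truth$bone_loss))
  if (keep()) body <- c(body, yn(bank$tooth_mobility, truth$tooth_mobility))
  if (keep()) body <- c(body, yn(bank$allergies, truth$allergies))
  if (keep()) body <- c(body, yn(bank$prior_surgery, truth$prior_surgery))
  if (keep()) body <- c(body, yn(bank$diabetes, truth$diabetes))
  fillers <- sample(bank$filler, sample(3:6, 1))
  body <- c(sample(c(body, fillers)),
            if (keep()) g(pick(bank$diagnosis)) else character(0))
  sentences <- c(g(pick(bank$header)), body)
  # Ordinal sentences start mid-template; normalize the leading capital.
  sentences <- sub("^([a-z])", "\\U\\1", sentences, perl = TRUE)
  if (case_jitter) sentences <- jitter_case(sentences)
  paste(sentences, collapse = " ")
}

#' Render a synthetic clinical note
#'
#' Turns one patient record into free text. Each extractable variable is
#' mentioned with probability `1 - omission_rate` using a randomly chosen
#' synonym template; the chart number and visit date header is always
#' present. The stage/grade diagnosis appears as one sentence; blood
#' pressure (systolic and diastolic) as one phrase.
#'
#' @param record One-row slice of a `perio_cohort`.
#' @param template_bank Template bank, see [default_template_bank()].
#' @param omission_rate Probability each variable is left out of the note,
#'   in `[0, 1]`. At 1 the note reduces to the header.
#' @param case_jitter If `TRUE`, sentence case is randomly upper/lower-cased
#'   to exercise case-insensitive extraction.
#' @param seed Integer seed.
#' @return Tibble with columns `chart_number`, `text`.
#' @export
#' @examples
#' cohort <- generate_cohort(2, seed = 1)
#' render_note(cohort[1, ], seed = 5)$text
render_note <- function(record, template_bank = default_template_bank(),
                        omission_rate = 0, case_jitter = FALSE, seed = 1L) {
  stopifnot(nrow(record) == 1, omission_rate >= 0, omission_rate <= 1,
            length(template_bank) > 0)
  truth <- note_truth(record)
  with_seed(seed, tibble::tibble(
    chart_number = record$chart_number,
    text = render_note_impl(truth, template_bank, omission_rate, case_jitter)
  ))
}

#' Render notes for a whole cohort
#'
#' @param cohort A `perio_cohort` tibble.
#' @inheritParams render_note
#' @return Tibble with one row per patient, columns `chart_number`, `text`.
#' @export
render_notes <- function(cohort, template_bank = default_template_bank(),
                         omission_rate = 0, case_jitter = FALSE, seed = 1L) {
  stopifnot(omission_rate >= 0, omission_rate <= 1)
  truth <- note_truth(cohort)
  with_seed(seed, tibble::tibble(
    chart_number = cohort$chart_number,
    text = purrr::map_chr(seq_len(nrow(cohort)), function(i) {
      render_note_impl(truth[i, ], template_bank, omission_rate, case_jitter)
    })
  ))
}
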