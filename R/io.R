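# Plain-text cohort serialization: one UTF-8 .txt file per note, one CSV
# chart per patient, one cohort-level labels CSV.

#' Write a cohort and its notes to disk
#'
#' Layout under `out_dir`: `notes/<chart_number>.txt` (UTF-8), one
#' `charts/<chart_number>.csv` per patient (one row per tooth, columns
#' `tooth_id,present,ppd_mm,cal_mm,bleeding,plaque,mobile`), and a
#' cohort-level `labels.csv` with `chart_number,date,stage,grade`.
#'
#' @param cohort A `perio_cohort` tibble (may be empty).
#' @param notes Tibble with `chart_number`, `text` from [render_notes()], or
#'   `NULL` to skip note files.
#' @param out_dir Output directory, created if needed.
#' @return Named list of written paths (`labels`, `charts`, `notes`),
#'   invisibly.
#' @export
write_cohort <- function(cohort, notes = NULL, out_dir) {
  dir.create(file.path(out_dir, "charts"), recursive = TRUE, showWarnings = FALSE)
  labels <- tibble::tibble(
    chart_number = cohort$chart_number,
    date = as.character(cohort$visit_date),
    stage = cohort$stage,
    grade = cohort$grade
  )
  labels_path <- file.path(out_dir, "labels.csv")
  readr::write_csv(labels, labels_path)
  chart_paths <- purrr::map2_chr(cohort$teeth, cohort$chart_number, function(t, id) {
    p <- file.path(out_dir, "charts", paste0(id, ".csv"))
    readr::write_csv(dplyr::mutate(
      t,
      dplyr::across(c("present", "bleeding", "plaque", "mobile"), as.integer)
    ), p, na = "")
    p
  })
  note_paths <- character(0)
  if (!is.null(notes)) {
    dir.create(file.path(out_dir, "notes"), showWarnings = FALSE)
    note_paths <- purrr::map2_chr(notes$text, notes$chart_number, function(txt, id) {
      p <- file.path(out_dir, "notes", paste0(id, ".txt"))
      writeLines(enc2utf8(txt), p, useBytes = TRUE)
      p
    })
  }
  invisible(list(labels = labels_path, charts = chart_paths, notes = note_paths))
}

#' Read a cohort directory back
#'
#' Inverse of [write_cohort()] over what the files carry: labels, per-patient
#' charts, and note texts. Medical-history fields are not serialized to the
#' chart files (in real data they live only in the note text), so the return
#' is not a full `perio_cohort`; round-trips are exact on labels, charts and
#' notes.
#'
#' @param dir Directory written by [write_cohort()].
#' @return List with tibbles `labels`, `notes` (empty if no notes were
#'   written) and a `teeth` list-column table `charts` keyed by
#'   `chart_number`.
#' @export
read_cohort <- function(dir) {
  labels_path <- file.path(dir, "labels.csv")
  if (!file.exists(labels_path)) {
    abort(glue::glue("no labels.csv under '{dir}'"))
  }
  labels <- readr::read_csv(labels_path, show_col_types = FALSE,
                            col_types = "icii")
  chart_files <- sort(list.files(file.path(dir, "charts"), "\\.csv$",
                                 full.names = TRUE))
  charts <- tibble::tibble(
    chart_number = as.integer(sub("\\.csv$", "", basename(chart_files))),
    teeth = purrr::map(chart_files, function(p) {
      readr::read_csv(p, show_col_types = FALSE, na = "",
                      col_types = "iiiiiii") |>
        dplyr::mutate(dplyr::across(c("present", "bleeding", "plaque",
                                      "mobile"), as.logical))
    })
  )
  note_files <- sort(list.files(file.path(dir, "notes"), "\\.txt$",
                                full.names = TRUE))
  notes <- tibble::tibble(
    chart_number = as.integer(sub("\\.txt$", "", basename(note_files))),
    text = purrr::map_chr(note_files, ~ paste(readLines(.x, encoding = "UTF-8"),
                                              collapse = "\n"))
  )
  list(labels = labels, charts = charts, notes = notes)
}
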