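# Pattern-based note extraction and chart summarization.
#
# The extraction phase turns each free-text note into one row of a structured
# feature table (16 note variables) and each periodontal chart into six
# summary columns. Patterns are data, not code: they live in a YAML schema so
# users can adapt them to local note styles without touching the package.

note_variable_names <- c(
  "chart_number", "date", "stage", "grade", "systolic_bp", "diastolic_bp",
  "heart_rate", "stain", "smoking", "plaque", "calculus", "bone_loss",
  "tooth_mobility", "allergies", "prior_surgery", "diabetes"
)

chart_variable_names <- c(
  "n_teeth_with_pockets", "pocket_score", "n_teeth_with_cal", "cal_score",
  "n_teeth_bleeding", "n_teeth_plaque"
)

#' Column order of the merged feature table
#'
#' The 22 columns of the structured table: 16 note-derived variables followed
#' by 6 chart-derived summaries.
#'
#' @return Character vector of column names.
#' @export
feature_table_columns <- function() c(note_variable_names, chart_variable_names)

known_converters <- c("integer", "date", "ordinal", "flag", "stage_roman",
                      "grade_letter")

#' Load and validate an extraction schema
#'
#' Reads a YAML pattern schema (see the packaged
#' `extdata/extraction_schema.yaml` for the format): per variable, an ordered
#' list of case-insensitive patterns -- plain strings with one capture group,
#' or `pattern`/`value` pairs assigning a fixed code on match -- and a
#' converter (`integer`, `date`, `ordinal` for no/light/medium/heavy to 0--3,
#' `flag`, `stage_roman`, `grade_letter`).
#'
#' @param path Path to a schema YAML file; default is the packaged schema.
#' @return A validated schema object (named list), class
#'   `perio_extraction_schema`.
#' @export
load_extraction_schema <- function(path = NULL) {
  path <- path %||% system.file("extdata", "extraction_schema.yaml",
                                package = "periodx", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  vars <- raw$variables
  if (is.null(vars) || length(vars) == 0) {
    abort("schema has no `variables` section", class = "periodx_config_error")
  }
  schema <- purrr::imap(vars, function(v, name) {
    conv <- v$converter %||% "integer"
    if (!conv %in% known_converters) {
      abort(glue::glue("unknown converter '{conv}' for variable '{name}'"),
            class = "periodx_config_error")
    }
    pats <- purrr::map(v$patterns, function(p) {
      if (is.character(p)) list(pattern = p, value = NULL)
      else list(pattern = p$pattern, value = p$value)
    })
    if (length(pats) == 0) {
      abort(glue::glue("variable '{name}' has no patterns"),
            class = "periodx_config_error")
    }
    list(name = name, converter = conv, patterns = pats)
  })
  structure(schema, class = c("perio_extraction_schema", "list"))
}

convert_capture <- function(text, converter) {
  text <- tolower(text)
  switch(converter,
    integer = suppressWarnings(as.integer(text)),
    date = if (!is.na(as.Date(text, optional = TRUE))) text else NA_character_,
    ordinal = c(no = 0L, light = 1L, medium = 2L, heavy = 3L)[[text]],
    flag = suppressWarnings(as.integer(text)),
    stage_roman = c(i = 1L, ii = 2L, iii = 3L, iv = 4L)[[text]],
    grade_letter = c(a = 1L, b = 2L, c = 3L)[[text]]
  )
}

na_for <- function(converter) {
  if (converter == "date") NA_character_ else NA_integer_
}

#' Extract structured variables from one clinical note
#'
#' Applies the schema's patterns to the note text, case-insensitively, first
#' match wins within each variable's ordered pattern list. Variables whose
#' patterns never match are left missing -- extraction never raises on absent
#' information and never fabricates a value: every non-missing field is
#' traceable to a character offset in the note (returned in the `offsets`
#' attribute).
#'
#' @param note A one-row tibble with a `text` column (as produced by
#'   [render_note()]), or a single string.
#' @param schema Schema from [load_extraction_schema()].
#' @return One-row tibble with the 16 note-variable columns; missing fields
#'   are `NA`. Attribute `offsets`: named integer vector of 1-based match
#'   positions for the captured fields.
#' @export
#' @examples
#' schema <- load_extraction_schema()
#' extract_features("BP: 132/78 mmHg, HR 72. Stage III grade A.", schema)
extract_features <- function(note, schema = load_extraction_schema()) {
  if (is.data.frame(note)) note <- note$text
  stopifnot(is.character(note), length(note) == 1, nzchar(note))
  if (!inherits(schema, "perio_extraction_schema")) {
    abort("`schema` must come from load_extraction_schema()",
          class = "periodx_config_error")
  }
  offsets <- integer(0)
  values <- purrr::map(schema, function(var) {
    for (p in var$patterns) {
      rx <- stringr::regex(p$pattern, ignore_case = TRUE)
      loc <- stringr::str_locate(note, rx)
      if (!is.na(loc[1, 1])) {
        if (!is.null(p$value)) {
          offsets[[var$name]] <<- loc[1, 1]
          return(convert_capture(as.character(p$value), var$converter))
        }
        cap <- stringr::str_match(note, rx)[1, 2]
        if (!is.na(cap)) {
          offsets[[var$name]] <<- loc[1, 1]
          return(convert_capture(cap, var$converter))
        }
      }
    }
    na_for(var$converter)
  })
  row <- tibble::as_tibble(values)
  # Guarantee the canonical 16 columns even for partial schemas.
  for (nm in setdiff(note_variable_names, names(row))) row[[nm]] <- NA_integer_
  row <- row[, union(intersect(note_variable_names, names(row)),
                     names(row)), drop = FALSE]
  attr(row, "offsets") <- offsets
  row
}

#' Extract features for many notes
#'
#' @param notes Tibble with `chart_number` and `text` columns.
#' @param schema Schema from [load_extraction_schema()].
#' @return Tibble with one row per note (note-derived chart number is
#'   replaced by the file/cohort chart number when they disagree is NOT done:
#'   the extracted value is kept, missing when unmatched).
#' @export
extract_notes <- function(notes, schema = load_extraction_schema()) {
  stopifnot(is.data.frame(notes), "text" %in% names(notes))
  purrr::map(notes$text, extract_features, schema = schema) |>
    purrr::list_rbind()
}

#' Summarize a periodontal chart
#'
#' Counts present teeth meeting each criterion and scores extent: a score of
#' 1 (generalized) means the affected fraction of present teeth reaches
#' `extent_fraction`, else 0 (localized).
#'
#' @param teeth Per-tooth tibble (`present`, `ppd_mm`, `cal_mm`, `bleeding`,
#'   `plaque` columns).
#' @param pocket_threshold_mm A tooth has a pocket when `ppd_mm` is at least
#'   this (default 4 mm).
#' @param cal_threshold_mm A tooth counts as having attachment loss when
#'   `cal_mm` is at least this (default 3 mm).
#' @param extent_fraction Localized/generalized cutoff on the affected
#'   fraction (default 0.30).
#' @return One-row tibble: `n_teeth_with_pockets`, `pocket_score`,
#'   `n_teeth_with_cal`, `cal_score`, `n_teeth_bleeding`, `n_teeth_plaque`.
#' @export
summarize_chart <- function(teeth, pocket_threshold_mm = 4,
                            cal_threshold_mm = 3, extent_fraction = 0.30) {
  stopifnot(pocket_threshold_mm > 0, cal_threshold_mm > 0,
            extent_fraction > 0, extent_fraction < 1)
  p <- teeth[teeth$present, , drop = FALSE]
  if (nrow(p) == 0) {
    abort("invalid chart: no present teeth", class = "periodx_invalid_record")
  }
  n_pockets <- sum(p$ppd_mm >= pocket_threshold_mm)
  n_cal <- sum(p$cal_mm >= cal_threshold_mm)
  tibble::tibble(
    n_teeth_with_pockets = n_pockets,
    pocket_score = as.integer(n_pockets / nrow(p) >= extent_fraction),
    n_teeth_with_cal = n_cal,
    cal_score = as.integer(n_cal / nrow(p) >= extent_fraction),
    n_teeth_bleeding = sum(p$bleeding),
    n_teeth_plaque = sum(p$plaque)
  )
}

#' Summarize all charts of a cohort
#'
#' @param cohort A `perio_cohort` tibble (or any tibble with `chart_number`
#'   and a `teeth` list-column).
#' @inheritParams summarize_chart
#' @return Tibble with `chart_number` plus the six chart-summary columns.
#' @export
summarize_charts <- function(cohort, pocket_threshold_mm = 4,
                             cal_threshold_mm = 3, extent_fraction = 0.30) {
  out <- purrr::map(cohort$teeth, summarize_chart,
                    pocket_threshold_mm = pocket_threshold_mm,
                    cal_threshold_mm = cal_threshold_mm,
                    extent_fraction = extent_fraction) |>
    purrr::list_rbind()
  dplyr::bind_cols(tibble::tibble(chart_number = cohort$chart_number), out)
}

#' Merge note features and chart summaries into one table
#'
#' Joins by chart number into the canonical 22-column layout. A note without
#' a matching chart (or vice versa) is kept with empty cells and triggers a
#' warning; a duplicated chart number is an error naming the duplicate.
#'
#' @param rows Note-feature tibble from [extract_notes()]; rows with a
#'   missing extracted chart number are dropped with a warning (they cannot
#'   be joined).
#' @param chart_summaries Tibble from [summarize_charts()].
#' @return Tibble with one row per patient and 22 columns in stable order.
#' @export
merge_to_table <- function(rows, chart_summaries) {
  stopifnot(is.data.frame(rows), is.data.frame(chart_summaries))
  if (anyNA(rows$chart_number)) {
    warn("dropping notes with no extractable chart number")
    rows <- rows[!is.na(rows$chart_number), , drop = FALSE]
  }
  for (tab in list(rows, chart_summaries)) {
    dup <- tab$chart_number[duplicated(tab$chart_number)]
    if (length(dup) > 0) {
      abort(glue::glue("duplicate chart number: {paste(unique(dup), collapse = ', ')}"))
    }
  }
  unmatched_notes <- setdiff(rows$chart_number, chart_summaries$chart_number)
  unmatched_charts <- setdiff(chart_summaries$chart_number, rows$chart_number)
  if (length(unmatched_notes) > 0) {
    warn(glue::glue("{length(unmatched_notes)} note(s) without a chart; chart-summary cells left empty"))
  }
  if (length(unmatched_charts) > 0) {
    warn(glue::glue("{length(unmatched_charts)} chart(s) without a note; note cells left empty"))
  }
  dplyr::full_join(rows, chart_summaries, by = "chart_number") |>
    dplyr::select(dplyr::all_of(feature_table_columns())) |>
    dplyr::arrange(.data$chart_number)
}

#' Write/read the feature table as CSV
#'
#' Missing cells are serialized as empty strings.
#'
#' @param table Feature table from [merge_to_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, na = "", show_col_types = FALSE,
                  col_types = readr::cols(date = readr::col_character(),
                                          .default = readr::col_integer()))
}
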