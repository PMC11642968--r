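# Pattern extraction, chart summarization and the merged feature table.

test_that("vitals and coded variables extract from canonical phrasings", {
  s <- default_schema()
  f <- extract_features("Chart number: 82. Visit date: 2019-10-18. BP: 132/78 mmHg, HR 72.", s)
  expect_equal(f$chart_number, 82L)
  expect_equal(f$date, "2019-10-18")
  expect_equal(f$systolic_bp, 132L)
  expect_equal(f$diastolic_bp, 78L)
  expect_equal(f$heart_rate, 72L)

  expect_equal(extract_features("HEAVY CALCULUS noted", s)$calculus, 3L)
  expect_equal(extract_features("tooth stain: medium", s)$stain, 2L)
  expect_equal(extract_features("Dx: stage III grade B periodontitis", s)$stage, 3L)
  expect_equal(extract_features("Dx: stage III grade B periodontitis", s)$grade, 2L)
})

test_that("missing information never raises and never fabricates", {
  s <- default_schema()
  f <- extract_features("Routine visit, no findings recorded beyond vitals.", s)
  expect_true(is.na(f$prior_surgery))
  expect_true(is.na(f$smoking))
  expect_length(attr(f, "offsets"), 0L)
  # every non-missing field is traceable to a character offset
  f2 <- extract_features("Chart no. 12. HR 70. Heavy calculus.", s)
  off <- attr(f2, "offsets")
  non_missing <- purrr::map_lgl(f2, ~ !is.na(.x))
  expect_setequal(names(off), names(f2)[non_missing])
  expect_true(all(off >= 1 & off <= nchar("Chart no. 12. HR 70. Heavy calculus.")))
})

test_that("extraction is case-invariant", {
  s <- default_schema()
  note <- small_notes()$text[1]
  a <- extract_features(note, s)
  b <- extract_features(toupper(note), s)
  attr(a, "offsets") <- NULL
  attr(b, "offsets") <- NULL
  expect_identical(a, b)
})

test_that("first match wins within a variable's ordered pattern list", {
  s <- default_schema()
  # negative phrasing listed first must beat the later positive pattern
  expect_equal(extract_features("Patient is a non-smoker.", s)$smoking, 0L)
  expect_equal(extract_features("Patient is a current smoker.", s)$smoking, 1L)
  expect_equal(extract_features("No previous FGG, GTR or GBR.", s)$prior_surgery, 0L)
  expect_equal(extract_features("Previous GTR surgery.", s)$prior_surgery, 1L)
})

test_that("chart summaries count present teeth and score extent", {
  teeth <- tibble::tibble(
    tooth_id = 1:28, present = TRUE,
    ppd_mm = c(rep(5L, 10), rep(2L, 18)),
    cal_mm = c(rep(4L, 6), rep(1L, 22)),
    bleeding = c(rep(TRUE, 23), rep(FALSE, 5)),
    plaque = FALSE, mobile = FALSE
  )
  s <- summarize_chart(teeth, pocket_threshold_mm = 4, cal_threshold_mm = 3,
                       extent_fraction = 0.30)
  expect_equal(s$n_teeth_with_pockets, 10L)
  expect_equal(s$pocket_score, 1L) # 10/28 = 0.357 >= 0.30
  expect_equal(s$n_teeth_with_cal, 6L)
  expect_equal(s$cal_score, 0L) # 6/28 = 0.214 < 0.30
  expect_equal(s$n_teeth_bleeding, 23L)

  none <- dplyr::mutate(teeth, ppd_mm = 1L, cal_mm = 0L, bleeding = FALSE)
  s0 <- summarize_chart(none)
  expect_equal(s0$n_teeth_with_pockets, 0L)
  expect_equal(s0$pocket_score, 0L)

  empty <- dplyr::mutate(teeth, present = FALSE)
  expect_error(summarize_chart(empty), class = "periodx_invalid_record")
})

test_that("merge produces the 22-column table and flags mismatches", {
  co <- small_cohort()[1:3, ]
  rows <- extract_notes(render_notes(co, seed = 11), default_schema())
  summaries <- summarize_charts(co)
  tbl <- merge_to_table(rows, summaries)
  expect_equal(dim(tbl), c(3L, 22L))
  expect_identical(names(tbl), feature_table_columns())

  # note without chart: row kept, chart-summary cells empty, with a warning
  expect_warning(tbl2 <- merge_to_table(rows, summaries[-1, ]),
                 "without a note|without a chart")
  expect_true(is.na(tbl2$n_teeth_bleeding[tbl2$chart_number == co$chart_number[1]]))
  expect_equal(nrow(tbl2), 3L)

  dup <- dplyr::bind_rows(rows, rows[1, ])
  expect_error(merge_to_table(dup, summaries),
               as.character(co$chart_number[1]))
})

test_that("feature table CSV round-trips with empty strings for missing", {
  co <- small_cohort()[1:4, ]
  notes <- render_notes(co, omission_rate = 0.5, seed = 12)
  tbl <- merge_to_table(extract_notes(notes, default_schema()),
                        summarize_charts(co))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tbl, path)
  raw <- readLines(path)
  expect_equal(length(raw), 5L)
  expect_false(any(grepl("NA", raw, fixed = TRUE)))
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl))
})

test_that("cohort files round-trip through write_cohort/read_cohort", {
  co <- small_cohort()[1:3, ]
  notes <- render_notes(co, seed = 13)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, notes, dir)
  expect_length(paths$charts, 3L)
  expect_length(paths$notes, 3L)
  back <- read_cohort(dir)
  expect_equal(back$labels$stage, co$stage)
  expect_equal(back$labels$grade, co$grade)
  expect_equal(back$notes$text, notes$text)
  expect_equal(back$charts$teeth, unclass(co$teeth), ignore_attr = TRUE)

  # empty cohort: labels.csv with header only
  dir2 <- withr::local_tempdir()
  write_cohort(co[0, ], NULL, dir2)
  expect_equal(length(readLines(file.path(dir2, "labels.csv"))), 1L)
})
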