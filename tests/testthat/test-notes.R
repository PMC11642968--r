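# Note rendering and its round-trip contract with extraction.

test_that("omission 0 notes mention every variable and round-trip exactly", {
  co <- small_cohort()
  notes <- small_notes()
  feats <- extract_notes(notes, default_schema())
  rec <- recovery_matrix(feats, note_truth(co))
  expect_true(all(rec))
})

test_that("omission 1 leaves only the chart number and date extractable", {
  co <- small_cohort()[1:5, ]
  notes <- render_notes(co, omission_rate = 1, seed = 7)
  feats <- extract_notes(notes, default_schema())
  expect_equal(feats$chart_number, co$chart_number)
  expect_equal(feats$date, as.character(co$visit_date))
  other <- setdiff(names(feats), c("chart_number", "date"))
  expect_true(all(is.na(as.matrix(feats[, other]))))
})

test_that("field recovery degrades monotonically with the omission rate", {
  co <- generate_cohort(200, seed = 31)
  truth <- note_truth(co)
  rates <- c(0, 0.25, 0.5, 1)
  recovered <- purrr::map_dbl(rates, function(r) {
    notes <- render_notes(co, omission_rate = r, case_jitter = TRUE,
                          seed = 32)
    mean(recovery_matrix(extract_notes(notes, default_schema()), truth))
  })
  expect_true(all(diff(recovered) <= 0))
  expect_equal(recovered[1], 1)
})

test_that("rendering is deterministic in the seed", {
  co <- small_cohort()[1:3, ]
  a <- render_notes(co, omission_rate = 0.3, case_jitter = TRUE, seed = 5)
  b <- render_notes(co, omission_rate = 0.3, case_jitter = TRUE, seed = 5)
  expect_identical(a, b)
})

test_that("a known blood-pressure phrase parses back to its numbers", {
  co <- small_cohort()[1, ]
  co$systolic_bp <- 132L
  co$diastolic_bp <- 78L
  co$heart_rate <- 72L
  note <- render_note(co, seed = 9)
  f <- extract_features(note, default_schema())
  expect_equal(f$systolic_bp, 132L)
  expect_equal(f$diastolic_bp, 78L)
  expect_equal(f$heart_rate, 72L)
})
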