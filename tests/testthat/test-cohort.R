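# Synthetic cohort generator: exact histograms, label consistency,
# determinism, measurement invariants.

test_that("requested class histograms are matched exactly", {
  co <- generate_cohort(309, stage_counts = c(6, 36, 206, 61),
                        grade_counts = c(19, 203, 87), seed = 3)
  expect_equal(as.integer(table(factor(co$stage, 1:4))), c(6, 36, 206, 61))
  expect_equal(as.integer(table(factor(co$grade, 1:3))), c(19, 203, 87))

  co4 <- generate_cohort(4, stage_counts = c(1, 1, 1, 1),
                         grade_counts = c(2, 1, 1), seed = 4)
  expect_equal(sort(co4$stage), 1:4)
})

test_that("infeasible distributions are configuration errors", {
  expect_error(generate_cohort(10, stage_counts = c(1, 1, 1, 1), seed = 1),
               class = "periodx_config_error")
  expect_error(generate_cohort(10, grade_counts = c(5, 5, 5), seed = 1),
               class = "periodx_config_error")
})

test_that("same seed gives byte-identical cohorts, different seed differs", {
  a <- generate_cohort(25, seed = 42)
  b <- generate_cohort(25, seed = 42)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c_ <- generate_cohort(25, seed = 43)
  expect_false(identical(a, c_))
})

test_that("stored labels agree with the rule engine on every record", {
  co <- small_cohort()
  expect_equal(assign_stage(co), co$stage)
  expect_equal(assign_grade(co), co$grade)
})

test_that("chart measurements respect their invariants", {
  co <- small_cohort()
  for (teeth in co$teeth) {
    present <- teeth[teeth$present, ]
    absent <- teeth[!teeth$present, ]
    expect_true(nrow(present) >= 8 && nrow(present) <= 32)
    expect_true(all(present$ppd_mm >= 0) && all(present$cal_mm >= 0))
    expect_true(all(is.na(absent$ppd_mm)) && all(is.na(absent$cal_mm)))
    expect_identical(teeth$tooth_id, 1:32)
  }
  expect_true(all(co$systolic_bp > co$diastolic_bp))
  expect_true(all(co$heart_rate >= 44 & co$heart_rate <= 118))
  expect_true(all(co$stain %in% 0:3 & co$calculus %in% 0:3 & co$plaque %in% 0:3))
  expect_true(all(co$bone_loss_percent >= 0 & co$bone_loss_percent <= 100))
})

test_that("cohort_features carries the label determinants", {
  co <- small_cohort()
  f <- cohort_features(co)
  expect_true(all(c(stage_determinants(), grade_determinants()) %in% names(f)))
  expect_equal(f$bone_loss_per_age, f$bone_loss_percent / f$age)
  # determinants reproduce labels through the rule cores
  r <- f$bone_loss_per_age
  base <- ifelse(r < 0.25, 1L, ifelse(r <= 1, 2L, 3L))
  expect_equal(pmin(base + (f$smoker | f$diabetic), 3L), f$grade)
})
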