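test_that("bundled cohort has the documented structure", {
  co <- bundled_cohort()
  expect_equal(nrow(co), 23)
  expect_equal(dplyr::n_distinct(co$patient_id), 19)
  expect_equal(sum(co$in_regimen_stats), 21)
  # multi-lesion patients: three lesions for 012, two each for 013 and 020
  counts <- dplyr::count(co, patient_id)
  expect_equal(counts$n[counts$patient_id == "012"], 3)
  expect_equal(counts$n[counts$patient_id %in% c("013", "020")], c(2, 2))
  # the two lesions excluded from regimen means
  excl <- dplyr::filter(co, !in_regimen_stats)
  expect_setequal(paste(excl$patient_id, excl$lesion_index), c("012 3", "020 1"))
  # not-measurable follow-up volumes are zero-coded
  expect_true(all(co$v_post_cm3[co$not_measurable] == 0))
  expect_setequal(co$patient_id[co$not_measurable], c("005", "014", "021", "022"))
})

test_that("per-fraction doses sum exactly to the printed total dose", {
  co <- bundled_cohort()
  for (i in seq_len(nrow(co))) {
    sch <- build_schedule(co[i, ])
    expect_identical(sch$fraction_dose * length(sch$pulse_starts),
                     co$total_dose_gy[i])
  }
})

test_that("cohort round-trips losslessly through CSV", {
  co <- bundled_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_equal(load_cohort(path), co, ignore_attr = TRUE)

  empty <- co[0, ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(empty, path2)
  expect_length(readLines(path2), 1)   # header only
})

test_that("validation errors name the offending row and field", {
  co <- bundled_cohort()

  bad <- co
  bad$v_pre_cm3[3] <- -1
  expect_error(validate_cohort(bad), "patient 003.*v_pre_cm3")

  bad <- co
  bad$treatment_days[[2]] <- c(1L, 3L)   # two days for four fractions
  expect_error(validate_cohort(bad), "patient 002.*2 treatment day\\(s\\) for 4 fraction")

  bad <- co
  bad$followup_days[1] <- 2              # before the last fraction (day 6)
  expect_error(validate_cohort(bad), "follow-up precedes")

  # missing column in the file
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(dplyr::mutate(co, treatment_days = "1"), -v_pre_cm3), path)
  expect_error(load_cohort(path), "missing column.*v_pre_cm3")

  # empty file: no partial cohort
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), path2)
  expect_error(load_cohort(path2), "empty|parse")
})

test_that("dose schedules follow the fraction calendar", {
  sch19 <- build_schedule(bundled_record("019"))
  expect_equal(length(sch19$pulse_starts), 1)
  expect_equal(sch19$fraction_dose, 34)
  expect_equal(sch19$treatment_duration, 1)

  sch01 <- build_schedule(bundled_record("001"))
  expect_equal(sch01$pulse_starts, c(0, 2, 5))
  expect_equal(sch01$fraction_dose, 18)
  expect_equal(sch01$treatment_duration, 6)

  expect_error(build_schedule(bundled_record("001"), pulse_width = 0), "positive")
  expect_error(build_schedule(bundled_record("001"), pulse_width = 1.2), "below one day")
  # sub-day fraction spacing would make wide pulses overlap
  rec <- bundled_record("001")
  rec$treatment_days[[1]] <- c(1L, 2L, 3L)
  sch <- build_schedule(rec, pulse_width = 0.5)
  expect_equal(sch$pulse_starts, c(0, 1, 2))
})

test_that("schedule forcing integrates to the total dose", {
  # with zero clearance x5 accumulates exactly the delivered dose
  p <- pkpd_params(cr = 0, etr = 0)
  for (id in c("001", "015", "019")) {
    rec <- bundled_record(id)
    traj <- simulate_lesion(rec, p, gamma = 0.1,
                            times = c(0, rec$followup_days))
    expect_equal(traj$x5[2], rec$total_dose_gy, tolerance = 1e-6)
  }
})
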