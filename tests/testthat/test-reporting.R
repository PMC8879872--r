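test_that("synth stage writes cohort, exponents and recovery summary", {
  out <- withr::local_tempdir()
  suppressMessages(run_synth(out, n_lesions = 4, seed = 21))
  expect_true(file.exists(file.path(out, "synthetic_cohort.csv")))
  expect_true(file.exists(file.path(out, "gamma_true.csv")))
  rec <- jsonlite::read_json(file.path(out, "recovery.json"))
  expect_true(all(c("median_abs_error", "max_abs_error", "fraction_within_0.02")
                  %in% names(rec)))
  # the generated cohort feeds back into calibration without error
  cal <- suppressMessages(run_calibrate(file.path(out, "synthetic_cohort.csv"),
                                        file.path(out, "cal")))
  expect_true(all(cal$converged))
  expect_true(all(cal$gamma_hat >= 1e-3 & cal$gamma_hat <= 1))
  expect_error(suppressMessages(run_synth(out, n_lesions = 4)), "seed")
})

test_that("calibrate stage is idempotent", {
  out <- withr::local_tempdir()
  gen <- generate_cohort(cohort_spec(2, seed = 13))
  path <- file.path(out, "cohort.csv")
  write_cohort(gen$cohort, path)
  suppressMessages(run_calibrate(path, file.path(out, "a")))
  suppressMessages(run_calibrate(path, file.path(out, "b")))
  expect_identical(readLines(file.path(out, "a", "calibration.csv")),
                   readLines(file.path(out, "b", "calibration.csv")))
  expect_error(suppressMessages(run_calibrate(path, out, overrides = list(bogus = 1))),
               "unknown parameter")
})

test_that("simulate stage writes one trajectory per lesion and needs exponents", {
  out <- withr::local_tempdir()
  gen <- generate_cohort(cohort_spec(2, seed = 13))
  cal <- calibrate_cohort(gen$cohort)
  files <- suppressMessages(run_simulate(gen$cohort, cal, out))
  expect_equal(nrow(files), 2)
  expect_true(all(file.exists(file.path(out, files$file))))
  tr <- readr::read_csv(file.path(out, files$file[1]), show_col_types = FALSE)
  expect_true(all(c("t_days", "x1_mm3", "x2_mm3", "x5", "xe5", "total_mm3",
                    "delta_v_mm3", "effect_per_day") %in% names(tr)))
  expect_error(suppressMessages(run_simulate(gen$cohort, NULL, out)), "gamma-file")
  # rerun is byte-identical
  out2 <- withr::local_tempdir()
  suppressMessages(run_simulate(gen$cohort, cal, out2))
  expect_identical(readLines(file.path(out, files$file[1])),
                   readLines(file.path(out2, files$file[1])))
})

test_that("report stage writes the documented JSON schema", {
  out <- withr::local_tempdir()
  co <- bundled_cohort()[c(1, 3, 19), ]
  cal <- calibrate_cohort(co)
  suppressMessages(run_report(co, out, calibration = cal, levels = c(0.1)))
  js <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_true(all(c("regimen_means", "response_counts", "regression",
                    "sensitivity_quartiles") %in% names(js)))
  expect_true(all(c("slope", "intercept", "r", "rmse_cm3", "n") %in% names(js$regression)))
  sens <- readr::read_csv(file.path(out, "sensitivity.csv"), show_col_types = FALSE)
  expect_equal(nrow(sens), 3)   # one row per (lesion, level)
  expect_true(file.exists(file.path(out, "efficacy.csv")))
})
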