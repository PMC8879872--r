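test_that("efficacy arithmetic and identities", {
  expect_equal(efficacy(10.5, 11), -4.7619, tolerance = 1e-4)
  expect_equal(efficacy(5.6, 4.6), 17.857, tolerance = 1e-4)
  expect_equal(efficacy(3, 3), 0)
  expect_equal(efficacy(3, 0), 100)
  # scale invariance
  expect_equal(efficacy(0.4 * 7, 0.1 * 7), efficacy(0.4, 0.1))
  expect_error(efficacy(0, 1), "v_pre")
})

test_that("regimen means are unweighted means over eligible lesions", {
  co <- bundled_cohort()
  reg <- regimen_efficacy(co)
  expect_equal(nrow(reg), 4)
  expect_equal(sum(reg$n_lesions), 21)
  # a single-lesion group's mean is that lesion's efficacy
  single <- dplyr::filter(reg, regimen == "60 Gy/8")
  expect_equal(single$mean_efficacy_pct, efficacy(10.5, 11))
  # a regimen whose lesions are all excluded is dropped with a warning
  co2 <- dplyr::mutate(co, in_regimen_stats = in_regimen_stats & total_dose_gy != 34)
  expect_warning(reg2 <- regimen_efficacy(co2), "34 Gy/1")
  expect_equal(nrow(reg2), 3)
})

test_that("response classification partitions the cohort", {
  co <- bundled_cohort()
  cls <- classify_responses(co)
  expect_equal(sum(cls$n), nrow(co))
  expect_equal(cls$n[cls$response_class == "stable_or_increased"], 3)
  co_zero <- dplyr::mutate(co, v_post_cm3 = 0, not_measurable = FALSE)
  cls0 <- classify_responses(co_zero)
  expect_equal(cls0$n[cls0$response_class == "stable_or_increased"], 0)
})

test_that("volume regression has its degenerate identities and is order-invariant", {
  co <- bundled_cohort()
  fake <- tibble::tibble(patient_id = co$patient_id, lesion_index = co$lesion_index,
                         v_sim_final = co$v_post_cm3, converged = TRUE)
  reg <- volume_regression(co, fake)
  expect_equal(reg$slope, 1)
  expect_equal(reg$r, 1)
  expect_equal(reg$rmse_cm3, 0)
  perm <- sample(nrow(co))
  expect_equal(volume_regression(co[perm, ], fake[perm, ]), reg)
  expect_error(volume_regression(co[1, ], fake[1, ]), "at least two")
})

test_that("zero perturbation leaves the final volume unchanged", {
  co <- bundled_cohort()[1, ]
  cal <- tibble::tibble(patient_id = co$patient_id, lesion_index = co$lesion_index,
                        gamma_hat = 0.05, converged = TRUE)
  sens <- sensitivity_analysis(co, cal, levels = c(0, 0.1))
  expect_equal(sens$pct_change_final[sens$perturbation == 0], 0)
  expect_gt(sens$pct_change_final[sens$perturbation == 0.1], 0)
})

test_that("relative normalisation makes the response exactly proportional to baseline", {
  # with burden normalised to its own baseline the system is scale-invariant,
  # so a fractional change of the initial volume propagates identically
  prel <- pkpd_params(normalization_mode = "relative")
  co <- bundled_cohort()[c(1, 7), ]
  cal <- tibble::tibble(patient_id = co$patient_id, lesion_index = co$lesion_index,
                        gamma_hat = c(0.03, 0.03), converged = TRUE)
  sens <- sensitivity_analysis(co, cal, prel, levels = c(0.05, 0.2))
  expect_equal(sens$pct_change_final, 100 * sens$perturbation, tolerance = 1e-5)
})

test_that("outcomes report carries every section", {
  co <- bundled_cohort()[c(1, 6), ]
  cal <- calibrate_cohort(co)
  rep <- outcomes_report(co, cal, levels = c(0.1))
  expect_named(rep, c("regimen_means", "response_counts", "regression",
                      "sensitivity_quartiles", "sensitivity"))
  expect_equal(nrow(rep$sensitivity), 2)
  expect_true(all(c("q25", "median", "q75") %in% names(rep$sensitivity_quartiles)))
})
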