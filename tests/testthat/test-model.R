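test_that("normalisation and interaction arithmetic", {
  expect_equal(normalized_dose(0, 20), 0)
  expect_equal(normalized_dose(20, 20), 1)
  expect_equal(normalized_dose(34, 20), 1.7)
  expect_error(normalized_dose(1, 0), "c50r")

  p <- pkpd_params()
  expect_equal(normalized_tumor(250, 250, 1000, p), 1)     # 500 mm^3 half-effect
  expect_equal(normalized_tumor(0, 0, 1000, p), 0)
  prel <- pkpd_params(normalization_mode = "relative")
  expect_equal(normalized_tumor(600, 400, 1000, prel), 2)  # 100% of baseline / 50
  expect_error(normalized_tumor(1, 1, 0, prel), "v0")

  expect_equal(interaction_index(1, 1, 8), 10)
  expect_equal(interaction_index(0.37, 0, 8), 0.37)        # no dose: index = burden
  expect_equal(interaction_index(0, 0, 8), 0)
})

test_that("Hill curve has its defining properties", {
  for (g in c(0.043, 0.1, 0.25, 1)) expect_equal(hill_effect(1, g), 0.5)
  expect_equal(hill_effect(0, 0.25), 0)
  expect_equal(hill_effect(10, 0.25), 0.6401, tolerance = 1e-4)
  i <- c(0, 10^seq(-3, 12, by = 0.5))
  h <- hill_effect(i, 0.15)
  expect_true(all(diff(h) > 0))            # strictly increasing
  expect_true(all(h >= 0 & h < 1))         # into [0, 1)
  expect_error(hill_effect(-1, 0.25), ">=")
  expect_error(hill_effect(1, 0), "gamma")
})

test_that("combined effect is exposure-gated and bounded", {
  p <- pkpd_params()
  expect_equal(combined_effect(0, 0, p, gamma = 0.1), 0)
  # without radiotherapy exposure there is no treatment effect
  expect_equal(combined_effect(5, 0, p, gamma = 0.1), 0)
  # at the half-effect interaction index the kill rate is emaxr/100 per day
  expect_equal(combined_effect(0, 1, p, gamma = 0.25), 0.5)
  e <- combined_effect(seq(0, 50, by = 5), rep(2, 11), p, gamma = 0.3)
  expect_true(all(e < p$emaxr / 50))
  # doubling exposure never decreases the effect
  e2 <- combined_effect(seq(0, 50, by = 5), rep(4, 11), p, gamma = 0.3)
  expect_true(all(e2 >= e))
})

test_that("zero-dose dynamics match the linear closed forms", {
  rec <- untreated_record(v_pre_cm3 = 1, followup = 30)
  traj <- simulate_lesion(rec, pkpd_params(), gamma = 0.15, times = 0:30)
  a <- 0.693; n <- 0.10
  x1_ref <- 1000 * exp((a - n) * traj$t_days)
  x2_ref <- 1000 * (n / (a - n)) * (exp((a - n) * traj$t_days) - 1)
  expect_equal(traj$x1, x1_ref, tolerance = 1e-6)
  expect_equal(traj$x2, x2_ref, tolerance = 1e-6)
  # spot values on day 1
  expect_equal(traj$x1[2], 1809.4, tolerance = 1e-4)
  expect_equal(traj$x2[2], 136.5, tolerance = 1e-3)
  # growth identity: d(x1+x2)/dt = a*x1, so total growth stays below e^(a t)
  expect_true(all(traj$total_mm3 <= 1000 * exp(a * traj$t_days) + 1e-6))
})

test_that("radiotherapy level decays exponentially after a bolus", {
  rec <- bundled_record("019")           # single 34 Gy fraction
  p <- pkpd_params(cr = 0.5)
  traj <- simulate_lesion(rec, p, gamma = 0.1, times = c(0, 1, 2, 4))
  ratios <- traj$x5[3:4] / traj$x5[2:3]
  expect_equal(ratios, exp(-0.5 * c(1, 2)), tolerance = 1e-6)
})

test_that("trajectory satisfies its pointwise identities", {
  rec <- bundled_record("008")
  traj <- simulate_lesion(rec, gamma = 0.05)
  expect_true(all(diff(traj$t_days) > 0))
  expect_equal(traj$total_mm3, traj$x1 + traj$x2)
  expect_equal(traj$delta_v_mm3, traj$x1)
  expect_true(all(as.matrix(traj[, c("x1", "x2", "x5", "xe5")]) >= 0))
  # reported series selection
  ptot <- pkpd_params(reported_volume = "total")
  traj2 <- simulate_lesion(rec, ptot, gamma = 0.05, times = c(0, 10))
  expect_equal(traj2$reported_mm3, traj2$total_mm3)
})

test_that("zero state is an equilibrium and effect responds to dose rate", {
  rec <- bundled_record("001")
  # doubling the total dose (same calendar) never increases the final volume
  rec2 <- rec; rec2$total_dose_gy <- rec$total_dose_gy * 2
  for (g in c(0.02, 0.05, 0.1, 0.3)) {
    f1 <- simulate_lesion(rec, gamma = g, times = c(0, rec$followup_days))
    f2 <- simulate_lesion(rec2, gamma = g, times = c(0, rec$followup_days))
    expect_lte(f2$reported_mm3[2], f1$reported_mm3[2])
    e1 <- simulate_lesion(rec, gamma = g)$effect_per_day
    e2 <- simulate_lesion(rec2, gamma = g)$effect_per_day
    expect_true(all(e2 >= e1 - 1e-12))   # pointwise effect non-decreasing in dose
  }
})

test_that("integration is converged with respect to tolerance refinement", {
  rec <- bundled_record("015")
  for (g in c(0.04, 0.1)) {
    f1 <- simulate_lesion(rec, pkpd_params(rtol = 1e-8, atol = 1e-8),
                          gamma = g, times = c(0, rec$followup_days))$reported_mm3[2]
    f2 <- simulate_lesion(rec, pkpd_params(rtol = 1e-10, atol = 1e-10),
                          gamma = g, times = c(0, rec$followup_days))$reported_mm3[2]
    expect_equal(f1, f2, tolerance = 1e-3)   # < 0.1 %
  }
})

test_that("parameter containers validate and round-trip through YAML", {
  expect_error(pkpd_params(c50r = -1), "c50r")
  expect_error(pkpd_params(emaxr = 0), "emaxr")
  expect_error(pkpd_params(gamma = -0.1), "gamma")
  p <- pkpd_params(washout = 0.02, normalization_mode = "relative")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_params(p, path)
  expect_equal(read_params(path), p)
  writeLines("nonsense_key: 3", path)
  expect_error(read_params(path), "unknown parameter")
})
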