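test_that("the same spec and seed reproduce the cohort exactly", {
  spec <- cohort_spec(n_patients = 3, seed = 17)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(cohort_spec(n_patients = 3, seed = 18))
  expect_false(identical(a$measurements, c2$measurements))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(400)
  x <- runif(1)
  set.seed(400)
  invisible(generate_cohort(cohort_spec(n_patients = 2, seed = 5)))
  expect_identical(runif(1), x)
})

test_that("noise-free cohorts lie exactly on their ground-truth curves", {
  spec <- cohort_spec(n_patients = 3, vois = c(LK = 1, S = 1.48),
                      noise_cv = 0, inter_cycle_amplitude_cv = 0, seed = 2)
  coh <- generate_cohort(spec)
  for (i in seq_len(nrow(coh$measurements))) {
    row <- coh$measurements[i, ]
    tr <- coh$truth[coh$truth$patient_id == row$patient_id &
                      coh$truth$cycle_id == row$cycle_id &
                      coh$truth$voi == row$voi, ]
    p <- triexp_params(omega2 = tr$omega2, omega3 = tr$omega3,
                       k1 = tr$k1, k2 = tr$k2, k3 = tr$k3, lam = tr$lam)
    expect_equal(row$odr_mGy_per_s,
                 evaluate_tdrc(p, row$t_hours * 3600), tolerance = 1e-12)
  }
})

test_that("stored true doses equal the closed-form integral bit for bit", {
  coh <- generate_cohort(cohort_spec(n_patients = 4, seed = 31))
  for (i in seq_len(nrow(coh$truth))) {
    tr <- coh$truth[i, ]
    p <- triexp_params(omega2 = tr$omega2, omega3 = tr$omega3, k1 = tr$k1,
                       k2 = tr$k2, k3 = tr$k3, lam = tr$lam)
    expect_identical(tr$true_dose_Gy, integrate_tdrc(p))
  }
})

test_that("schedules, late-slot alternation and missingness are honored", {
  miss <- data.frame(patient_id = "P01", cycle_id = 1L, slot = "24H")
  spec <- cohort_spec(n_patients = 4, vois = c(LK = 1), missing = miss,
                      seed = 9)
  coh <- generate_cohort(spec)
  m <- coh$measurements
  # cycle 1 has EARLY/24H/LATE (minus the masked row), later cycles 24H only
  expect_setequal(m$slot[m$cycle_id > 1], "24H")
  p1c1 <- m[m$patient_id == "P01" & m$cycle_id == 1, ]
  expect_setequal(p1c1$slot, c("EARLY", "LATE"))
  p2c1 <- m[m$patient_id == "P02" & m$cycle_id == 1, ]
  expect_setequal(p2c1$slot, c("EARLY", "24H", "LATE"))
  # 96/144 alternation by patient
  late1 <- m$t_hours[m$patient_id == "P01" & m$slot == "LATE"]
  late2 <- m$t_hours[m$patient_id == "P02" & m$slot == "LATE"]
  expect_true(all(abs(late1 / 96 - 1) <= 0.15 + 1e-9))
  expect_true(all(abs(late2 / 144 - 1) <= 0.15 + 1e-9))
  # exact times jittered around the nominal slots
  t24 <- m$t_hours[m$slot == "24H"]
  expect_true(all(t24 >= 24 * 0.85 & t24 <= 24 * 1.15))
})

test_that("24 h ODR variation coefficients sit in the configured band", {
  spec <- cohort_spec(n_patients = 20, vois = c(LK = 1, RK = 1.1),
                      seed = 77)
  coh <- generate_cohort(spec)
  m <- coh$measurements[coh$measurements$slot == "24H", ]
  cvs <- c()
  for (pid in unique(m$patient_id)) for (voi in unique(m$voi)) {
    sub <- m[m$patient_id == pid & m$voi == voi, ]
    if (nrow(sub) >= 2) {
      cvs <- c(cvs, odr_variation_coefficient(sub$odr_mGy_per_s,
                                              sub$injected_MBq))
    }
  }
  # inter-cycle amplitude CV 10% + 5% noise + time jitter: medians in the
  # 5-20% band
  expect_gt(median(cvs), 5)
  expect_lt(median(cvs), 20)
})

test_that("inter-cycle amplitude variability converges to the spec CV", {
  spec <- cohort_spec(n_patients = 500, vois = c(LK = 1), n_cycles = 4,
                      noise_cv = 0, rate_cv = 0, shape_cv = 0,
                      inter_cycle_amplitude_cv = 0.10,
                      activity_sd_MBq = 0, seed = 55)
  coh <- generate_cohort(spec)
  tr <- coh$truth
  cvs <- vapply(split(tr$omega2, tr$patient_id),
                function(x) sd(x) / mean(x), numeric(1))
  expect_equal(mean(cvs), 0.10, tolerance = 0.20)
})

test_that("per-cycle organ doses land in the clinical magnitude bands", {
  coh <- generate_cohort(cohort_spec(n_patients = 30, seed = 8))
  tr <- coh$truth
  med <- tapply(tr$true_dose_Gy, tr$voi, median)
  expect_gt(med[["LK"]], 1.5); expect_lt(med[["LK"]], 6)
  expect_gt(med[["L"]], 2); expect_lt(med[["L"]], 9)
  expect_gt(med[["L2L4"]], 0.1); expect_lt(med[["L2L4"]], 0.8)
  # 24 h kidney ODR near 0.01 mGy/s, the scale the fit tolerance of
  # 1e-5 mGy/s is a thousandth of
  m24 <- coh$measurements[coh$measurements$slot == "24H" &
                            coh$measurements$voi == "LK", ]
  expect_gt(median(m24$odr_mGy_per_s), 0.003)
  expect_lt(median(m24$odr_mGy_per_s), 0.03)
})

test_that("conserved-kinetics constructor scales cycles exactly", {
  pat <- make_conserved_kinetics_patient(base_truth(),
                                         cycle_scales = c(1, 1),
                                         schedule_hours = list(c(1, 24, 96),
                                                               c(1, 24, 96)))
  m1 <- pat$measurements[pat$measurements$cycle_id == 1, ]
  m2 <- pat$measurements[pat$measurements$cycle_id == 2, ]
  expect_equal(m1$odr_mGy_per_s, m2$odr_mGy_per_s)     # scale 1: identical
  pat2 <- make_conserved_kinetics_patient(base_truth(),
                                          cycle_scales = c(1, 0.5))
  expect_equal(pat2$truth$true_dose_Gy[2], pat2$truth$true_dose_Gy[1] / 2)
  expect_error(make_conserved_kinetics_patient(base_truth(), c(1, -1)),
               class = "cohort_spec_error")
})

test_that("phantom organs recover their assigned values through masks", {
  ph <- generate_phantom(organs = list(
    list(label = "LK", center_mm = c(60, 60, 60), radii_mm = c(20, 16, 18),
         value = 3.2)))
  vol <- scalar_volume(ph$volume$values, ph$volume$spacing, unit = "mGy/s")
  expect_equal(compute_odr(vol, ph$masks$LK), 3.2)
  ph2 <- generate_phantom(organs = list(
    list(label = "A", center_mm = c(40, 40, 40), radii_mm = c(12, 12, 12),
         value = 1),
    list(label = "B", center_mm = c(90, 90, 90), radii_mm = c(14, 10, 12),
         value = 2)))
  v2 <- scalar_volume(ph2$volume$values, ph2$volume$spacing, unit = "mGy/s")
  expect_equal(compute_odr(v2, ph2$masks$A), 1)
  expect_equal(compute_odr(v2, ph2$masks$B), 2)
  expect_error(generate_phantom(organs = list(
    list(label = "X", center_mm = c(200, 40, 40), radii_mm = c(30, 10, 10),
         value = 1))), class = "cohort_spec_error")
  expect_error(generate_phantom(organs = list(
    list(label = "X", center_mm = c(40, 40, 40), radii_mm = c(0, 10, 10),
         value = 1))), class = "cohort_spec_error")
})
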