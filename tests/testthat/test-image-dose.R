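test_that("counts convert to activity through the sensitivity factor", {
  # 6840 counts over 900 s = 7.6 cps; at 7.6 cps/MBq that is 1 MBq
  v <- scalar_volume(array(6840, c(1, 1, 1)), spacing = c(10, 10, 10),
                     unit = "counts")
  cal <- calibration_config(7.6, duration_s = 900)
  res <- counts_to_activity(v, cal)
  expect_equal(res$total_MBq, 1)
  expect_equal(res$volume$unit, "MBq/mL")
  expect_equal(res$volume$values[1], 1)     # 1 MBq in a 1 mL voxel

  # zero counts -> zero activity; doubling sensitivity halves activity
  z <- scalar_volume(array(0, c(3, 3, 3)), spacing = c(4, 4, 4),
                     unit = "counts")
  expect_equal(counts_to_activity(z, cal)$total_MBq, 0)
  res2 <- counts_to_activity(v, calibration_config(15.2, duration_s = 900))
  expect_equal(res2$total_MBq, res$total_MBq / 2)

  # unit propagation: a dose-rate map cannot be calibrated as counts
  bad <- scalar_volume(array(1, c(2, 2, 2)), spacing = c(4, 4, 4),
                       unit = "mGy/s")
  expect_error(counts_to_activity(bad, cal), class = "unit_error")
})

test_that("paralyzable dead-time correction inverts the forward model", {
  tau <- 1.87e-6
  # fixed-point oracle on n = m * exp(tau * n), frozen after convergence
  m <- 10000
  n_oracle <- m
  for (i in 1:200) n_oracle <- m * exp(tau * n_oracle)
  n <- deadtime_correct(m, tau)
  expect_equal(n, n_oracle, tolerance = 1e-9)
  expect_equal(n, 1.0192e4, tolerance = 1e-4)
  expect_gte(n, m)

  # tau = 0 is the identity; round-trip with the forward model
  expect_identical(deadtime_correct(m, 0), m)
  set.seed(31)
  true_rates <- runif(30, 0, 1.5e5)
  obs <- deadtime_observe(true_rates, tau)
  expect_equal(deadtime_correct(obs, tau), true_rates, tolerance = 1e-9)

  # correction factor monotone increasing in the observed rate
  ms <- seq(1000, 150000, length.out = 40)
  fac <- deadtime_correct(ms, tau) / ms
  expect_true(all(diff(fac) > 0))

  # saturation branch
  expect_error(deadtime_correct(exp(-1) / tau * 1.01, tau),
               class = "deadtime_saturation_error")
  # non-paralyzable option
  expect_equal(deadtime_correct(1000, 1e-6, model = "nonparalyzable"),
               1000 / (1 - 1e-3))
})

test_that("dose-rate map scaling is linear in the total activity", {
  u <- scalar_volume(array(runif(27), c(3, 3, 3)), spacing = c(4, 4, 4),
                     unit = "mGy/s per MBq")
  expect_equal(scale_dose_rate_map(u, 0)$values, array(0, c(3, 3, 3)))
  m1 <- scale_dose_rate_map(u, 2500)
  m2 <- scale_dose_rate_map(u, 5000)
  expect_equal(m2$values, 2 * m1$values)
  expect_equal(m1$values, u$values * 2500)   # elementwise oracle
  expect_equal(m1$unit, "mGy/s")
  expect_error(scale_dose_rate_map(u, -1), class = "tdrc_domain_error")
  wrong <- scalar_volume(u$values, u$spacing, unit = "mGy/s")
  expect_error(scale_dose_rate_map(wrong, 1), class = "unit_error")
})

test_that("ODR equals the naive voxel-loop mean over the mask", {
  # trivial 3-voxel case
  vals <- array(0, c(3, 1, 1)); vals[, 1, 1] <- c(1, 2, 3)
  map <- scalar_volume(vals, spacing = c(4, 4, 4), unit = "mGy/s")
  msk <- voi_mask(array(TRUE, c(3, 1, 1)), "LK", spacing = c(4, 4, 4))
  expect_equal(compute_odr(map, msk), 2)

  # random phantom vs explicit loop
  set.seed(8)
  ph <- generate_phantom(dim_vox = c(24, 20, 18),
                         spacing_mm = c(4.4, 4.4, 4.4),
                         organs = list(
                           list(label = "LK", center_mm = c(40, 40, 35),
                                radii_mm = c(18, 14, 16), value = 2.5),
                           list(label = "S", center_mm = c(75, 55, 45),
                                radii_mm = c(12, 10, 12), value = 4)),
                         unit = "MBq/mL")
  noisy <- scalar_volume(ph$volume$values +
                           array(rnorm(prod(dim(ph$volume$values)), 0, .1),
                                 dim(ph$volume$values)),
                         spacing = ph$volume$spacing, unit = "mGy/s")
  for (lbl in names(ph$masks)) {
    acc <- 0; n <- 0
    d <- dim(noisy$values)
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      if (ph$masks[[lbl]]$values[i, j, k]) {
        acc <- acc + noisy$values[i, j, k]; n <- n + 1
      }
    }
    expect_equal(compute_odr(noisy, ph$masks[[lbl]]), acc / n)
  }

  # uniform map returns the constant for any mask
  u <- scalar_volume(array(0.7, c(24, 20, 18)), spacing = c(4.4, 4.4, 4.4),
                     unit = "mGy/s")
  expect_equal(compute_odr(u, ph$masks$LK), 0.7)

  # invariant to padding outside the mask
  padded <- noisy
  padded$values[!ph$masks$LK$values & !ph$masks$S$values] <- 99
  expect_equal(compute_odr(padded, ph$masks$LK),
               compute_odr(noisy, ph$masks$LK))
})

test_that("maps are resampled trilinearly onto the mask grid", {
  # a linear field is reproduced exactly by trilinear interpolation
  d <- c(10, 10, 10)
  cx <- (seq_len(d[1]) - 1) * 4
  f <- function(x, y, z) 0.1 + 0.02 * x + 0.01 * y - 0.005 * z
  vals <- outer(outer(0.02 * cx, 0.01 * cx, `+`), -0.005 * cx, `+`) + 0.1
  map <- scalar_volume(vals, spacing = c(4, 4, 4), unit = "mGy/s")
  # mask grid at half spacing, interior
  md <- c(8, 8, 8)
  msk_vals <- array(FALSE, md); msk_vals[3:6, 3:6, 3:6] <- TRUE
  msk <- voi_mask(msk_vals, "LK", spacing = c(2, 2, 2), origin = c(6, 6, 6))
  got <- compute_odr(map, msk)
  idx <- which(msk_vals, arr.ind = TRUE)
  world <- sweep((idx - 1) * 2, 2, c(6, 6, 6), `+`)
  expect_equal(got, mean(f(world[, 1], world[, 2], world[, 3])),
               tolerance = 1e-12)
  # a mask grid extending beyond the map gets the outside fill value (0)
  far <- voi_mask(array(TRUE, c(2, 2, 2)), "X", spacing = c(1000, 1, 1))
  expect_true(is.finite(compute_odr(map, far)))
})

test_that("local deposition converts concentration to dose rate analytically", {
  # single hot voxel closed form: 1 MBq/mL, 148 keV/decay, 1 g/mL
  # 1e6 decay/s/mL * 2.37e-14 J / 1e-3 kg = 2.37e-5 Gy/s = 2.37e-2 mGy/s
  a <- array(0, c(4, 4, 4)); a[2, 2, 2] <- 1
  act <- scalar_volume(a, spacing = c(10, 10, 10), unit = "MBq/mL")
  ld <- local_deposition_map(act)
  expect_equal(ld$map_mGy_s$values[2, 2, 2], 2.37e-2, tolerance = 1e-12)
  expect_equal(ld$total_MBq, 1)              # 1 MBq/mL in a 1 mL voxel
  expect_equal(ld$unit_map$unit, "mGy/s per MBq")
  # zero map and linearity
  z <- scalar_volume(array(0, c(2, 2, 2)), spacing = c(4, 4, 4),
                     unit = "MBq/mL")
  expect_true(all(local_deposition_map(z)$map_mGy_s$values == 0))
  act2 <- scalar_volume(2 * a, spacing = c(10, 10, 10), unit = "MBq/mL")
  expect_equal(local_deposition_map(act2)$map_mGy_s$values,
               2 * ld$map_mGy_s$values)
  # scaled-back round trip through the unit map
  back <- scale_dose_rate_map(ld$unit_map, ld$total_MBq)
  expect_equal(back$values, ld$map_mGy_s$values)
  expect_error(local_deposition_map(act, mean_energy_J = 0),
               class = "calibration_error")
})

test_that("volumes round-trip through NIfTI and MetaImage", {
  v <- scalar_volume(array(runif(5 * 4 * 3), c(5, 4, 3)),
                     spacing = c(4.4, 4.4, 4.4), origin = c(1.5, -2, 3),
                     unit = "mGy/s")
  fn <- tempfile(fileext = ".nii.gz")
  write_volume(v, fn)
  v2 <- read_volume(fn, unit = "mGy/s")
  expect_identical(v2$values, v$values)            # double datatype
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)  # float32 pixdim
  expect_identical(v2$origin, v$origin)

  fm <- tempfile(fileext = ".mhd")
  write_volume(v, fm)
  v3 <- read_volume(fm, unit = "mGy/s")
  expect_identical(v3$values, v$values)
  expect_identical(v3$spacing, v$spacing)          # text header, bit-exact
  expect_identical(v3$origin, v$origin)

  m <- voi_mask(array(rep(c(TRUE, FALSE), 30), c(5, 4, 3)), "LK",
                spacing = c(4.4, 4.4, 4.4))
  fm2 <- tempfile(fileext = ".mhd")
  write_volume(m, fm2)
  m2 <- read_mask(fm2, "LK")
  expect_identical(m2$values, m$values)
  unlink(c(fn, fm, sub("mhd$", "raw", fm), fm2, sub("mhd$", "raw", fm2)))
})
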