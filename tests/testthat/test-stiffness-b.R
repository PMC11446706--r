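test_that("principal axis of a z-aligned cylinder is (0,0,1)", {
  lm <- make_labelmap(tiny_spec())
  ax <- principal_axis(lm, "m1")
  expect_equal(ax$direction, c(0, 0, 1), tolerance = 1e-6)
  expect_gt(ax$elongation, 1.5)
  expect_false(ax$qc_isotropic)
  expect_error(principal_axis(lm, "nope"), "not found")
})

test_that("principal axis recovers a rotated ellipsoid axis within 1 degree", {
  theta <- 30 * pi / 180
  d <- c(0, sin(theta), cos(theta))
  spec <- phantom_spec(
    shape = c(8, 64, 96), spacing = c(10, 1.5, 1.5),
    compartments = list(
      muscle_compartment("ell", shape = "ellipsoid", center = c(40, 48, 72),
                         axis = d, semiaxes = c(40, 10, 10), pdff = 0.1,
                         stiffness_kpa = 3)),
    dixon_noise_sd = 0, wave_noise_sd = 0, oblique_fraction = 0,
    outlier_fraction = 0, invalid_fraction = 0)
  ax <- principal_axis(make_labelmap(spec), "ell")
  angle <- acos(min(abs(sum(ax$direction * d)), 1)) * 180 / pi
  expect_lt(angle, 1)
})

test_that("a near-spherical muscle raises the isotropy QC flag", {
  spec <- phantom_spec(
    shape = c(8, 48, 48), spacing = c(10, 1.5, 1.5),
    compartments = list(
      muscle_compartment("ball", shape = "ellipsoid", center = c(40, 36, 36),
                         semiaxes = c(16, 16, 16), pdff = 0.1,
                         stiffness_kpa = 3)),
    dixon_noise_sd = 0, wave_noise_sd = 0, oblique_fraction = 0,
    outlier_fraction = 0, invalid_fraction = 0)
  ax <- principal_axis(make_labelmap(spec), "ball")
  expect_true(ax$qc_isotropic)
  expect_lt(ax$elongation, 1.5)
})

test_that("slice selection maximizes muscle-measurement overlap deterministically", {
  labels <- array(0L, c(12, 8, 8))
  cross_section <- c(0, 0, 4, 8, 16, 30, 16, 8, 8, 4, 0, 0)  # peak at slice 6
  for (s in 1:12) if (cross_section[s] > 0)
    labels[s, , ][seq_len(cross_section[s])] <- 1L
  lm <- mre_labelmap(labels, data.frame(label = 1, muscle = "m"),
                     spacing = c(10, 1.5, 1.5))
  expect_identical(select_slice(lm, "m"), 6L)
  # knocking out slice 6 moves to the next-largest overlap
  measurable <- array(TRUE, dim(labels)); measurable[6, , ] <- FALSE
  expect_identical(select_slice(lm, "m", measurable), 5L)  # tie 5/7 -> lowest
  # single-slice muscle returns that slice
  single <- array(0L, c(12, 8, 8)); single[9, 1:3, 1:3] <- 1L
  lms <- mre_labelmap(single, data.frame(label = 1, muscle = "m"))
  expect_identical(select_slice(lms, "m"), 9L)
  # zero overlap everywhere -> missing with QC attribute
  none <- select_slice(lm, "m", array(FALSE, dim(labels)))
  expect_true(is.na(none))
  expect_identical(attr(none, "qc"), "no_overlap")
})

test_that("profile extraction reproduces an analytic in-slice sinusoid", {
  spec <- tiny_spec()
  lm <- make_labelmap(spec)
  zw <- (seq_len(96) - 1) * 1.5
  wave <- mre_volume(
    aperm(array(rep(sin(2 * pi * zw / 30), each = 8 * 32), c(8, 32, 96)),
          c(1, 2, 3)),
    affine = lm$affine)
  ax <- principal_axis(lm, "m1")
  prof <- extract_profile(wave, 5, ax, lm, "m1")
  zs <- prof$centroid[3] + prof$positions * prof$direction[3]
  expected <- sin(2 * pi * zs / 30)
  expected <- expected - mean(expected)
  expect_gt(length(prof$values), 50)
  expect_lt(max(abs(prof$values - expected)), 1e-6)
  # constant image detrends to zeros
  const <- mre_volume(array(3, dim(lm$labels)), affine = lm$affine)
  pc <- extract_profile(const, 5, ax, lm, "m1")
  expect_lt(max(abs(pc$values)), 1e-12)
})

test_that("the longest contiguous in-muscle run is selected", {
  labels <- array(0L, c(4, 9, 60))
  labels[2, 3:7, 5:20] <- 1L   # 16-sample run
  labels[2, 3:7, 30:55] <- 1L  # 26-sample run (longer)
  lm <- mre_labelmap(labels, data.frame(label = 1, muscle = "m"),
                     spacing = c(10, 1.5, 1.5))
  ax <- principal_axis(lm, "m")
  wave <- mre_volume(array(rnorm(prod(dim(labels))), dim(labels)),
                     affine = lm$affine)
  prof <- extract_profile(wave, 2, ax, lm, "m")
  zs <- prof$centroid[3] + prof$positions * prof$direction[3]
  expect_true(all(zs > 29 * 1.5 - 1e-6))  # all samples in the later run
})

test_that("dominant wavelength finds the strongest spectral component", {
  x <- (0:127) * 1.5
  prof <- list(positions = x, values = sin(2 * pi * x / 30))
  expect_equal(dominant_wavelength(prof), 30, tolerance = 0.025)
  # larger-amplitude component wins on power
  two <- list(positions = x,
              values = 2 * sin(2 * pi * x / 24) + sin(2 * pi * x / 40))
  expect_equal(dominant_wavelength(two), 24, tolerance = 0.025)
  # sign flip and DC offset leave the estimate unchanged
  expect_identical(dominant_wavelength(prof),
                   dominant_wavelength(list(positions = x,
                                            values = -prof$values + 5)))
  expect_error(
    dominant_wavelength(list(positions = cumsum(runif(32, 0.5, 1.5)),
                             values = rnorm(32))),
    "uniformly spaced")
})

test_that("wavelengths beyond the 50 mm cutoff are rejected as artefacts", {
  x <- (0:127) * 1.5
  res <- dominant_wavelength(list(positions = x,
                                  values = sin(2 * pi * x / 60)))
  expect_true(is.na(res))
  expect_identical(attr(res, "qc"), "artefact")
  # custom cutoff is honoured
  expect_equal(dominant_wavelength(list(positions = x,
                                        values = sin(2 * pi * x / 60)),
                                   max_wavelength_mm = 80),
               60, tolerance = 0.1)
})

test_that("8-phase averaging recovers the implanted wavelength and handles dropouts", {
  spec <- tiny_spec(stiffness_kpa = 3.24)  # lambda = 30 mm
  lm <- make_labelmap(spec)
  ws <- simulate_waves(lm, spec)
  ax <- principal_axis(lm, "m1")
  sl <- select_slice(lm, "m1")
  est <- wavelength_over_phases(ws, sl, ax, lm, "m1")
  expect_identical(est$n_valid_phases, 8L)
  expect_equal(est$mean_wavelength_mm, 30, tolerance = 0.35)
  # opposite phases give identical wavelengths (|FFT| sign invariance)
  expect_equal(est$lambda_mm[1], est$lambda_mm[5], tolerance = 1e-12)
  expect_equal(est$lambda_mm[2], est$lambda_mm[6], tolerance = 1e-12)

  # artefact phases are dropped; mean over the survivors with a QC note
  ws_bad <- ws
  zw <- (seq_len(96) - 1) * 1.5
  flat60 <- array(rep(sin(2 * pi * zw / 60), each = 8 * 32), c(8, 32, 96))
  for (k in 6:8) ws_bad$values[, , , k] <- flat60
  est5 <- wavelength_over_phases(ws_bad, sl, ax, lm, "m1")
  expect_identical(est5$n_valid_phases, 5L)
  expect_true("phases_dropped" %in% est5$qc)
  expect_equal(est5$mean_wavelength_mm, mean(est5$lambda_mm[1:5]))
  # fewer than 4 valid phases -> missing estimate
  for (k in 3:8) ws_bad$values[, , , k] <- flat60
  est2 <- wavelength_over_phases(ws_bad, sl, ax, lm, "m1")
  expect_true(is.na(est2$mean_wavelength_mm))
  expect_true(is.na(est2$stiffness_kpa))
  expect_true("insufficient_phases" %in% est2$qc)
})

test_that("stiffness formula mu = rho (f lambda)^2 in kPa", {
  expect_equal(shear_stiffness(50, 60, 1000), 9.0, tolerance = 1e-12)
  expect_equal(shear_stiffness(30, 60, 1000), 3.24, tolerance = 1e-12)
  # quadratic in lambda, linear in density, quadratic in frequency
  expect_equal(shear_stiffness(40), 4 * shear_stiffness(20), tolerance = 1e-12)
  expect_equal(shear_stiffness(30, 120), 4 * shear_stiffness(30, 60),
               tolerance = 1e-12)
  expect_true(is.na(shear_stiffness(NA_real_)))
  expect_error(shear_stiffness(-5), "positive")
})

test_that("rotating geometry and wave field together preserves the estimate", {
  theta <- 20 * pi / 180
  d <- c(0, sin(theta), cos(theta))
  spec <- phantom_spec(
    shape = c(8, 64, 96), spacing = c(10, 1.5, 1.5),
    compartments = list(
      muscle_compartment("rot", center = c(40, 48, 72), axis = d,
                         radius = 14, length = 110, pdff = 0.1,
                         stiffness_kpa = 3.24)),
    dixon_noise_sd = 0, wave_noise_sd = 0, oblique_fraction = 0,
    outlier_fraction = 0, invalid_fraction = 0)
  lm <- make_labelmap(spec)
  ws <- simulate_waves(lm, spec)
  res <- estimate_stiffness_b(ws, lm)
  expect_equal(res$mean_wavelength_mm, 30, tolerance = 0.04)
})

test_that("oblique contamination stays within the sanity envelope", {
  spec0 <- tiny_spec(stiffness_kpa = 3.24)
  lm <- make_labelmap(spec0)
  base <- estimate_stiffness_b(simulate_waves(lm, spec0), lm)$stiffness_kpa
  spec1 <- tiny_spec(stiffness_kpa = 3.24, oblique_fraction = 0.9)
  contaminated <- estimate_stiffness_b(simulate_waves(lm, spec1),
                                       lm)$stiffness_kpa
  # the added 0.7-lambda component cannot shift the estimate by more than
  # the stiffness it implies itself
  lam_prime <- 0.7 * true_wavelength_mm(3.24)
  expect_lte(contaminated, base + shear_stiffness(lam_prime))
  expect_gte(contaminated, base - shear_stiffness(lam_prime))
})

test_that("a purely oblique wave artificially elevates measured stiffness", {
  # wave propagates at 45 degrees to the muscle's long axis: its apparent
  # wavelength along the axis is stretched by 1/cos(45), inflating stiffness
  spec_geom <- tiny_spec(stiffness_kpa = 3.24)
  lm <- make_labelmap(spec_geom)
  spec_wave <- spec_geom
  spec_wave$compartments[[1]]$axis <- c(0, sin(pi / 4), cos(pi / 4))
  ws <- simulate_waves(lm, spec_wave)
  res <- estimate_stiffness_b(ws, lm)
  apparent <- true_wavelength_mm(3.24) / cos(pi / 4)  # 42.4 mm
  expect_equal(res$mean_wavelength_mm, apparent, tolerance = 0.03)
  expect_gt(res$stiffness_kpa, 3.24 * 1.5)
})
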