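#' Define a phantom muscle compartment
#'
#' A geometric primitive (cylinder or ellipsoid) standing in for one thigh
#' muscle, with known ground-truth fat fraction and shear stiffness.
#'
#' @param name muscle name (legend entry).
#' @param center centre in world mm.
#' @param shape `"cylinder"` or `"ellipsoid"`.
#' @param axis long-axis direction (normalized internally).
#' @param radius,length cylinder radius and length, mm.
#' @param semiaxes length-3 ellipsoid semi-axes, mm (first along `axis`).
#' @param pdff true proton-density fat fraction in `[0, 1]`.
#' @param stiffness_kpa true shear stiffness, kPa (> 0).
#' @param side `"left"` or `"right"`.
#' @return A list describing the compartment.
#' @export
muscle_compartment <- function(name, center, shape = c("cylinder", "ellipsoid"),
                               axis = c(0, 0, 1), radius = 16, length = 170,
                               semiaxes = NULL, pdff = 0.05,
                               stiffness_kpa = 3.0, side = "left") {
  shape <- match.arg(shape)
  if (!is.numeric(pdff) || pdff < 0 || pdff > 1)
    stop("true PDFF must lie in [0, 1], got ", pdff)
  if (!is.numeric(stiffness_kpa) || stiffness_kpa <= 0)
    stop("true stiffness must be positive, got ", stiffness_kpa)
  if (abs(vnorm(axis) - 1) > 1e-8) {
    warning("compartment axis is not a unit vector; normalizing")
    axis <- normalize(axis)
  }
  if (shape == "ellipsoid" && (is.null(semiaxes) || length(semiaxes) != 3L))
    stop("an ellipsoid compartment needs 3 semiaxes")
  list(name = name, side = side, shape = shape, center = as.numeric(center),
       axis = as.numeric(axis), radius = radius, length = length,
       semiaxes = semiaxes, pdff = pdff, stiffness_kpa = stiffness_kpa)
}

default_thigh_compartments <- function() {
  # Four representative thigh muscles; PDFF and stiffness set to typical
  # healthy-control values (a few percent fat, ~3 kPa at 60 Hz).
  list(
    muscle_compartment("rectus_femoris",      center = c(55, 30, 108),
                       pdff = 0.05, stiffness_kpa = 2.9),
    muscle_compartment("vastus_lateralis",    center = c(55, 66, 108),
                       pdff = 0.06, stiffness_kpa = 3.5),
    muscle_compartment("semimembranosus",     center = c(105, 30, 108),
                       pdff = 0.07, stiffness_kpa = 2.7),
    muscle_compartment("biceps_femoris_long", center = c(105, 66, 108),
                       pdff = 0.05, stiffness_kpa = 3.0)
  )
}

#' Specify a synthetic thigh phantom
#'
#' Describes the grid geometry, muscle compartments and corruption levels of
#' a synthetic dataset with known ground truth. The default geometry mirrors
#' a sagittal MRE acquisition: 16 slices of 10 mm thickness with 1.5 mm
#' in-plane spacing (slice axis first). Default corruption levels emulate a
#' plausible in vivo scan: Dixon noise at 1/20 of the signal scale, wave
#' noise at 1/10 of the displacement amplitude, a 10% oblique secondary wave,
#' 2% extreme vendor-map outliers and 10% invalid vendor-map voxels.
#'
#' @param shape grid dimensions (slices, in-plane, in-plane).
#' @param spacing voxel spacing, mm.
#' @param compartments list of [muscle_compartment]s; later compartments
#'   overwrite earlier ones where they overlap.
#' @param signal_scale Dixon signal scale S (fat + water in muscle).
#' @param dixon_noise_sd additive Gaussian noise sd on fat and water images.
#' @param wave_amplitude displacement amplitude A of the simulated wave.
#' @param wave_noise_sd additive Gaussian noise sd on wave images.
#' @param oblique_fraction relative amplitude in `[0, 1)` of a contaminating
#'   plane wave rotated 45 degrees in-plane with wavelength `0.7 * lambda`.
#' @param outlier_fraction fraction (max 0.05) of in-muscle vendor-map voxels
#'   replaced by extreme values (x10 or x0.1).
#' @param invalid_fraction fraction in `[0, 1)` of in-muscle vendor-map
#'   voxels marked invalid.
#' @param vendor_noise_sd_kpa Gaussian noise sd on the vendor stiffness map.
#' @param frequency_hz,density_kg_m3 wave model constants.
#' @param seed default RNG seed for the stochastic generators.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(16, 64, 144), spacing = c(10, 1.5, 1.5),
                         compartments = default_thigh_compartments(),
                         signal_scale = 100, dixon_noise_sd = 5,
                         wave_amplitude = 1, wave_noise_sd = 0.1,
                         oblique_fraction = 0.1, outlier_fraction = 0.02,
                         invalid_fraction = 0.1, vendor_noise_sd_kpa = 0.2,
                         frequency_hz = 60, density_kg_m3 = 1000, seed = 1) {
  if (length(compartments) < 1L) stop("at least one muscle compartment required")
  stopifnot(length(shape) == 3L, all(shape >= 1),
            length(spacing) == 3L, all(spacing > 0),
            signal_scale > 0, dixon_noise_sd >= 0, wave_amplitude > 0,
            wave_noise_sd >= 0, frequency_hz > 0, density_kg_m3 > 0)
  if (oblique_fraction < 0 || oblique_fraction >= 1)
    stop("oblique_fraction must lie in [0, 1)")
  if (outlier_fraction < 0 || outlier_fraction > 0.05)
    stop("outlier_fraction must lie in [0, 0.05]")
  if (invalid_fraction < 0 || invalid_fraction >= 1)
    stop("invalid_fraction must lie in [0, 1)")
  spec <- structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                         compartments = compartments,
                         signal_scale = signal_scale,
                         dixon_noise_sd = dixon_noise_sd,
                         wave_amplitude = wave_amplitude,
                         wave_noise_sd = wave_noise_sd,
                         oblique_fraction = oblique_fraction,
                         outlier_fraction = outlier_fraction,
                         invalid_fraction = invalid_fraction,
                         vendor_noise_sd_kpa = vendor_noise_sd_kpa,
                         frequency_hz = frequency_hz,
                         density_kg_m3 = density_kg_m3,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  lam <- vapply(compartments, function(m)
    true_wavelength_mm(m$stiffness_kpa, frequency_hz, density_kg_m3), 0)
  if (all(lam > 50))
    warning("no compartment has a wavelength within the 50 mm cutoff; ",
            "wavelength-based estimates will all be missing")
  spec
}

spec_affine <- function(spec) diag(c(spec$spacing, 1))

#' Shear wavelength implied by a stiffness
#'
#' Inverts mu = rho (f lambda)^2: `lambda = sqrt(mu / rho) / f`, returned
#' in mm.
#'
#' @param stiffness_kpa shear stiffness, kPa.
#' @param frequency_hz vibration frequency, Hz.
#' @param density_kg_m3 tissue density, kg/m3.
#' @return Wavelength in mm.
#' @export
true_wavelength_mm <- function(stiffness_kpa, frequency_hz = 60,
                               density_kg_m3 = 1000) {
  sqrt(stiffness_kpa * 1000 / density_kg_m3) / frequency_hz * 1000
}

#' Rasterize a phantom's muscle compartments into a label map
#'
#' Deterministic in the spec: each compartment is rasterized in order, later
#' compartments overwriting earlier ones; the number of overwritten voxels is
#' recorded in the `"overwritten"` attribute.
#'
#' @param spec a [phantom_spec].
#' @return An [mre_labelmap] with one label per compartment.
#' @export
make_labelmap <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  aff <- spec_affine(spec)
  xyz <- world_coords(aff, spec$shape)
  lab <- integer(nrow(xyz))
  overwritten <- integer(length(spec$compartments))
  for (ci in seq_along(spec$compartments)) {
    m <- spec$compartments[[ci]]
    v <- sweep(xyz, 2, m$center)
    a <- drop(v %*% m$axis)
    if (m$shape == "cylinder") {
      r2 <- rowSums(v^2) - a^2
      inside <- r2 <= m$radius^2 & abs(a) <= m$length / 2
    } else {
      fr <- orthonormal_frame(m$axis)
      b <- drop(v %*% fr[, 2]); cc <- drop(v %*% fr[, 3])
      inside <- (a / m$semiaxes[1])^2 + (b / m$semiaxes[2])^2 +
        (cc / m$semiaxes[3])^2 <= 1
    }
    if (!any(inside))
      stop("compartment '", m$name, "' lies entirely outside the grid")
    overwritten[ci] <- sum(lab[inside] != 0L)
    lab[inside] <- ci
  }
  legend <- data.frame(
    label = seq_along(spec$compartments),
    muscle = vapply(spec$compartments, `[[`, "", "name"),
    side = vapply(spec$compartments, `[[`, "", "side"),
    stringsAsFactors = FALSE)
  lm <- mre_labelmap(array(lab, spec$shape), legend, affine = aff)
  attr(lm, "overwritten") <- overwritten
  lm
}

#' Simulate Dixon fat and water volumes
#'
#' Inside muscle m the noiseless signals are `fat = S * pdff(m)` and
#' `water = S * (1 - pdff(m))`; independent zero-mean Gaussian noise
#' (`dixon_noise_sd`) is then added to both images everywhere (background is
#' noise only) and negative values are clipped to zero.
#'
#' @param labelmap label map from [make_labelmap] (matching geometry).
#' @param spec the [phantom_spec].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return `list(fat = , water = )` of [mre_volume]s.
#' @export
simulate_dixon <- function(labelmap, spec, seed = spec$seed) {
  stopifnot(inherits(labelmap, "mre_labelmap"), inherits(spec, "phantom_spec"))
  if (!identical(dim(labelmap$labels), spec$shape))
    stop("labelmap geometry does not match spec")
  S <- spec$signal_scale
  lab <- as.vector(labelmap$labels)
  fat <- numeric(length(lab)); water <- numeric(length(lab))
  for (ci in seq_along(spec$compartments)) {
    m <- spec$compartments[[ci]]
    sel <- lab == ci
    fat[sel] <- S * m$pdff
    water[sel] <- S * (1 - m$pdff)
  }
  if (spec$dixon_noise_sd > 0) {
    with_seed(seed, {
      fat <- fat + rnorm(length(fat), 0, spec$dixon_noise_sd)
      water <- water + rnorm(length(water), 0, spec$dixon_noise_sd)
    })
    fat <- pmax(fat, 0); water <- pmax(water, 0)
  }
  aff <- labelmap$affine
  list(fat = mre_volume(array(fat, spec$shape), affine = aff),
       water = mre_volume(array(water, spec$shape), affine = aff))
}

#' Simulate the 8-phase MRE wave series
#'
#' Inside muscle m with unit axis d and wavelength
#' `lambda(m) = sqrt(mu(m)/rho) / f`, phase k (k = 0..7) is
#' `A sin(2 pi (x . d) / lambda + 2 pi k / 8)` plus, when
#' `oblique_fraction > 0`, a contaminating plane wave of relative amplitude
#' `oblique_fraction` travelling along the axis rotated 45 degrees about the
#' slice normal with wavelength `0.7 lambda`, plus Gaussian noise; the
#' background is noise only. This reproduces the known failure mode in which
#' oblique wave components bias the measured wavelength.
#'
#' @inheritParams simulate_dixon
#' @return An [mre_wave_series].
#' @export
simulate_waves <- function(labelmap, spec, seed = spec$seed) {
  stopifnot(inherits(labelmap, "mre_labelmap"), inherits(spec, "phantom_spec"))
  aff <- labelmap$affine
  xyz <- world_coords(aff, spec$shape)
  lab <- as.vector(labelmap$labels)
  n <- nrow(xyz)
  A <- spec$wave_amplitude
  slice_normal <- normalize(aff[1:3, 1])
  vals <- array(0, c(spec$shape, 8L))
  base <- matrix(0, n, 8L)
  for (ci in seq_along(spec$compartments)) {
    m <- spec$compartments[[ci]]
    sel <- lab == ci
    if (!any(sel)) next
    lam <- true_wavelength_mm(m$stiffness_kpa, spec$frequency_hz,
                              spec$density_kg_m3)
    d <- normalize(m$axis)
    proj <- drop(xyz[sel, , drop = FALSE] %*% d)
    arg1 <- 2 * pi * proj / lam
    if (spec$oblique_fraction > 0) {
      d2 <- rotate_about(d, slice_normal, pi / 4)
      proj2 <- drop(xyz[sel, , drop = FALSE] %*% d2)
      arg2 <- 2 * pi * proj2 / (0.7 * lam)
    }
    for (k in 0:7) {
      ph <- 2 * pi * k / 8
      w <- A * sin(arg1 + ph)
      if (spec$oblique_fraction > 0)
        w <- w + spec$oblique_fraction * A * sin(arg2 + ph)
      base[sel, k + 1L] <- w
    }
  }
  if (spec$wave_noise_sd > 0)
    base <- base + with_seed(seed, matrix(rnorm(n * 8L, 0, spec$wave_noise_sd),
                                          n, 8L))
  for (k in 1:8) vals[, , , k] <- array(base[, k], spec$shape)
  mre_wave_series(vals, frequency_hz = spec$frequency_hz, affine = aff)
}

#' Simulate a vendor-style stiffness map
#'
#' In-muscle voxels take the compartment's true stiffness plus Gaussian
#' noise; a fraction `outlier_fraction` of them (floor of the count, so the
#' realized fraction is within one voxel of the request) is replaced by
#' extreme values (x10 or x0.1), and a fraction `invalid_fraction` is marked
#' invalid. Background voxels carry no value and are invalid, mirroring the
#' shaded unmeasurable regions of vendor output.
#'
#' @inheritParams simulate_dixon
#' @return An [mre_stiffness_map] (kPa).
#' @export
simulate_vendor_map <- function(labelmap, spec, seed = spec$seed) {
  stopifnot(inherits(labelmap, "mre_labelmap"), inherits(spec, "phantom_spec"))
  lab <- as.vector(labelmap$labels)
  stiff <- numeric(length(lab))
  valid <- logical(length(lab))
  with_seed(seed, {
    for (ci in seq_along(spec$compartments)) {
      m <- spec$compartments[[ci]]
      idx <- which(lab == ci)
      nvox <- length(idx)
      if (!nvox) next
      v <- m$stiffness_kpa + rnorm(nvox, 0, spec$vendor_noise_sd_kpa)
      n_out <- floor(spec$outlier_fraction * nvox)
      if (n_out > 0) {
        pick <- sample(nvox, n_out)
        v[pick] <- v[pick] * sample(c(10, 0.1), n_out, replace = TRUE)
      }
      stiff[idx] <- v
      ok <- rep(TRUE, nvox)
      n_inv <- floor(spec$invalid_fraction * nvox)
      if (n_inv > 0) ok[sample(nvox, n_inv)] <- FALSE
      valid[idx] <- ok
    }
  })
  mre_stiffness_map(mre_volume(array(stiff, spec$shape),
                               affine = labelmap$affine),
                    array(valid, spec$shape))
}

#' Generate one complete phantom dataset
#'
#' Convenience wrapper producing the label map, Dixon pair, wave series,
#' vendor stiffness map and a ground-truth table from one spec and seed.
#'
#' @param spec a [phantom_spec].
#' @param seed RNG seed; sub-seeds for the individual generators are derived
#'   from it deterministically.
#' @return A list with elements `labelmap`, `fat`, `water`, `waves`,
#'   `stiffness_map` and `truth` (data frame with per-muscle true PDFF,
#'   stiffness and wavelength).
#' @export
generate_phantom <- function(spec, seed = spec$seed) {
  labelmap <- make_labelmap(spec)
  dixon <- simulate_dixon(labelmap, spec, seed = derive_seed(seed, 1))
  waves <- simulate_waves(labelmap, spec, seed = derive_seed(seed, 2))
  vendor <- simulate_vendor_map(labelmap, spec, seed = derive_seed(seed, 3))
  truth <- data.frame(
    label = seq_along(spec$compartments),
    muscle = vapply(spec$compartments, `[[`, "", "name"),
    side = vapply(spec$compartments, `[[`, "", "side"),
    true_pdff = vapply(spec$compartments, `[[`, 0, "pdff"),
    true_stiffness_kpa = vapply(spec$compartments, `[[`, 0, "stiffness_kpa"),
    stringsAsFactors = FALSE)
  truth$true_wavelength_mm <- true_wavelength_mm(
    truth$true_stiffness_kpa, spec$frequency_hz, spec$density_kg_m3)
  list(labelmap = labelmap, fat = dixon$fat, water = dixon$water,
       waves = waves, stiffness_map = vendor, truth = truth)
}

#' Simulate a test-retest session pair
#'
#' Emulates two identical scans separated by a short interval: session 2 is
#' regenerated with fresh noise after perturbing each compartment's true
#' PDFF and stiffness by a zero-mean Gaussian with relative standard
#' deviation `between_session_sd` (i.e. sd = `between_session_sd * truth`).
#' With `between_session_sd = 0` the truths are identical and only the noise
#' realization differs.
#'
#' @param spec a [phantom_spec].
#' @param between_session_sd relative sd of the true-value perturbation
#'   (>= 0).
#' @param seed RNG seed.
#' @return A list with elements `spec`, `session1`, `session2` (each as
#'   returned by [generate_phantom]) and the two truth tables `truth1`,
#'   `truth2`.
#' @export
make_session_pair <- function(spec, between_session_sd = 0, seed = spec$seed) {
  stopifnot(between_session_sd >= 0)
  s1 <- generate_phantom(spec, seed = derive_seed(seed, 11))
  spec2 <- spec
  if (between_session_sd > 0) {
    with_seed(derive_seed(seed, 12), {
      for (ci in seq_along(spec2$compartments)) {
        m <- spec2$compartments[[ci]]
        m$pdff <- clamp(m$pdff * (1 + rnorm(1, 0, between_session_sd)), 0, 1)
        m$stiffness_kpa <- max(m$stiffness_kpa *
                                 (1 + rnorm(1, 0, between_session_sd)), 1e-6)
        spec2$compartments[[ci]] <- m
      }
    })
  }
  s2 <- generate_phantom(spec2, seed = derive_seed(seed, 13))
  list(spec = spec, session1 = s1, session2 = s2,
       truth1 = s1$truth, truth2 = s2$truth)
}

#' Simulate a test-retest cohort and measure it
#'
#' Generates `n_subjects` phantom subjects, each scanned at `baseline` and
#' `week1`, and runs the Dixon quantification pipeline on every scan,
#' returning a long-format [measurement_table] of per-muscle PDFF and volume.
#' Subject-level truths are drawn around the spec's compartment values:
#' PDFF with absolute sd `between_subject$pdff`, and an overall size factor
#' (scaling radius and length) with relative sd `between_subject$size`.
#' Session 2 truths are re-perturbed with sd `session_sd_scale` times the
#' corresponding between-subject sd; the size factor additionally wobbles by
#' `size_session_sd` between sessions, emulating repositioning and
#' segmentation variability (without it, measured volumes would be exactly
#' repeatable and their retest agreement trivially perfect).
#'
#' @param n_subjects number of simulated subjects.
#' @param spec base [phantom_spec] shared by the cohort.
#' @param between_subject list with absolute sd `pdff` and relative sd
#'   `size` of the subject-level truth distributions.
#' @param session_sd_scale session perturbation, as a multiple of the
#'   between-subject sd (the test-retest "noise dial": 0 = identical truths).
#' @param size_session_sd relative sd of the between-session size wobble.
#' @param group cohort group label.
#' @param seed RNG seed.
#' @param metrics subset of `c("pdff_fraction", "volume_cc")` to measure.
#' @return A [measurement_table] with sessions `baseline` and `week1`.
#' @export
simulate_reliability_cohort <- function(n_subjects = 20,
                                        spec = phantom_spec(),
                                        between_subject = list(pdff = 0.025,
                                                               size = 0.08),
                                        session_sd_scale = 0,
                                        size_session_sd = 0.01,
                                        group = "control", seed = 1,
                                        metrics = c("pdff_fraction",
                                                    "volume_cc")) {
  stopifnot(n_subjects >= 2, session_sd_scale >= 0)
  metrics <- match.arg(metrics, several.ok = TRUE)
  draws <- with_seed(seed, {
    list(sub = sample.int(2^30, n_subjects),
         pdff = matrix(rnorm(n_subjects * length(spec$compartments)),
                       n_subjects),
         size = rnorm(n_subjects),
         sess_pdff = matrix(rnorm(n_subjects * length(spec$compartments)),
                            n_subjects),
         sess_size = rnorm(n_subjects))
  })
  floor_abs <- spec$signal_scale * 0.01
  rows <- vector("list", n_subjects * 2L)
  ri <- 0L
  for (s in seq_len(n_subjects)) {
    base_pdff <- vapply(spec$compartments, `[[`, 0, "pdff") +
      between_subject$pdff * draws$pdff[s, ]
    base_pdff <- clamp(base_pdff, 0.005, 0.95)
    base_size <- max(0.5, 1 + between_subject$size * draws$size[s])
    for (sess in 1:2) {
      pdff_s <- base_pdff
      size_s <- base_size
      if (sess == 2L) {
        pdff_s <- clamp(pdff_s + session_sd_scale * between_subject$pdff *
                          draws$sess_pdff[s, ], 0.005, 0.95)
        size_s <- max(0.5, size_s * (1 + size_session_sd * draws$sess_size[s]))
      }
      spec_s <- spec
      for (ci in seq_along(spec_s$compartments)) {
        m <- spec_s$compartments[[ci]]
        m$pdff <- pdff_s[ci]
        m$radius <- m$radius * size_s
        m$length <- m$length * size_s
        if (!is.null(m$semiaxes)) m$semiaxes <- m$semiaxes * size_s
        spec_s$compartments[[ci]] <- m
      }
      labelmap <- make_labelmap(spec_s)
      dixon <- simulate_dixon(labelmap, spec_s,
                              seed = derive_seed(draws$sub[s], sess))
      out <- NULL
      if ("pdff_fraction" %in% metrics) {
        pdff_map <- compute_pdff(dixon$fat, dixon$water,
                                 signal_floor = floor_abs)
        pt <- muscle_pdff(pdff_map, labelmap)
        out <- rbind(out, data.frame(muscle = pt$muscle, side = pt$side,
                                     metric = "pdff_fraction",
                                     value = pt$mean_pdff))
      }
      if ("volume_cc" %in% metrics) {
        vt <- muscle_volume(labelmap)
        out <- rbind(out, data.frame(muscle = vt$muscle, side = vt$side,
                                     metric = "volume_cc",
                                     value = vt$volume_cc))
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(subject_id = sprintf("S%03d", s), group = group,
                               session = c("baseline", "week1")[sess],
                               out, stringsAsFactors = FALSE)
    }
  }
  measurement_table(do.call(rbind, rows))
}
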