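#' Principal proximo-distal axis of a muscle
#'
#' First principal component of the world coordinates of the muscle's
#' voxels. Shear waves travel along the muscle fibre direction, so the
#' wavelength must be measured along this axis; measuring across it would
#' pick up oblique wave components and bias stiffness upward. The direction
#' sign is fixed to a positive superior (+z) component. A QC flag is raised
#' when the elongation ratio (first over second principal extent) is below
#' 1.5, i.e. the shape is too isotropic for a well-defined long axis.
#'
#' @param labelmap an [mre_labelmap].
#' @param muscle muscle name (or label number).
#' @param side optional side to disambiguate.
#' @return A list of class `muscle_axis` with `muscle`, `side`, `direction`
#'   (unit 3-vector, world mm), `centroid` (world mm), `elongation` and
#'   logical `qc_isotropic`.
#' @export
principal_axis <- function(labelmap, muscle, side = NULL) {
  row <- resolve_label(labelmap, muscle, side)
  idx <- which(labelmap$labels == row$label)
  if (length(idx) < 10L)
    stop("muscle '", row$muscle, "' has fewer than 10 voxels (",
         length(idx), ")")
  dims <- dim(labelmap$labels)
  ijk <- arrayInd(idx, dims) - 1
  xyz <- ijk %*% t(labelmap$affine[1:3, 1:3])
  xyz <- sweep(xyz, 2, labelmap$affine[1:3, 4], "+")
  pc <- prcomp(xyz, center = TRUE, scale. = FALSE)
  dir <- pc$rotation[, 1]
  # deterministic sign: positive superior component, falling back to the
  # first nonzero component for axes lying in the axial plane
  if (dir[3] < 0) dir <- -dir
  else if (dir[3] == 0) {
    nz <- which(dir != 0)[1]
    if (length(nz) && dir[nz] < 0) dir <- -dir
  }
  elong <- if (pc$sdev[2] > 0) pc$sdev[1] / pc$sdev[2] else Inf
  structure(list(muscle = row$muscle, side = row$side,
                 direction = unname(dir), centroid = unname(colMeans(xyz)),
                 elongation = elong, qc_isotropic = elong < 1.5),
            class = "muscle_axis")
}

#' Select the slice with maximum muscle/measurement overlap
#'
#' Returns the index (1-based, along the first/slice axis) of the sagittal
#' slice maximizing the voxel count of `muscle AND measurable`; ties break
#' to the lowest index. When no slice overlaps, `NA` is returned with a
#' `qc` attribute.
#'
#' @param labelmap an [mre_labelmap].
#' @param muscle muscle name or label.
#' @param measurable logical 3D array of voxels where the MRE measurement is
#'   usable; defaults to the whole grid.
#' @param side optional side.
#' @return Integer slice index, or `NA` with `attr(, "qc") = "no_overlap"`.
#' @export
select_slice <- function(labelmap, muscle, measurable = NULL, side = NULL) {
  row <- resolve_label(labelmap, muscle, side)
  m <- labelmap$labels == row$label
  if (!is.null(measurable)) {
    if (!identical(dim(measurable), dim(labelmap$labels)))
      stop("'measurable' must match the label grid shape")
    m <- m & measurable
  }
  counts <- apply(m, 1, sum)
  if (all(counts == 0L))
    return(structure(NA_integer_, qc = "no_overlap"))
  which.max(counts)
}

# Bilinear interpolation in a 2D slice at continuous 1-based coordinates.
interp_slice <- function(sl, cj, ck) {
  nj <- nrow(sl); nk <- ncol(sl)
  j0 <- clamp(floor(cj), 1, nj - 1); k0 <- clamp(floor(ck), 1, nk - 1)
  fj <- clamp(cj - j0, 0, 1); fk <- clamp(ck - k0, 0, 1)
  sl[cbind(j0, k0)] * (1 - fj) * (1 - fk) +
    sl[cbind(j0 + 1, k0)] * fj * (1 - fk) +
    sl[cbind(j0, k0 + 1)] * (1 - fj) * fk +
    sl[cbind(j0 + 1, k0 + 1)] * fj * fk
}

empty_profile <- function(qc) {
  structure(list(positions = numeric(0), values = numeric(0),
                 step = NA_real_, qc = qc), class = "wave_profile")
}

#' Extract a 1D wave profile along a muscle's axis in one slice
#'
#' The measurement is 2D in-slice, so the muscle axis is first projected
#' into the slice plane. A line is drawn through the in-slice muscle
#' centroid along the projected axis and the wave image is sampled along it
#' by bilinear interpolation at a step equal to the smaller in-plane
#' spacing. The profile is restricted to the longest contiguous run of
#' samples inside the muscle and detrended by mean removal. Runs shorter
#' than 4 samples yield an empty profile with a QC flag.
#'
#' @param wave an [mre_volume] (one wave phase).
#' @param slice slice index (1-based, first axis).
#' @param axis a `muscle_axis` from [principal_axis].
#' @param labelmap the [mre_labelmap] (same geometry as `wave`).
#' @param muscle muscle name or label.
#' @param side optional side.
#' @param step sample spacing in mm; defaults to `min(spacing[2:3])`.
#' @return A list of class `wave_profile`: `positions` (mm along the
#'   projected axis, relative to the in-slice centroid), `values`
#'   (mean-subtracted), `step`, `direction`, `centroid` and `qc` (`NULL`
#'   when clean).
#' @export
extract_profile <- function(wave, slice, axis, labelmap, muscle, side = NULL,
                            step = NULL) {
  stopifnot(inherits(wave, "mre_volume"), inherits(axis, "muscle_axis"))
  if (!same_geometry(wave, labelmap))
    stop("wave and label map geometry mismatch")
  row <- resolve_label(labelmap, muscle, side)
  aff <- labelmap$affine
  normal <- normalize(aff[1:3, 1])
  d <- axis$direction
  dp <- d - sum(d * normal) * normal
  if (vnorm(dp) < 1e-8)
    stop("muscle axis is perpendicular to the slice plane")
  dp <- normalize(dp)
  mask2 <- labelmap$labels[slice, , ] == row$label
  if (!any(mask2)) return(empty_profile("no_overlap"))
  jk <- which(mask2, arr.ind = TRUE)
  ijk <- cbind(slice - 1, jk - 1)  # 0-based voxel indices
  xyz <- ijk %*% t(aff[1:3, 1:3])
  xyz <- sweep(xyz, 2, aff[1:3, 4], "+")
  cw <- colMeans(xyz)
  tproj <- drop(sweep(xyz, 2, cw) %*% dp)
  step <- step %||% min(labelmap$spacing[2:3])
  ts <- seq(min(tproj), max(tproj), by = step)
  if (length(ts) < 4L) return(empty_profile("short_run"))
  pts <- sweep(outer(ts, dp), 2, cw, "+")
  inv <- solve(aff)
  cont <- pts %*% t(inv[1:3, 1:3])
  cont <- sweep(cont, 2, inv[1:3, 4], "+") + 1  # continuous 1-based
  # in-muscle membership at each sample, by nearest voxel
  nn <- round(cont)
  dims <- dim(labelmap$labels)
  inb <- nn[, 2] >= 1 & nn[, 2] <= dims[2] & nn[, 3] >= 1 & nn[, 3] <= dims[3]
  inm <- logical(length(ts))
  inm[inb] <- labelmap$labels[cbind(slice, nn[inb, 2], nn[inb, 3])] == row$label
  if (!any(inm)) return(empty_profile("no_overlap"))
  runs <- rle(inm)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  tr <- which(runs$values)
  best <- tr[which.max(runs$lengths[tr])]
  sel <- starts[best]:ends[best]
  if (length(sel) < 4L) return(empty_profile("short_run"))
  vals <- interp_slice(wave$values[slice, , ], cont[sel, 2], cont[sel, 3])
  structure(list(positions = ts[sel], values = vals - mean(vals),
                 step = step, direction = dp, centroid = cw, qc = NULL),
            class = "wave_profile")
}

#' Dominant wavelength of a 1D profile by Fourier power analysis
#'
#' The profile is zero-padded to at least 8x its length (next power of two)
#' to refine the spectral grid, and the power spectrum is evaluated over the
#' nonzero frequencies. The wavelength with maximum power is returned; power
#' ties break to the longer wavelength. When the dominant wavelength exceeds
#' `max_wavelength_mm` the result is missing (`NA`): such long wavelengths
#' are treated as artefacts, not measurements.
#'
#' @param profile a `wave_profile` from [extract_profile], or any list with
#'   uniformly spaced `positions` (mm) and `values`.
#' @param max_wavelength_mm artefact cutoff, mm (default 50).
#' @return Wavelength in mm, or `NA` (fewer than 4 samples, empty profile,
#'   or dominant wavelength beyond the cutoff, flagged via
#'   `attr(, "qc") = "artefact"`).
#' @export
dominant_wavelength <- function(profile, max_wavelength_mm = 50) {
  pos <- profile$positions
  v <- profile$values
  n <- length(v)
  if (n < 4L) return(NA_real_)
  dpos <- diff(pos)
  if (max(abs(dpos - dpos[1])) > 1e-6 * abs(dpos[1]))
    stop("profile positions must be uniformly spaced")
  dx <- abs(dpos[1])
  v <- v - mean(v)
  nfft <- 2^ceiling(log2(max(8 * n, 8)))
  pw <- Mod(fft(c(v, numeric(nfft - n))))^2
  k <- seq_len(nfft %/% 2)           # nonzero frequencies
  pw <- pw[k + 1L]
  freq <- k / (nfft * dx)
  peak <- which.max(pw)              # first max = lowest freq = longest lambda
  lam <- 1 / freq[peak]
  if (lam > max_wavelength_mm)
    return(structure(NA_real_, qc = "artefact"))
  lam
}

#' Per-muscle wavelength averaged over the 8 wave phases
#'
#' Runs [extract_profile] and [dominant_wavelength] on each of the 8 phase
#' images; phases returning a missing wavelength are dropped and the
#' remaining wavelengths averaged. At least `min_valid_phases` (default 4)
#' valid phases are required, otherwise the estimate is missing with a QC
#' flag. The mean wavelength is converted to shear stiffness with
#' [shear_stiffness].
#'
#' @param series an [mre_wave_series].
#' @param slice slice index from [select_slice].
#' @param axis a `muscle_axis`.
#' @param labelmap an [mre_labelmap] sharing the wave geometry.
#' @param muscle muscle name or label.
#' @param side optional side.
#' @param max_wavelength_mm artefact cutoff, mm.
#' @param density_kg_m3 tissue density for the stiffness conversion.
#' @param min_valid_phases minimum number of usable phases.
#' @return A list of class `wavelength_estimate`: `muscle`, `side`, `slice`,
#'   `lambda_mm` (8 per-phase values, possibly `NA`), `n_valid_phases`,
#'   `mean_wavelength_mm`, `stiffness_kpa` and `qc` (character vector of
#'   flags, empty when clean).
#' @export
wavelength_over_phases <- function(series, slice, axis, labelmap, muscle,
                                   side = NULL, max_wavelength_mm = 50,
                                   density_kg_m3 = 1000,
                                   min_valid_phases = 4) {
  stopifnot(inherits(series, "mre_wave_series"))
  qc <- character(0)
  lambda <- rep(NA_real_, 8L)
  if (!is.na(slice)) {
    for (k in 1:8) {
      prof <- extract_profile(wave_phase(series, k), slice, axis, labelmap,
                              muscle, side = side)
      if (!length(prof$values)) {
        qc <- union(qc, prof$qc)
        next
      }
      lambda[k] <- dominant_wavelength(prof, max_wavelength_mm)
    }
  } else qc <- union(qc, "no_slice")
  valid <- !is.na(lambda)
  if (sum(valid) >= min_valid_phases) {
    if (any(!valid)) qc <- union(qc, "phases_dropped")
    mean_lambda <- mean(lambda[valid])
  } else {
    qc <- union(qc, "insufficient_phases")
    mean_lambda <- NA_real_
  }
  if (isTRUE(axis$qc_isotropic)) qc <- union(qc, "isotropic_axis")
  structure(list(muscle = axis$muscle, side = axis$side, slice = slice,
                 lambda_mm = lambda, n_valid_phases = sum(valid),
                 mean_wavelength_mm = mean_lambda,
                 stiffness_kpa = shear_stiffness(mean_lambda,
                                                 series$frequency_hz,
                                                 density_kg_m3),
                 qc = qc),
            class = "wavelength_estimate")
}

#' Shear stiffness from wavelength
#'
#' `mu = rho (f lambda)^2` with the wavelength converted to metres; computed
#' in Pa and reported in kPa. At 60 Hz and 1000 kg/m3, a 30 mm wavelength
#' gives 3.24 kPa and a 50 mm wavelength 9.0 kPa.
#'
#' @param wavelength_mm wavelength in mm (vectorized; `NA` passes through).
#' @param frequency_hz vibration frequency, Hz.
#' @param density_kg_m3 tissue density, kg/m3.
#' @return Shear stiffness in kPa.
#' @export
shear_stiffness <- function(wavelength_mm, frequency_hz = 60,
                            density_kg_m3 = 1000) {
  if (any(wavelength_mm <= 0, na.rm = TRUE))
    stop("wavelength must be positive")
  mu_pa <- density_kg_m3 * (frequency_hz * wavelength_mm / 1000)^2
  mu_pa / 1000
}

#' Method B: per-muscle stiffness from wave images
#'
#' Full wavelength-based pipeline for every muscle in the legend: principal
#' proximo-distal axis, maximum-overlap slice, per-phase dominant
#' wavelength along the in-plane-projected axis, 8-phase average, and
#' `mu = rho (f lambda)^2`. Muscles failing any stage carry QC flags and a
#' missing stiffness rather than a numeric guess.
#'
#' @param series an [mre_wave_series].
#' @param labelmap an [mre_labelmap] sharing the wave geometry.
#' @param measurable optional logical array of usable-measurement voxels for
#'   slice selection; defaults to the full wave footprint.
#' @param config an [mre_config] supplying the wavelength cutoff, density
#'   and phase requirements.
#' @return Data frame with one row per muscle: `label`, `muscle`, `side`,
#'   `slice`, per-phase wavelengths `lambda_p1` .. `lambda_p8` (mm),
#'   `n_valid_phases`, `mean_wavelength_mm`, `stiffness_kpa`, `qc`
#'   (semicolon-joined flags).
#' @export
estimate_stiffness_b <- function(series, labelmap, measurable = NULL,
                                 config = mre_config()) {
  stopifnot(inherits(series, "mre_wave_series"),
            inherits(labelmap, "mre_labelmap"))
  if (!same_geometry(series, labelmap))
    stop("wave series and label map geometry mismatch")
  lg <- labelmap$legend
  rows <- vector("list", nrow(lg))
  for (i in seq_len(nrow(lg))) {
    lamcols <- as.list(rep(NA_real_, 8L))
    names(lamcols) <- paste0("lambda_p", 1:8)
    base <- data.frame(label = lg$label[i], muscle = lg$muscle[i],
                       side = lg$side[i], slice = NA_integer_, lamcols,
                       n_valid_phases = 0L, mean_wavelength_mm = NA_real_,
                       stiffness_kpa = NA_real_, qc = "",
                       stringsAsFactors = FALSE)
    est <- tryCatch({
      ax <- principal_axis(labelmap, lg$label[i])
      sl <- select_slice(labelmap, lg$label[i], measurable = measurable)
      wavelength_over_phases(
        series, sl, ax, labelmap, lg$label[i],
        max_wavelength_mm = config$max_wavelength_mm,
        density_kg_m3 = config$density_kg_m3,
        min_valid_phases = config$min_valid_phases)
    }, error = function(e) e)
    if (inherits(est, "error")) {
      base$qc <- paste0("error: ", conditionMessage(est))
    } else {
      base$slice <- if (is.na(est$slice)) NA_integer_ else est$slice
      base[paste0("lambda_p", 1:8)] <- as.list(est$lambda_mm)
      base$n_valid_phases <- est$n_valid_phases
      base$mean_wavelength_mm <- est$mean_wavelength_mm
      base$stiffness_kpa <- est$stiffness_kpa
      base$qc <- paste(est$qc, collapse = ";")
    }
    rows[[i]] <- base
  }
  do.call(rbind, rows)
}
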