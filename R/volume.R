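#' 3D scalar volume with world geometry
#'
#' The basic image container used throughout the package: a 3D numeric grid
#' together with a 4x4 voxel-to-world affine. World coordinates are
#' millimetres in RAS orientation. The affine follows the NIfTI convention
#' and maps 0-based voxel indices to world mm; R-level array indexing remains
#' the usual 1-based. Voxel spacing is always derived from the affine column
#' norms, so the affine is the single source of geometric truth.
#'
#' @param values 3D numeric array.
#' @param affine 4x4 voxel-index (0-based) to world-mm matrix. Defaults to a
#'   diagonal affine built from `spacing`.
#' @param spacing length-3 voxel spacing in mm, used only when `affine` is
#'   missing.
#' @return An object of class `mre_volume` with fields `values`, `affine`
#'   and `spacing` (mm).
#' @examples
#' v <- mre_volume(array(0, c(4, 4, 4)), spacing = c(1.5, 1.5, 10))
#' v$spacing
#' @export
mre_volume <- function(values, affine = NULL, spacing = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3D array, got ", length(dim(values)), " dimensions")
  if (any(dim(values) == 0L)) stop("volume grid must be non-empty")
  if (is.null(affine)) {
    spacing <- spacing %||% c(1, 1, 1)
    if (length(spacing) != 3L || any(spacing <= 0))
      stop("'spacing' must be 3 strictly positive values")
    affine <- diag(c(spacing, 1))
  }
  affine <- matrix(as.numeric(affine), 4L, 4L)
  if (abs(det(affine)) < 1e-10) stop("affine must be invertible")
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(sp <= 0)) stop("affine implies non-positive voxel spacing")
  structure(list(values = values, affine = affine, spacing = sp),
            class = "mre_volume")
}

#' @export
print.mre_volume <- function(x, ...) {
  cat("<mre_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

vol_dim <- function(x) {
  if (inherits(x, "mre_volume")) dim(x$values)
  else if (inherits(x, "mre_labelmap")) dim(x$labels)
  else if (inherits(x, "mre_wave_series")) dim(x$values)[1:3]
  else if (inherits(x, "mre_stiffness_map")) dim(x$stiffness$values)
  else stop("no geometry for class ", paste(class(x), collapse = "/"))
}

vol_affine <- function(x) {
  if (inherits(x, "mre_stiffness_map")) x$stiffness$affine else x$affine
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(vol_dim(a), vol_dim(b)) &&
    max(abs(vol_affine(a) - vol_affine(b))) < tol
}

# World-mm coordinates of all voxel centres, in array linearization order
# (first index fastest). Returns an N x 3 matrix.
world_coords <- function(affine, dims) {
  idx <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1,
                               j = seq_len(dims[2]) - 1,
                               k = seq_len(dims[3]) - 1))
  xyz <- idx %*% t(affine[1:3, 1:3])
  sweep(xyz, 2, affine[1:3, 4], "+")
}

voxel_volume_mm3 <- function(x) abs(det(vol_affine(x)[1:3, 1:3]))

#' Read a 3D volume from a NIfTI file
#'
#' @param path path to a NIfTI-1/2 file (`.nii` or `.nii.gz`).
#' @return An [mre_volume] with the affine taken from the file's xform; a
#'   trailing singleton 4th dimension is dropped.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3L)
    stop("expected a 3D image in '", path, "', got ", length(d), " dimensions")
  mre_volume(array(as.numeric(img), d), affine = RNifti::xform(img))
}

#' Write a 3D volume to a NIfTI file
#'
#' @param vol an [mre_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "mre_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::`sform<-`(img, structure(vol$affine, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Integer label map aligned to a volume geometry
#'
#' Assigns each voxel to a named muscle (or 0 for background). The legend
#' maps each nonzero label to a muscle name and body side.
#'
#' @param labels 3D array of non-negative integers; 0 is background.
#' @param legend data frame with columns `label`, `muscle` and optionally
#'   `side` (default `"left"`); every nonzero label in `labels` must appear.
#' @param affine,spacing geometry, as for [mre_volume].
#' @return An object of class `mre_labelmap`.
#' @export
mre_labelmap <- function(labels, legend, affine = NULL, spacing = NULL) {
  geom <- mre_volume(labels, affine = affine, spacing = spacing)
  lab <- geom$values
  storage.mode(lab) <- "integer"
  if (any(lab < 0L, na.rm = TRUE)) stop("labels must be non-negative integers")
  legend <- as.data.frame(legend)
  if (!all(c("label", "muscle") %in% names(legend)))
    stop("legend must have columns 'label' and 'muscle'")
  if (is.null(legend$side)) legend$side <- "left"
  legend$label <- as.integer(legend$label)
  if (any(legend$label == 0L)) stop("label 0 is reserved for background")
  present <- setdiff(unique(as.vector(lab)), 0L)
  missing_lab <- setdiff(present, legend$label)
  if (length(missing_lab))
    stop("labels present in grid but absent from legend: ",
         paste(missing_lab, collapse = ", "))
  structure(list(labels = lab, legend = legend,
                 affine = geom$affine, spacing = geom$spacing),
            class = "mre_labelmap")
}

#' @export
print.mre_labelmap <- function(x, ...) {
  cat("<mre_labelmap> ", paste(dim(x$labels), collapse = " x "), " voxels, ",
      nrow(x$legend), " labelled regions\n", sep = "")
  invisible(x)
}

# Resolve a legend row from a muscle name (optionally disambiguated by side)
# or a raw label number.
resolve_label <- function(labelmap, muscle, side = NULL) {
  lg <- labelmap$legend
  if (is.numeric(muscle)) {
    row <- lg[lg$label == as.integer(muscle), , drop = FALSE]
  } else {
    row <- lg[lg$muscle == muscle, , drop = FALSE]
    if (!is.null(side)) row <- row[row$side == side, , drop = FALSE]
  }
  if (nrow(row) == 0L) stop("muscle not found in legend: ", muscle)
  if (nrow(row) > 1L)
    stop("ambiguous muscle '", muscle, "': specify side (",
         paste(row$side, collapse = ", "), ")")
  row
}

#' Read/write a label map (NIfTI grid + CSV legend)
#'
#' @param path,legend_path NIfTI file for the integer grid and CSV file for
#'   the legend (columns `label`, `muscle`, `side`).
#' @return An `mre_labelmap` (read) or the paths, invisibly (write).
#' @export
read_labelmap <- function(path, legend_path) {
  vol <- read_volume(path)
  lg <- read.csv(legend_path, stringsAsFactors = FALSE)
  mre_labelmap(round(vol$values), lg, affine = vol$affine)
}

#' @param labelmap an `mre_labelmap`.
#' @rdname read_labelmap
#' @export
write_labelmap <- function(labelmap, path, legend_path) {
  write_volume(mre_volume(labelmap$labels, affine = labelmap$affine), path)
  write.csv(labelmap$legend, legend_path, row.names = FALSE)
  invisible(c(path, legend_path))
}

#' Eight-phase MRE wave series
#'
#' Ordered stack of 8 wave images sampling one vibration cycle at phase
#' offsets 0, 45, ..., 315 degrees, stored as a 4D grid with phase along the
#' 4th axis, plus the driver frequency.
#'
#' @param phases 4D array with 8 volumes along the 4th axis, or a list of 8
#'   [mre_volume]s sharing geometry (phase order 0 to 315 degrees).
#' @param frequency_hz driver vibration frequency in Hz (> 0).
#' @param affine,spacing geometry when `phases` is an array.
#' @return An object of class `mre_wave_series`.
#' @export
mre_wave_series <- function(phases, frequency_hz = 60,
                            affine = NULL, spacing = NULL) {
  if (!is.numeric(frequency_hz) || length(frequency_hz) != 1L || frequency_hz <= 0)
    stop("frequency_hz must be a positive scalar")
  if (is.list(phases)) {
    if (length(phases) != 8L) stop("a wave series needs exactly 8 phase volumes")
    for (p in phases[-1])
      if (!same_geometry(phases[[1]], p))
        stop("all 8 phase volumes must share geometry")
    affine <- phases[[1]]$affine
    vals <- array(0, c(dim(phases[[1]]$values), 8L))
    for (k in 1:8) vals[, , , k] <- phases[[k]]$values
  } else {
    vals <- as.array(phases)
    if (length(dim(vals)) != 4L || dim(vals)[4] != 8L)
      stop("'phases' must be a 4D array with 8 volumes along the 4th axis")
    if (is.null(affine)) {
      spacing <- spacing %||% c(1, 1, 1)
      affine <- diag(c(spacing, 1))
    }
    affine <- matrix(as.numeric(affine), 4L, 4L)
  }
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(values = vals, affine = affine, spacing = sp,
                 frequency_hz = frequency_hz),
            class = "mre_wave_series")
}

#' @export
print.mre_wave_series <- function(x, ...) {
  cat("<mre_wave_series> ", paste(dim(x$values)[1:3], collapse = " x "),
      " voxels x 8 phases, ", x$frequency_hz, " Hz\n", sep = "")
  invisible(x)
}

#' Extract one phase-offset image from a wave series
#'
#' @param series an `mre_wave_series`.
#' @param k phase index 1..8 (phase offset `(k-1) * 45` degrees).
#' @return An [mre_volume].
#' @export
wave_phase <- function(series, k) {
  stopifnot(inherits(series, "mre_wave_series"), k >= 1, k <= 8)
  mre_volume(series$values[, , , k, drop = TRUE], affine = series$affine)
}

#' Read/write an 8-phase wave series as a single 4D NIfTI
#'
#' The 4th axis holds the 8 phase offsets in fixed order 0 to 315 degrees;
#' that ordering is part of the file contract.
#'
#' @param path NIfTI path.
#' @param frequency_hz driver frequency in Hz (not stored in NIfTI).
#' @return An `mre_wave_series` (read) or `path`, invisibly (write).
#' @export
read_wave_series <- function(path, frequency_hz = 60) {
  if (!file.exists(path)) stop("cannot read wave series: no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 8L)
    stop("expected a 4D NIfTI with 8 phase volumes in '", path, "'")
  mre_wave_series(array(as.numeric(img), d), frequency_hz = frequency_hz,
                  affine = RNifti::xform(img))
}

#' @param series an `mre_wave_series`.
#' @rdname read_wave_series
#' @export
write_wave_series <- function(series, path) {
  stopifnot(inherits(series, "mre_wave_series"))
  img <- RNifti::asNifti(series$values)
  RNifti::pixdim(img) <- c(series$spacing, 1)
  RNifti::`sform<-`(img, structure(series$affine, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Vendor-style stiffness map with validity mask
#'
#' A voxelwise stiffness image (kPa) as produced by a scanner vendor's
#' inversion, together with a boolean mask of voxels where wave propagation
#' was measurable; invalid voxels are excluded from all downstream ROI
#' statistics.
#'
#' @param stiffness an [mre_volume] in kPa.
#' @param valid logical array of the same shape; defaults to
#'   `is.finite(stiffness$values)`.
#' @return An object of class `mre_stiffness_map`.
#' @export
mre_stiffness_map <- function(stiffness, valid = NULL) {
  stopifnot(inherits(stiffness, "mre_volume"))
  if (is.null(valid)) valid <- is.finite(stiffness$values)
  valid <- array(as.logical(valid), dim(stiffness$values))
  if (!identical(dim(valid), dim(stiffness$values)))
    stop("'valid' must match the stiffness grid shape")
  if (any(valid & !is.finite(stiffness$values)))
    stop("stiffness must be finite wherever marked valid")
  structure(list(stiffness = stiffness, valid = valid),
            class = "mre_stiffness_map")
}

#' @export
print.mre_stiffness_map <- function(x, ...) {
  cat("<mre_stiffness_map> ", paste(dim(x$stiffness$values), collapse = " x "),
      " voxels, ", sum(x$valid), " valid\n", sep = "")
  invisible(x)
}

#' Read/write a stiffness map as two NIfTI files (map + 0/1 validity)
#'
#' @param path NIfTI path of the stiffness image (kPa).
#' @param validity_path NIfTI path of the validity mask (0/1).
#' @return An `mre_stiffness_map` (read) or the paths, invisibly (write).
#' @export
read_stiffness_map <- function(path, validity_path = NULL) {
  vol <- read_volume(path)
  valid <- NULL
  if (!is.null(validity_path)) {
    vmask <- read_volume(validity_path)
    if (!same_geometry(vol, vmask))
      stop("validity mask geometry does not match the stiffness map")
    valid <- vmask$values > 0.5
  }
  mre_stiffness_map(vol, valid)
}

#' @param map an `mre_stiffness_map`.
#' @rdname read_stiffness_map
#' @export
write_stiffness_map <- function(map, path, validity_path) {
  vals <- map$stiffness$values
  vals[!map$valid & !is.finite(vals)] <- 0
  write_volume(mre_volume(vals, affine = map$stiffness$affine), path)
  write_volume(mre_volume(array(as.numeric(map$valid), dim(map$valid)),
                          affine = map$stiffness$affine), validity_path)
  invisible(c(path, validity_path))
}
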