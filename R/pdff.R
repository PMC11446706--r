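#' Compute a PDFF map from Dixon fat and water volumes
#'
#' Voxelwise proton-density fat fraction, `PDFF = fat / (fat + water)`,
#' returned as a fraction in `[0, 1]`. Voxels whose total signal
#' `fat + water` does not exceed `signal_floor` are marked missing (`NA`)
#' rather than propagating 0/0; the floor keeps pure-noise background ratios
#' out of downstream ROI means. An optional voxelwise pre-correction hook
#' (e.g. a T1-weighting correction) can be applied to both input images
#' before the ratio; the default is the identity.
#'
#' @param fat,water [mre_volume]s with identical geometry.
#' @param signal_floor minimum total signal for a defined PDFF (>= 0).
#' @param precorrect optional `function(fat_values, water_values)` returning
#'   `list(fat = , water = )` of corrected arrays.
#' @return An [mre_volume] with values in `[0, 1]` or `NA`, carrying the
#'   input affine.
#' @export
compute_pdff <- function(fat, water, signal_floor = 0, precorrect = NULL) {
  stopifnot(inherits(fat, "mre_volume"), inherits(water, "mre_volume"))
  if (!same_geometry(fat, water))
    stop("fat and water geometry mismatch: ",
         paste(dim(fat$values), collapse = "x"), " vs ",
         paste(dim(water$values), collapse = "x"))
  if (signal_floor < 0) stop("signal_floor must be >= 0")
  f <- fat$values; w <- water$values
  if (!is.null(precorrect)) {
    corr <- precorrect(f, w)
    f <- corr$fat; w <- corr$water
  }
  tot <- f + w
  pdff <- f / tot
  pdff[!is.finite(tot) | tot <= signal_floor] <- NA_real_
  pdff <- clamp(pdff, 0, 1)
  mre_volume(pdff, affine = fat$affine)
}

#' Per-muscle mean PDFF
#'
#' Mean PDFF over the non-missing voxels of each labelled muscle.
#'
#' @param pdff a PDFF [mre_volume] (values in `[0, 1]` or `NA`).
#' @param labelmap an [mre_labelmap] with matching geometry.
#' @return Data frame with one row per legend entry: `label`, `muscle`,
#'   `side`, `mean_pdff` (`NA` when no usable voxel), `n_voxels` (ROI size)
#'   and `n_used` (non-missing voxels).
#' @export
muscle_pdff <- function(pdff, labelmap) {
  stopifnot(inherits(pdff, "mre_volume"), inherits(labelmap, "mre_labelmap"))
  if (!same_geometry(pdff, labelmap))
    stop("PDFF and label map geometry mismatch")
  lg <- labelmap$legend
  lab <- as.vector(labelmap$labels)
  vals <- as.vector(pdff$values)
  res <- lg[c("label", "muscle", "side")]
  res$mean_pdff <- NA_real_
  res$n_voxels <- 0L
  res$n_used <- 0L
  for (i in seq_len(nrow(lg))) {
    v <- vals[lab == lg$label[i]]
    res$n_voxels[i] <- length(v)
    v <- v[!is.na(v)]
    res$n_used[i] <- length(v)
    if (length(v)) res$mean_pdff[i] <- mean(v)
  }
  res
}

#' Per-muscle volume in cc
#'
#' Volume = voxel count times voxel volume (from the affine), reported in
#' cubic centimetres.
#'
#' @param labelmap an [mre_labelmap].
#' @return Data frame with `label`, `muscle`, `side`, `n_voxels`,
#'   `volume_cc`.
#' @export
muscle_volume <- function(labelmap) {
  stopifnot(inherits(labelmap, "mre_labelmap"))
  vox_cc <- voxel_volume_mm3(labelmap) / 1000
  lg <- labelmap$legend
  counts <- tabulate(as.vector(labelmap$labels), nbins = max(lg$label))
  res <- lg[c("label", "muscle", "side")]
  res$n_voxels <- counts[lg$label]
  res$volume_cc <- res$n_voxels * vox_cc
  res
}

#' Total-thigh PDFF across muscles
#'
#' Aggregates per-muscle PDFF means into a single thigh-level value, by
#' default weighting each muscle by its volume (an unweighted mean is
#' available for sensitivity analysis).
#'
#' @param pdff_table output of [muscle_pdff].
#' @param volume_table output of [muscle_volume] (required when `weighted`).
#' @param weighted logical; volume-weighted (default) or plain mean.
#' @return A single PDFF fraction.
#' @export
total_thigh_pdff <- function(pdff_table, volume_table = NULL, weighted = TRUE) {
  ok <- !is.na(pdff_table$mean_pdff)
  if (!any(ok)) return(NA_real_)
  if (!weighted) return(mean(pdff_table$mean_pdff[ok]))
  if (is.null(volume_table)) stop("volume_table required for weighted mean")
  m <- merge(pdff_table[ok, c("label", "mean_pdff")],
             volume_table[c("label", "volume_cc")], by = "label")
  sum(m$mean_pdff * m$volume_cc) / sum(m$volume_cc)
}

#' Normality cutoff for total-thigh PDFF
#'
#' The threshold below which a thigh is considered to have a normal fat
#' fraction: mean of the healthy-control values plus 2.5 sample standard
#' deviations.
#'
#' @param control_values numeric vector (length >= 2) of control total-thigh
#'   PDFF values (any consistent unit: fraction or percent).
#' @return `mean + 2.5 * sd` in the input unit.
#' @export
normal_pdff_cutoff <- function(control_values) {
  control_values <- control_values[!is.na(control_values)]
  if (length(control_values) < 2L)
    stop("at least 2 control values are required")
  mean(control_values) + 2.5 * sd(control_values)
}
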