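#' Resample a label map onto a target geometry
#'
#' Nearest-neighbour resampling through the composition of the two affines
#' (both assumed to map into the same world frame, i.e. rigid/affine
#' co-registration only). No interpolation is performed, so no labels are
#' invented; target voxels falling outside the source grid become
#' background.
#'
#' @param labelmap source [mre_labelmap].
#' @param target an [mre_volume] (or any object with geometry) defining the
#'   output grid.
#' @return An [mre_labelmap] on the target geometry with the same legend.
#' @export
resample_labels <- function(labelmap, target) {
  stopifnot(inherits(labelmap, "mre_labelmap"))
  tdim <- vol_dim(target)
  taff <- vol_affine(target)
  if (abs(det(taff)) < 1e-10) stop("target affine is degenerate")
  xyz <- world_coords(taff, tdim)
  src_inv <- solve(labelmap$affine)
  cont <- xyz %*% t(src_inv[1:3, 1:3])
  cont <- sweep(cont, 2, src_inv[1:3, 4], "+")
  idx <- round(cont) + 1  # continuous 0-based -> nearest 1-based
  sdim <- dim(labelmap$labels)
  inb <- idx[, 1] >= 1 & idx[, 1] <= sdim[1] &
    idx[, 2] >= 1 & idx[, 2] <= sdim[2] &
    idx[, 3] >= 1 & idx[, 3] <= sdim[3]
  out <- integer(nrow(idx))
  out[inb] <- labelmap$labels[idx[inb, , drop = FALSE]]
  mre_labelmap(array(out, tdim), labelmap$legend, affine = taff)
}

#' Per-muscle trimmed-mean stiffness from a vendor map (Method A)
#'
#' For each labelled muscle: invalid voxels are discarded, the remaining
#' stiffness values are sorted, `floor(trim * n)` voxels are dropped from
#' each tail (the lowest and highest values, where residual outliers
#' concentrate), and the rest are averaged. Trimming is per-muscle ROI, not
#' per map, so small muscles are not biased by the global distribution.
#'
#' @param map an [mre_stiffness_map] (kPa).
#' @param labels an [mre_labelmap] aligned with the map (use
#'   [resample_labels] first if needed).
#' @param trim symmetric trim fraction per tail, in `[0, 0.5)`; the study
#'   default is 0.05.
#' @return Data frame with one row per muscle: `label`, `muscle`, `side`,
#'   `mean_stiffness_kpa` (`NA` when no valid voxel survives),
#'   `n_voxels_total`, `n_voxels_valid`, `n_voxels_used`.
#' @export
trimmed_muscle_mean <- function(map, labels, trim = 0.05) {
  stopifnot(inherits(map, "mre_stiffness_map"),
            inherits(labels, "mre_labelmap"))
  if (trim < 0 || trim >= 0.5) stop("trim must lie in [0, 0.5)")
  if (!same_geometry(map, labels))
    stop("stiffness map and label map geometry mismatch")
  lab <- as.vector(labels$labels)
  vals <- as.vector(map$stiffness$values)
  valid <- as.vector(map$valid) & is.finite(vals)
  lg <- labels$legend
  res <- lg[c("label", "muscle", "side")]
  res$mean_stiffness_kpa <- NA_real_
  res$n_voxels_total <- 0L
  res$n_voxels_valid <- 0L
  res$n_voxels_used <- 0L
  for (i in seq_len(nrow(lg))) {
    sel <- lab == lg$label[i]
    res$n_voxels_total[i] <- sum(sel)
    v <- vals[sel & valid]
    n <- length(v)
    res$n_voxels_valid[i] <- n
    if (n == 0L) next
    k <- floor(trim * n)
    v <- sort(v)[(k + 1L):(n - k)]
    res$n_voxels_used[i] <- length(v)
    res$mean_stiffness_kpa[i] <- mean(v)
  }
  res
}

#' Method A: per-muscle stiffness from a vendor stiffness map
#'
#' Co-registers the segmentation onto the stiffness-map grid when the
#' geometries differ (nearest-neighbour through the shared world frame),
#' then applies the validity mask and the symmetric trimmed mean.
#'
#' @param map an [mre_stiffness_map].
#' @param labelmap an [mre_labelmap] in the same world frame.
#' @param trim trim fraction per tail (default 0.05).
#' @return As [trimmed_muscle_mean].
#' @export
estimate_stiffness_a <- function(map, labelmap, trim = 0.05) {
  if (!same_geometry(map, labelmap))
    labelmap <- resample_labels(labelmap, map$stiffness)
  trimmed_muscle_mean(map, labelmap, trim = trim)
}
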