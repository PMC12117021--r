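# Lesion-network mapping from a normative resting-state connectome.
#
# The binary lesion mask seeds a resting-state analysis in every normative
# subject: the mean time course over seed voxels is correlated with every
# brain voxel, correlations are Fisher z-transformed, and maps are averaged
# voxel-wise across subjects. Because activity inside and around the seed
# trivially correlates with itself, the averaged map is masked to cerebral
# cortical grey matter before any statistics.

#' Mean seed time course
#'
#' @param ts a [volume4d()] of one normative subject.
#' @param seed binary [volume3d()] seed mask (the lesion); must overlap the
#'   4D volume in at least one voxel.
#' @return Numeric time series (mean across seed voxels at each timepoint).
#' @export
seed_timecourse <- function(ts, seed) {
  check_same_grid(ts, seed)
  idx <- which(seed$data > 0 & !is.na(seed$data))
  if (!length(idx)) stop("seed_timecourse: seed does not overlap the volume")
  d <- dim(ts$data)
  mat <- matrix(ts$data, nrow = prod(d[1:3]), ncol = d[4])
  colMeans(mat[idx, , drop = FALSE])
}

#' Voxel-wise Pearson correlation with a seed time course
#'
#' @param ts a [volume4d()].
#' @param seed_tc numeric time series of length `dim(ts$data)[4]`; must be
#'   non-constant.
#' @return A [volume3d()] of Pearson r; voxels with constant series are
#'   missing (`NA`).
#' @export
correlation_map <- function(ts, seed_tc) {
  d <- dim(ts$data)
  if (length(seed_tc) != d[4])
    stop("correlation_map: seed time course length mismatch")
  if (sd(seed_tc) == 0)
    stop("correlation_map: constant seed time course")
  mat <- matrix(ts$data, nrow = prod(d[1:3]), ncol = d[4])
  r <- as.vector(suppressWarnings(cor(t(mat), seed_tc)))
  volume3d(array(r, dim = d[1:3]), affine = ts$affine)
}

#' Fisher z transform
#'
#' `z = atanh(r)`, with `|r|` clipped at `1 - 1e-7` so voxels inside the
#' seed (r = 1 with themselves) stay finite.
#'
#' @param r correlation value, vector, array, or [volume3d()].
#' @return Same shape as the input, transformed.
#' @export
fisher_z <- function(r) {
  if (inherits(r, "volume3d"))
    return(volume3d(fisher_z(r$data), affine = r$affine, space = r$space))
  bad <- !is.na(r) & abs(r) > 1
  if (any(bad)) stop("fisher_z: |r| > 1")
  atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
}

#' Per-patient lesion-network map
#'
#' For every normative subject, correlates the seed (lesion) time course
#' with every voxel, Fisher-transforms, then averages voxel-wise across
#' subjects. At each voxel only subjects with a valid (non-missing) value
#' contribute; voxels valid in fewer than half the subjects are set
#' missing. With cortical masking, every voxel whose parcellation label is
#' not cortical — including the subcortical seed region and white matter —
#' is set missing, removing the trivially inflated autocorrelation around
#' the seed.
#'
#' @param seed binary [volume3d()] lesion mask.
#' @param connectome list of [volume4d()] normative subjects (>= 1).
#' @param parcellation a [parcellation()]; required when `mask_cortex`.
#' @param mask_cortex restrict the map to cortical grey matter.
#' @param detrend remove a per-voxel linear trend from each subject's time
#'   series before correlating (time series are otherwise used as supplied,
#'   assuming upstream preprocessing).
#' @return An object of class `lesion_network_map` with fields `zmap`
#'   ([volume3d()] of averaged Fisher z), `n_subjects`, `masked`.
#' @export
lesion_network_map <- function(seed, connectome, parcellation = NULL,
                               mask_cortex = TRUE, detrend = FALSE) {
  if (!length(connectome)) stop("lesion_network_map: empty connectome")
  if (mask_cortex && is.null(parcellation))
    stop("lesion_network_map: parcellation required for cortical masking")
  do.call(check_same_grid, c(list(seed), connectome,
                             if (!is.null(parcellation)) list(parcellation)))
  d3 <- dim(seed$data)
  zsum <- array(0, d3)
  zn <- array(0L, d3)
  for (subj in connectome) {
    ts <- subj
    if (detrend) ts <- detrend_volume4d(ts)
    tc <- seed_timecourse(ts, seed)
    z <- fisher_z(correlation_map(ts, tc))$data
    ok <- !is.na(z)
    zsum[ok] <- zsum[ok] + z[ok]
    zn <- zn + ok
  }
  need <- length(connectome) / 2
  zmap <- ifelse(zn >= pmax(need, 1L), zsum / pmax(zn, 1L), NA_real_)
  if (mask_cortex) {
    cortical <- array(parcellation$labels %in% parcellation$cortical_ids, d3)
    zmap[!cortical] <- NA_real_
  }
  structure(list(zmap = volume3d(array(zmap, d3), affine = seed$affine,
                                 space = seed$space),
                 n_subjects = length(connectome),
                 masked = mask_cortex),
            class = "lesion_network_map")
}

#' @export
print.lesion_network_map <- function(x, ...) {
  cat("<lesion_network_map> averaged over ", x$n_subjects, " subjects, ",
      sum(!is.na(x$zmap$data)), " valid voxels",
      if (x$masked) " (cortex-masked)", "\n", sep = "")
  invisible(x)
}

#' Stack lesion-network maps per patient
#'
#' Convenience wrapper building one map per lesion and returning the
#' patients x voxels matrix restricted to voxels valid in all patients,
#' the form consumed by the voxel-wise statistics.
#'
#' @param lesions list of binary [volume3d()] lesion masks.
#' @param connectome list of [volume4d()].
#' @param parcellation a [parcellation()].
#' @param mask_cortex,detrend see [lesion_network_map()].
#' @return List with `maps` (list of `lesion_network_map`), `X`
#'   (patients x voxels matrix over jointly valid voxels), `voxels` (flat
#'   indices of those voxels) and `dim` (grid extents).
#' @export
lesion_network_stack <- function(lesions, connectome, parcellation = NULL,
                                 mask_cortex = TRUE, detrend = FALSE) {
  maps <- lapply(lesions, lesion_network_map, connectome = connectome,
                 parcellation = parcellation, mask_cortex = mask_cortex,
                 detrend = detrend)
  zs <- vapply(maps, function(m) as.vector(m$zmap$data),
               numeric(length(maps[[1]]$zmap$data)))
  valid <- rowSums(is.na(zs)) == 0
  list(maps = maps,
       X = t(zs[valid, , drop = FALSE]),
       voxels = which(valid),
       dim = dim(maps[[1]]$zmap$data))
}

detrend_volume4d <- function(ts) {
  d <- dim(ts$data)
  mat <- matrix(ts$data, nrow = prod(d[1:3]), ncol = d[4])
  t_idx <- seq_len(d[4])
  t_c <- t_idx - mean(t_idx)
  beta <- (mat %*% t_c) / sum(t_c^2)
  mat <- mat - beta %*% t(t_c)
  volume4d(array(mat, d), affine = ts$affine, subject_id = ts$subject_id)
}
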