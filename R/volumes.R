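#' @importFrom stats cor sd quantile rnorm runif qnorm pnorm pt dt dcauchy
#'   integrate cor.test chisq.test p.adjust pchisq setNames uniroot var
#' @importFrom utils head
NULL

# ---- Volume containers -----------------------------------------------------

#' 3D scalar volume with a voxel-to-world affine
#'
#' The basic spatial container of the pipeline: lesion masks (binary),
#' lesion-network maps, statistic maps and probabilistic tract maps (float).
#' The affine maps 0-based voxel indices to world millimetre coordinates,
#' following the NIfTI convention; the public API addresses voxels with the
#' usual 1-based R array indices.
#'
#' @param data 3D numeric array. `NA` encodes missing (e.g. masked) voxels.
#' @param affine 4x4 invertible voxel-to-world matrix (mm).
#' @param space template identifier string; volumes entering one analysis
#'   must agree on shape and affine (checked, never resampled).
#' @return An object of class `volume3d` with fields `data`, `affine`, `space`.
#' @export
volume3d <- function(data, affine = diag(4), space = "synth") {
  if (length(dim(data)) != 3L || any(dim(data) < 1L))
    stop("volume3d: 'data' must be a 3D array with positive extents")
  affine <- check_affine(affine)
  structure(list(data = data, affine = affine, space = space),
            class = "volume3d")
}

#' 4D BOLD-like time-series volume for one normative subject
#'
#' @param data 4D array (x, y, z, time), time dimension >= 2.
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @param subject_id identifier of the normative subject.
#' @return An object of class `volume4d`.
#' @export
volume4d <- function(data, affine = diag(4), subject_id = "subject") {
  if (length(dim(data)) != 4L || any(dim(data) < 1L))
    stop("volume4d: 'data' must be a 4D array")
  if (dim(data)[4] < 2L)
    stop("volume4d: time dimension must be >= 2")
  affine <- check_affine(affine)
  structure(list(data = data, affine = affine, subject_id = subject_id),
            class = "volume4d")
}

#' Integer-labelled parcellation with a designated cortical subset
#'
#' @param labels 3D integer array; 0 is background.
#' @param affine 4x4 voxel-to-world matrix.
#' @param label_table named character vector mapping id (as name) to region
#'   name.
#' @param cortical_ids integer ids defining cerebral cortical grey matter;
#'   every id must occur in `labels`.
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(labels, affine = diag(4), label_table = character(),
                         cortical_ids = integer()) {
  if (length(dim(labels)) != 3L)
    stop("parcellation: 'labels' must be a 3D array")
  storage.mode(labels) <- "integer"
  affine <- check_affine(affine)
  cortical_ids <- as.integer(cortical_ids)
  present <- unique(as.integer(labels))
  missing_ids <- setdiff(cortical_ids, present)
  if (length(missing_ids))
    stop("parcellation: cortical ids absent from labels: ",
         paste(missing_ids, collapse = ", "))
  structure(list(labels = labels, affine = affine,
                 label_table = label_table, cortical_ids = cortical_ids),
            class = "parcellation")
}

check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stop("affine must be a finite 4x4 matrix")
  d <- det(affine[1:3, 1:3])
  if (!is.finite(d) || abs(d) < 1e-12)
    stop("affine is singular")
  affine
}

#' @export
print.volume3d <- function(x, ...) {
  cat("<volume3d> ", paste(dim(x$data), collapse = " x "),
      " voxels, space '", x$space, "'\n", sep = "")
  invisible(x)
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat("<volume4d> subject '", x$subject_id, "', ",
      paste(d[1:3], collapse = " x "), " voxels x ", d[4],
      " timepoints\n", sep = "")
  invisible(x)
}

is_binary_data <- function(x, tol = 1e-6) {
  v <- x[!is.na(x)]
  all(abs(v) <= tol | abs(v - 1) <= tol)
}

#' Check that volumes share one spatial grid
#'
#' Volumes entering an analysis together must agree on shape and affine to
#' within `tol`; mismatches are hard errors (no resampling is performed).
#'
#' @param ... objects of class `volume3d`, `volume4d` or `parcellation`.
#' @param tol maximum absolute affine discrepancy.
#' @return Invisibly `TRUE`; stops on mismatch.
#' @export
check_same_grid <- function(..., tol = 1e-4) {
  objs <- list(...)
  get_shape <- function(o) {
    if (inherits(o, "parcellation")) dim(o$labels)
    else dim(o$data)[1:3]
  }
  get_affine <- function(o) o$affine
  ref_shape <- get_shape(objs[[1]])
  ref_aff <- get_affine(objs[[1]])
  for (o in objs[-1]) {
    if (!identical(as.integer(get_shape(o)), as.integer(ref_shape)))
      stop("grid mismatch: shapes differ (",
           paste(ref_shape, collapse = "x"), " vs ",
           paste(get_shape(o), collapse = "x"), ")")
    if (max(abs(get_affine(o) - ref_aff)) > tol)
      stop("grid mismatch: affines differ beyond tolerance ", tol)
  }
  invisible(TRUE)
}

# ---- NIfTI I/O -------------------------------------------------------------

#' Read a 3D NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param expect_binary if `TRUE`, reject volumes whose values are not all
#'   within `1e-6` of 0 or 1.
#' @param space template tag to attach.
#' @return A [volume3d()].
#' @export
read_volume <- function(path, expect_binary = FALSE, space = "synth") {
  if (!file.exists(path)) stop("read_volume: no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("read_volume: expected 3D data, got ",
         length(dim(arr)), "D: ", path)
  if (expect_binary && !is_binary_data(arr))
    stop("read_volume: volume is not binary within tolerance 1e-6: ", path)
  volume3d(array(as.double(arr), dim(arr)), affine = nifti_affine(img),
           space = space)
}

#' Read a 4D NIfTI time-series volume
#'
#' @param path path to a 4D NIfTI file.
#' @param subject_id identifier to attach.
#' @return A [volume4d()].
#' @export
read_volume4d <- function(path, subject_id = basename(path)) {
  if (!file.exists(path)) stop("read_volume4d: no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop("read_volume4d: expected 4D data: ", path)
  volume4d(array(as.double(arr), dim(arr)), affine = nifti_affine(img),
           subject_id = subject_id)
}

nifti_affine <- function(img) {
  hdr <- RNifti::niftiHeader(img)
  x <- if (hdr$sform_code > 0)
    RNifti::xform(img, useQuaternionFirst = FALSE)
  else
    RNifti::xform(img)
  m <- matrix(as.numeric(x), 4, 4)
  m
}

#' Write a volume as NIfTI
#'
#' Data are stored as float64 so that write-then-read round-trips bitwise;
#' the affine is stored in the sform (code 2). `NA` values are written as
#' `NaN`.
#'
#' @param vol a [volume3d()] or [volume4d()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, c("volume3d", "volume4d")))
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

# ---- Coordinate transforms -------------------------------------------------

#' Map world (mm) points to voxel indices
#'
#' Applies the inverse affine and rounds to the nearest voxel (half-up), so
#' each voxel owns the half-open unit cube centred on its lattice point.
#' Returned indices are 1-based; they may fall outside the array bounds and
#' callers are expected to filter.
#'
#' @param vol a `volume3d` (or any object with an `affine` field).
#' @param points numeric n x 3 matrix (or length-3 vector) of mm coordinates.
#' @return Integer n x 3 matrix of 1-based voxel indices.
#' @export
world_to_voxel <- function(vol, points) {
  pts <- rbind3(points)
  inv <- solve(vol$affine)
  v0 <- cbind(pts, 1) %*% t(inv)     # 0-based continuous voxel coords
  idx <- floor(v0[, 1:3, drop = FALSE] + 0.5) + 1
  storage.mode(idx) <- "integer"
  idx
}

#' Map voxel indices to world (mm) coordinates of voxel centres
#'
#' @param vol a `volume3d`.
#' @param idx integer n x 3 matrix of 1-based voxel indices.
#' @return Numeric n x 3 matrix of mm coordinates.
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- rbind3(idx)
  w <- cbind(idx - 1, 1) %*% t(vol$affine)
  w[, 1:3, drop = FALSE]
}

rbind3 <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be n x 3")
  if (!all(is.finite(points))) stop("points must be finite")
  points
}

# flat indices of voxels inside array bounds; 0 for out-of-bounds rows
flat_index <- function(dims, idx) {
  ok <- idx[, 1] >= 1L & idx[, 1] <= dims[1] &
        idx[, 2] >= 1L & idx[, 2] <= dims[2] &
        idx[, 3] >= 1L & idx[, 3] <= dims[3]
  out <- integer(nrow(idx))
  out[ok] <- idx[ok, 1] +
    (idx[ok, 2] - 1L) * dims[1] +
    (idx[ok, 3] - 1L) * dims[1] * dims[2]
  out
}
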